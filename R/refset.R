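#' Six-class secondary-structure fraction vector
#'
#' The deconvolution works with six classes: ordered alpha-helix `h_r`,
#' distorted alpha-helix `h_d`, ordered beta-strand `s_r`, distorted
#' beta-strand `s_d`, `turn`, and `unordered`. Distorted residues are the
#' terminal/irregular residues of a segment (about four per helix, two per
#' strand); they are what links contents to segment numbers.
#'
#' During deconvolution, candidate solutions may carry slightly negative
#' components (down to the -0.025 selection floor) and sums slightly off 1;
#' a *clean* fraction vector (after final cleanup) has every component in
#' \eqn{[0, 1]} and components summing to 1 within 1e-9.
#'
#' @param h_r,h_d,s_r,s_d,turn,unordered Fractions of residues
#'   (dimensionless).
#' @param clean If `TRUE` (default) enforce the post-cleanup invariants;
#'   if `FALSE` only require each component >= -0.025.
#' @return A named numeric vector of class `fraction_vector` with components
#'   `h_r, h_d, s_r, s_d, turn, unordered`.
#' @examples
#' fraction_vector(0.067, 0.104, 0.159, 0.113, 0.25, 0.307)
#' @export
fraction_vector <- function(h_r, h_d, s_r, s_d, turn, unordered,
                            clean = TRUE) {
  f <- c(h_r = h_r, h_d = h_d, s_r = s_r, s_d = s_d, turn = turn,
         unordered = unordered)
  validate_fractions(f, clean = clean)
  structure(f, class = "fraction_vector")
}

ss_classes <- c("h_r", "h_d", "s_r", "s_d", "turn", "unordered")

validate_fractions <- function(f, clean = TRUE) {
  if (length(f) != 6L || any(!is.finite(f))) {
    stop("a fraction vector has 6 finite components", call. = FALSE)
  }
  if (clean) {
    if (any(f < 0) || any(f > 1)) {
      stop("clean fractions must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(f) - 1) > 1e-9) {
      stop("clean fractions must sum to 1 (got ", format(sum(f)), ")",
           call. = FALSE)
    }
  } else if (any(f < -0.025 - 1e-12)) {
    stop("fraction components below the -0.025 floor", call. = FALSE)
  }
  invisible(f)
}

#' Clip-and-renormalize cleanup of a raw fraction solution
#'
#' Negative components are clipped to zero and the vector is rescaled to sum
#' to 1. Applied once, to the final averaged deconvolution solution only, so
#' that the -0.025 fraction-rule floor stays observable on intermediates.
#'
#' @param f Numeric vector of 6 raw fractions.
#' @return A clean [fraction_vector()].
#' @export
cleanup_fractions <- function(f) {
  f <- pmax(as.numeric(f), 0)
  s <- sum(f)
  if (s <= 0) stop("cannot renormalize an all-zero fraction vector", call. = FALSE)
  f <- f / s
  names(f) <- ss_classes
  structure(f, class = "fraction_vector")
}

#' A reference protein: spectrum plus known fractions
#'
#' @param name Identifier.
#' @param spectrum A [cd_spectrum()].
#' @param fractions A clean [fraction_vector()] (or named numeric of 6).
#' @param n_res Residue count (>= 1).
#' @return An object of class `reference_protein`.
#' @export
reference_protein <- function(name, spectrum, fractions, n_res) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  fractions <- structure(as.numeric(fractions)[1:6], names = ss_classes,
                         class = "fraction_vector")
  validate_fractions(fractions, clean = TRUE)
  if (!is.numeric(n_res) || n_res < 1) stop("n_res must be >= 1", call. = FALSE)
  structure(list(name = as.character(name), spectrum = spectrum,
                 fractions = fractions, n_res = as.integer(n_res)),
            class = "reference_protein")
}

#' Assemble a reference set on a common analysis grid
#'
#' The deconvolution basis: an ordered collection of reference proteins, each
#' with a CD spectrum and a known six-class fraction vector. All spectra are
#' resampled to the common grid at construction. At least 6 members are
#' required (the rank needed to resolve 6 classes).
#'
#' @param proteins List of [reference_protein()] objects.
#' @param grid Common wavelength grid (nm); defaults to [analysis_grid()]
#'   intersected with the span shared by all member spectra.
#' @return An object of class `reference_set` with elements `proteins`,
#'   `grid`.
#' @export
reference_set <- function(proteins, grid = NULL) {
  if (length(proteins) < 6L) {
    stop("a reference set needs at least 6 members (6-class rank requirement)",
         call. = FALSE)
  }
  stopifnot(all(vapply(proteins, inherits, logical(1), "reference_protein")))
  if (is.null(grid)) {
    lo <- max(vapply(proteins, function(p) min(p$spectrum$wavelengths), 0))
    hi <- min(vapply(proteins, function(p) max(p$spectrum$wavelengths), 0))
    g <- analysis_grid()
    grid <- g[g >= lo & g <= hi]
    if (length(grid) < 2L) stop("member spectra share no analysis window",
                                call. = FALSE)
  }
  proteins <- lapply(proteins, function(p) {
    p$spectrum <- resample_to_grid(p$spectrum, grid)
    p
  })
  structure(list(proteins = proteins, grid = as.numeric(grid)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d proteins on %d-point grid %.0f-%.0f nm\n",
              length(x$proteins), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$proteins)

#' Build the spectra and fraction matrices of a reference set
#'
#' @param rs A [reference_set()].
#' @return A list with `spectra` (wavelengths x proteins matrix of
#'   \eqn{\Delta\epsilon}) and `fractions` (6 classes x proteins matrix);
#'   column order follows member order.
#' @export
build_matrices <- function(rs) {
  stopifnot(inherits(rs, "reference_set"))
  nm <- vapply(rs$proteins, `[[`, character(1), "name")
  spectra <- vapply(rs$proteins, function(p) {
    if (length(p$spectrum$wavelengths) != length(rs$grid) ||
        max(abs(p$spectrum$wavelengths - rs$grid)) > 1e-9) {
      stop("member '", p$name, "' is not on the common grid", call. = FALSE)
    }
    p$spectrum$values
  }, numeric(length(rs$grid)))
  fractions <- vapply(rs$proteins, function(p) as.numeric(p$fractions),
                      numeric(6))
  dimnames(spectra) <- list(NULL, nm)
  dimnames(fractions) <- list(ss_classes, nm)
  list(spectra = spectra, fractions = fractions)
}

#' Leave-one-out evaluation of a reference set
#'
#' Each member's spectrum is deconvolved against the remaining members; the
#' pooled root-mean-square deviation (delta) and Pearson correlation (r)
#' between estimated and known fractions, over all (protein, class) pairs,
#' summarize how well the set supports deconvolution. This mirrors the
#' standard benchmark reported for measured VUVCD reference databases
#' (delta ~ 0.06, r ~ 0.85 for a 31-protein set).
#'
#' Both statistics pool all classes; `r` is reported as `NA` with
#' `degenerate_correlation = TRUE` when the true fractions have zero
#' variance across the pooled pairs.
#'
#' @param rs A [reference_set()] with at least 7 members.
#' @param config A [selcon_config()].
#' @return A list: `delta`, `r`, `n_evaluated`, `failed` (names of members
#'   whose deconvolution failed, skipped with a warning),
#'   `degenerate_correlation`, and `per_protein` (data frame of per-member
#'   RMSDs).
#' @export
loo_evaluate <- function(rs, config = selcon_config()) {
  stopifnot(inherits(rs, "reference_set"))
  n <- length(rs$proteins)
  if (n < 7L) stop("leave-one-out needs at least 7 members", call. = FALSE)
  est <- truth <- matrix(NA_real_, nrow = 6, ncol = n,
                         dimnames = list(ss_classes, NULL))
  failed <- character(0)
  for (i in seq_len(n)) {
    rest <- reference_set(rs$proteins[-i], grid = rs$grid)
    qry <- rs$proteins[[i]]$spectrum
    res <- tryCatch(selcon_deconvolve(qry, rest, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, rs$proteins[[i]]$name)
      warning("deconvolution failed for member '", rs$proteins[[i]]$name,
              "': ", conditionMessage(res), call. = FALSE)
      next
    }
    est[, i] <- as.numeric(res$fractions)
    truth[, i] <- as.numeric(rs$proteins[[i]]$fractions)
  }
  ok <- !is.na(est[1, ])
  if (!any(ok)) {
    stop("deconvolution failed for every member of the set", call. = FALSE)
  }
  e <- est[, ok, drop = FALSE]
  t_ <- truth[, ok, drop = FALSE]
  delta <- sqrt(mean((e - t_)^2))
  # a set whose members all share one fraction vector has no across-protein
  # variance to correlate against
  degenerate <- all(apply(t_, 1, function(x) diff(range(x)) < 1e-12))
  r <- if (degenerate) NA_real_ else stats::cor(as.numeric(e), as.numeric(t_))
  per <- data.frame(
    name = vapply(rs$proteins, `[[`, character(1), "name")[ok],
    rmsd = sqrt(colMeans((e - t_)^2))
  )
  list(delta = delta, r = r, n_evaluated = sum(ok), failed = failed,
       degenerate_correlation = degenerate, per_protein = per)
}

#' Write a reference set to a directory (YAML manifest + spectrum files)
#'
#' There is no community standard container for CD reference sets, so the
#' package uses a YAML manifest (`manifest.yaml`) listing, per protein, its
#' name, residue count, six fractions, and the relative path of its spectrum
#' file in the [write_spectrum()] format.
#'
#' @param rs A [reference_set()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_reference_set <- function(rs, dir) {
  stopifnot(inherits(rs, "reference_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(rs$proteins), function(i) {
    p <- rs$proteins[[i]]
    fn <- sprintf("%s.cd.tsv", gsub("[^A-Za-z0-9_.-]", "_", p$name))
    write_spectrum(p$spectrum, file.path(dir, fn))
    list(name = p$name, n_res = p$n_res, spectrum = fn,
         fractions = as.list(stats::setNames(as.numeric(p$fractions), ss_classes)))
  })
  manifest <- list(grid = list(min_nm = min(rs$grid), max_nm = max(rs$grid),
                               step_nm = if (length(rs$grid) > 1)
                                 rs$grid[2] - rs$grid[1] else 1),
                   proteins = entries)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param path Manifest file path (or the directory containing
#'   `manifest.yaml`).
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  manifest <- yaml::read_yaml(path)
  dir <- dirname(path)
  proteins <- lapply(manifest$proteins, function(e) {
    f <- unlist(e$fractions)[ss_classes]
    reference_protein(e$name, read_spectrum(file.path(dir, e$spectrum)),
                      f, e$n_res)
  })
  g <- manifest$grid
  reference_set(proteins, grid = seq(g$min_nm, g$max_nm, by = g$step_nm))
}
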