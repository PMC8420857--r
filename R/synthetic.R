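#' Default Gaussian band parameters for the six basis curves
#'
#' Literature-standard CD band shapes: the ordered-helix curve has a
#' positive band near 192 nm and negative bands near 208 and 222 nm; the
#' strand curve a positive band near 198 nm and a negative one near 216 nm;
#' unordered structure a strong negative band near 198 nm; turns small broad
#' features. Distorted classes are attenuated, slightly shifted versions of
#' their ordered counterparts. Each entry is a list of
#' `c(center_nm, width_nm, amplitude)` triples; amplitudes are in
#' \eqn{\Delta\epsilon} units for a hypothetical pure structure.
#'
#' These shapes emulate the physics well enough to exercise the
#' deconvolution; they are synthetic and make no claim to match any measured
#' reference database.
#'
#' @return Named list (one element per class in
#'   `h_r, h_d, s_r, s_d, turn, unordered`) of lists of numeric triples.
#' @export
default_band_params <- function() {
  list(
    h_r = list(c(192, 6, 18), c(208, 6, -10), c(222, 8, -11)),
    h_d = list(c(192, 6, 6), c(205, 7, -4), c(222, 9, -3)),
    s_r = list(c(198, 7, 7), c(216, 9, -5)),
    s_d = list(c(200, 8, 2.5), c(218, 10, -2)),
    turn = list(c(185, 8, 3), c(205, 12, 1)),
    unordered = list(c(198, 7, -7), c(218, 10, 0.5))
  )
}

#' Generate the six basis spectra from Gaussian bands
#'
#' Each class curve is a sum of Gaussian components
#' \eqn{A \exp(-(\lambda - c)^2 / (2 w^2))}. With `jitter > 0`, band
#' centers and amplitudes are perturbed (normal, sd = `jitter` nm for
#' centers and `jitter` percent of amplitude), deterministically for a
#' fixed seed.
#'
#' @param grid Wavelength grid (nm), within 160--320.
#' @param params Band parameterization as in [default_band_params()].
#' @param jitter Non-negative perturbation scale (0 = exact defaults).
#' @param seed Integer seed used when `jitter > 0`.
#' @return An object of class `basis_spectra`: list with `grid` and
#'   `curves` (length(grid) x 6 matrix, columns in class order).
#' @export
make_basis_spectra <- function(grid = analysis_grid(), params = default_band_params(),
                               jitter = 0, seed = 1L) {
  grid <- as.numeric(grid)
  if (any(grid < 160 | grid > 320)) {
    stop("grid must lie within [160, 320] nm", call. = FALSE)
  }
  if (!identical(sort(names(params)), sort(ss_classes))) {
    stop("params must name all six classes", call. = FALSE)
  }
  rng <- local_rng(seed)
  curves <- vapply(ss_classes, function(cls) {
    bands <- params[[cls]]
    y <- numeric(length(grid))
    for (b in bands) {
      if (!is.numeric(b) || length(b) != 3L || b[2] <= 0) {
        stop("each band must be a numeric triple (center, width > 0, amplitude)",
             call. = FALSE)
      }
      ctr <- b[1]; wid <- b[2]; amp <- b[3]
      if (jitter > 0) {
        ctr <- ctr + rng$rnorm(1, 0, jitter)
        amp <- amp * (1 + rng$rnorm(1, 0, jitter / 100))
      }
      y <- y + amp * exp(-(grid - ctr)^2 / (2 * wid^2))
    }
    y
  }, numeric(length(grid)))
  structure(list(grid = grid, curves = curves), class = "basis_spectra")
}

# small deterministic RNG scope: draws do not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = function(...) draw(stats::rnorm, ...),
       runif = function(...) draw(stats::runif, ...),
       rgamma = function(...) draw(stats::rgamma, ...),
       sample = function(...) draw(base::sample, ...))
}

#' Simulate a reference set with known fractions
#'
#' Fractions are drawn per protein from one of three Dirichlet archetypes
#' (helix-rich, strand-rich, mixed) over the four totals (helix, strand,
#' turn, unordered); the distorted shares are then fixed fractions of the
#' class totals (`h_d = distorted_h * helix_total`,
#' `s_d = distorted_s * strand_total`), a simplification of the
#' roughly-constant number of distorted residues per segment. Spectra are
#' the fraction-weighted sums of the basis curves plus white noise with
#' standard deviation `noise_sigma` times the peak absolute amplitude of
#' the clean spectrum.
#'
#' @param n Number of proteins (>= 6).
#' @param basis A [make_basis_spectra()] result.
#' @param noise_sigma Noise level as a fraction of each spectrum's peak
#'   amplitude (e.g. 0.02 for 2 percent).
#' @param alpha List of Dirichlet parameter vectors (length 4: helix,
#'   strand, turn, unordered), one per archetype, cycled over proteins.
#' @param distorted_h,distorted_s Distorted share of the helix and strand
#'   totals (defaults 0.4 and 0.45).
#' @param n_res_range Residue counts are drawn uniformly from this range.
#' @param seed Integer seed; fixed seed gives a byte-identical set.
#' @return A [reference_set()]; each member's name is `ref##`.
#' @export
make_reference_set <- function(n, basis = make_basis_spectra(),
                               noise_sigma = 0.02,
                               alpha = list(helix_rich = c(8, 2, 2, 3),
                                            strand_rich = c(2, 8, 2, 3),
                                            mixed = c(4, 4, 2.5, 3.5)),
                               distorted_h = 0.4, distorted_s = 0.45,
                               n_res_range = c(80, 350), seed = 1L) {
  if (n < 6L) stop("a reference set needs at least 6 members", call. = FALSE)
  stopifnot(inherits(basis, "basis_spectra"))
  rng <- local_rng(seed)
  proteins <- lapply(seq_len(n), function(i) {
    a <- alpha[[((i - 1L) %% length(alpha)) + 1L]]
    g <- rng$rgamma(4, shape = a, rate = 1)
    tot <- g / sum(g) # (helix, strand, turn, unordered)
    f <- c(h_r = tot[1] * (1 - distorted_h), h_d = tot[1] * distorted_h,
           s_r = tot[2] * (1 - distorted_s), s_d = tot[2] * distorted_s,
           turn = tot[3], unordered = tot[4])
    clean <- as.numeric(basis$curves %*% f)
    peak <- max(abs(clean))
    noisy <- clean + rng$rnorm(length(clean), 0, noise_sigma * peak)
    n_res <- floor(rng$runif(1, n_res_range[1], n_res_range[2] + 1))
    reference_protein(sprintf("ref%02d", i),
                      cd_spectrum(basis$grid, noisy,
                                  meta = list(name = sprintf("ref%02d", i))),
                      f, n_res)
  })
  reference_set(proteins, grid = basis$grid)
}

#' Simulate a query spectrum with known fractions
#'
#' @param fractions A clean [fraction_vector()] (or named numeric of 6).
#' @param basis A [make_basis_spectra()] result.
#' @param noise_sigma Noise level as a fraction of peak amplitude.
#' @param seed Integer seed.
#' @param name Sample name stored in the metadata.
#' @return A [cd_spectrum()] on the basis grid.
#' @export
make_query_spectrum <- function(fractions, basis = make_basis_spectra(),
                                noise_sigma = 0, seed = 1L, name = "query") {
  f <- as.numeric(fractions)
  validate_fractions(f, clean = TRUE)
  clean <- as.numeric(basis$curves %*% f)
  if (noise_sigma > 0) {
    rng <- local_rng(seed)
    clean <- clean + rng$rnorm(length(clean), 0, noise_sigma * max(abs(clean)))
  }
  cd_spectrum(basis$grid, clean, meta = list(name = name))
}

#' Planted-truth propensity profile
#'
#' Builds a profile in which residues of a known labeling score
#' `base + margin + noise` for their own class and `base + noise` otherwise.
#' With `margin` well above `noise_sigma`, [constrained_assign()] with the
#' true counts as targets recovers the labeling exactly; with `margin = 0`
#' recovery is at chance level.
#'
#' @param labels True label string over `{H, E, C}`.
#' @param margin In-class score bonus.
#' @param noise_sigma Standard deviation of the additive normal noise.
#' @param base Baseline score.
#' @param sequence Optional amino-acid string (defaults to poly-A) stored in
#'   the profile.
#' @param seed Integer seed.
#' @return A [propensity_profile()].
#' @export
make_planted_profile <- function(labels, margin = 2, noise_sigma = 0.2,
                                 base = 0, sequence = NULL, seed = 1L) {
  lab <- label_chars(labels)
  if (any(!lab %in% c("H", "E", "C"))) {
    stop("labels must be over {H, E, C}", call. = FALSE)
  }
  n <- length(lab)
  rng <- local_rng(seed)
  h <- base + margin * (lab == "H") + rng$rnorm(n, 0, noise_sigma)
  e <- base + margin * (lab == "E") + rng$rnorm(n, 0, noise_sigma)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  propensity_profile(sequence, h, e)
}

#' Random label string with given counts (for tests and demos)
#'
#' Draws a uniformly random arrangement by shuffling positions, then
#' returns the labeling; counts of H/E residues are exact, segment counts
#' are whatever the shuffle yields.
#'
#' @param n Sequence length.
#' @param n_h,n_e Residue counts (must satisfy `n_h + n_e <= n`).
#' @param seed Integer seed.
#' @return A label string.
#' @export
random_labels <- function(n, n_h, n_e, seed = 1L) {
  if (n_h + n_e > n) stop("n_h + n_e must not exceed n", call. = FALSE)
  rng <- local_rng(seed)
  lab <- rep("C", n)
  pos <- rng$sample(n, n_h + n_e)
  lab[pos[seq_len(n_h)]] <- "H"
  if (n_e > 0) lab[pos[n_h + seq_len(n_e)]] <- "E"
  paste(lab, collapse = "")
}
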