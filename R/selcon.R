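#' Configuration for the self-consistent deconvolution
#'
#' All selection thresholds of the SELCON3-style scheme, surfaced so their
#' sensitivity can be tested.
#'
#' @param tol_sum Sum-rule half-width: a candidate solution survives if its
#'   component sum lies in `[1 - tol_sum, 1 + tol_sum]`.
#' @param frac_floor Fraction-rule floor: every component must be
#'   `>= frac_floor` (slightly negative components are tolerated on raw
#'   solutions; cleanup happens only at the end).
#' @param fit_max Spectral-fit rule: maximum RMSD (\eqn{\Delta\epsilon}
#'   units) between the rank-k reconstruction of the query spectrum and the
#'   measured query.
#' @param helix_tol Helix-stability rule: total helix content of a surviving
#'   solution must be within `helix_tol` of the converged highest-rank
#'   solution.
#' @param tol_sc Self-consistency tolerance: iterate until the maximum
#'   absolute change of any class is below this.
#' @param max_iter Maximum self-consistency iterations.
#' @param k_max Maximum number of SVD components considered (capped at the
#'   number of reference proteins and at the numerical rank of the combined
#'   spectra matrix).
#' @param range_nm Analysis wavelength window (nm), intersected with the
#'   available data.
#' @return A list of class `selcon_config`.
#' @export
selcon_config <- function(tol_sum = 0.05, frac_floor = -0.025, fit_max = 0.25,
                          helix_tol = 0.03, tol_sc = 1e-3, max_iter = 100L,
                          k_max = 8L, range_nm = c(175, 240)) {
  structure(list(tol_sum = tol_sum, frac_floor = frac_floor,
                 fit_max = fit_max, helix_tol = helix_tol, tol_sc = tol_sc,
                 max_iter = as.integer(max_iter), k_max = as.integer(k_max),
                 range_nm = range_nm),
            class = "selcon_config")
}

#' Initial guess: fractions of the nearest reference spectrum
#'
#' The starting point of the self-consistent iteration is the fraction
#' vector of the reference protein whose spectrum is closest to the query in
#' RMSD. Ties go to the lower-index member.
#'
#' @param query A [cd_spectrum()] already resampled to the set's grid.
#' @param rs A [reference_set()].
#' @return A list: `fractions` (named numeric, 6), `nearest` (member name),
#'   `rmsd`.
#' @export
initial_guess <- function(query, rs) {
  stopifnot(inherits(query, "cd_spectrum"), inherits(rs, "reference_set"))
  if (length(rs$proteins) == 0L) stop("empty reference set", call. = FALSE)
  mats <- build_matrices(rs)
  if (length(query$values) != nrow(mats$spectra)) {
    stop("query must be resampled to the reference grid first", call. = FALSE)
  }
  rmsd <- sqrt(colMeans((mats$spectra - query$values)^2))
  k <- which.min(rmsd) # which.min returns the first (lowest-index) minimum
  list(fractions = mats$fractions[, k], nearest = colnames(mats$spectra)[k],
       rmsd = rmsd[[k]])
}

#' Self-consistent SVD deconvolution of a CD spectrum
#'
#' Estimates the six secondary-structure fractions of a query protein from
#' its CD spectrum against a reference set, with the self-consistent scheme
#' of the SELCON3 family:
#'
#' 1. The query spectrum is prepended to the reference spectra matrix and
#'    the current fraction guess (initially the nearest member's fractions,
#'    see [initial_guess()]), renormalized to sum to 1 like every reference
#'    column, to the fractions matrix.
#' 2. The combined spectra matrix is factored by SVD.
#' 3. For each truncation rank k = 1..K the query's fractions are
#'    reconstructed by projecting the fractions matrix onto the rank-k row
#'    space.
#' 4. The guess is replaced by the highest-rank solution and steps 1--3
#'    repeat until no class changes by more than `tol_sc`.
#' 5. Candidate solutions (one per rank) are filtered by the sum rule,
#'    fraction rule, spectral-fit rule and helix-stability rule (see
#'    [selcon_config()]).
#' 6. The final estimate is the mean of the surviving solutions, clipped to
#'    non-negative values and renormalized to sum to 1.
#'
#' K is `config$k_max` capped at the number of reference proteins and at the
#' numerical rank of the combined spectra matrix (singular values above
#' `1e-8` of the largest); on noise-free, low-rank sets the discarded
#' components are numerically meaningless directions.
#'
#' @param query A [cd_spectrum()]; resampled internally to the analysis
#'   window (`config$range_nm` intersected with the set grid and the query
#'   span, which must cover at least 40 nm).
#' @param rs A [reference_set()].
#' @param config A [selcon_config()].
#' @return A list of class `selcon_result`: `fractions` (clean
#'   [fraction_vector()]), `raw_solution` (pre-cleanup mean),
#'   `diagnostics` (list: `iterations`, `converged`, `n_candidates`,
#'   `n_surviving`, `rejections` per rule, `fit_rmsd` of the best surviving
#'   rank, `k_used`, `initial_nearest`), and `grid`.
#'
#' If no candidate survives the selection rules an error of class
#' `vuvcd_no_solution` is signalled, carrying the diagnostics in its
#' `data` field; non-convergence raises `vuvcd_no_convergence`.
#' @export
selcon_deconvolve <- function(query, rs, config = selcon_config()) {
  stopifnot(inherits(query, "cd_spectrum"), inherits(rs, "reference_set"))
  grid <- rs$grid
  grid <- grid[grid >= config$range_nm[1] & grid <= config$range_nm[2]]
  grid <- grid[grid >= min(query$wavelengths) & grid <= max(query$wavelengths)]
  if (length(grid) < 2L || diff(range(grid)) < 40) {
    stop("query and reference set must share an analysis window of >= 40 nm",
         call. = FALSE)
  }
  q <- resample_to_grid(query, grid)$values
  rs_g <- reference_set(rs$proteins, grid = grid)
  mats <- build_matrices(rs_g)
  C <- mats$spectra       # m x n
  Fm <- mats$fractions    # 6 x n
  n <- ncol(C)

  ig <- initial_guess(resample_to_grid(query, grid), rs_g)
  guess <- as.numeric(ig$fractions)

  iter <- 0L
  converged <- FALSE
  sols <- NULL
  fit_rmsd <- NULL
  k_eff <- NULL
  while (iter < config$max_iter) {
    iter <- iter + 1L
    A <- cbind(q, C)                 # m x (n+1)
    # reference fraction columns sum to 1; the prepended guess must too, or
    # the projection feeds its own shrinkage back into the iteration; a
    # degenerate (near-zero) guess falls back to uniform fractions
    gs <- sum(guess)
    g1 <- if (is.finite(gs) && gs > 0.25) guess / gs else rep(1 / 6, 6)
    Fx <- cbind(g1, Fm)
    sv <- svd(A)
    rank_num <- sum(sv$d > 1e-8 * sv$d[1])
    k_eff <- max(1L, min(config$k_max, n, rank_num))
    # projection of e1 (the query's column) onto the rank-k row space
    v1 <- sv$v[1, , drop = FALSE]    # first row of V: 1 x r
    sols <- matrix(NA_real_, nrow = 6, ncol = k_eff)
    fit_rmsd <- numeric(k_eff)
    for (k in seq_len(k_eff)) {
      Vk <- sv$v[, seq_len(k), drop = FALSE]
      w <- Vk %*% t(v1[, seq_len(k), drop = FALSE]) # V_k V_k' e1, (n+1) x 1
      sols[, k] <- Fx %*% w
      qk <- sv$u[, seq_len(k), drop = FALSE] %*%
        (sv$d[seq_len(k)] * t(Vk[1, , drop = FALSE])) # rank-k reconstruction
      fit_rmsd[k] <- sqrt(mean((qk - q)^2))
    }
    new_guess <- sols[, k_eff]
    delta <- max(abs(new_guess - guess))
    guess <- new_guess
    if (delta < config$tol_sc) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("vuvcd_no_convergence", "error", "condition"),
      list(message = sprintf(
        "self-consistent iteration did not converge in %d iterations",
        config$max_iter),
        call = sys.call(-1),
        data = list(iterations = iter, last_guess = guess)))
    stop(cond)
  }

  helix_anchor <- sum(sols[1:2, k_eff])
  sums <- colSums(sols)
  pass_sum <- abs(sums - 1) <= config$tol_sum
  pass_frac <- apply(sols, 2, function(f) all(f >= config$frac_floor))
  pass_fit <- fit_rmsd <= config$fit_max
  helix_tot <- colSums(sols[1:2, , drop = FALSE])
  pass_helix <- abs(helix_tot - helix_anchor) <= config$helix_tol
  keep <- pass_sum & pass_frac & pass_fit & pass_helix

  diagnostics <- list(
    iterations = iter, converged = converged, n_candidates = k_eff,
    n_surviving = sum(keep),
    rejections = c(sum_rule = sum(!pass_sum), fraction_rule = sum(!pass_frac),
                   fit_rule = sum(!pass_fit), helix_rule = sum(!pass_helix)),
    fit_rmsd = if (any(keep)) min(fit_rmsd[keep]) else min(fit_rmsd),
    k_used = k_eff, initial_nearest = ig$nearest)

  if (!any(keep)) {
    cond <- structure(
      class = c("vuvcd_no_solution", "error", "condition"),
      list(message = paste0(
        "no candidate solution survived the selection rules (rejections: ",
        paste(names(diagnostics$rejections), diagnostics$rejections,
              sep = "=", collapse = ", "), ")"),
        call = sys.call(-1), data = diagnostics))
    stop(cond)
  }

  raw <- rowMeans(sols[, keep, drop = FALSE])
  names(raw) <- ss_classes
  structure(list(fractions = cleanup_fractions(raw), raw_solution = raw,
                 diagnostics = diagnostics, grid = grid),
            class = "selcon_result")
}

#' @export
print.selcon_result <- function(x, ...) {
  f <- 100 * as.numeric(x$fractions)
  cat(sprintf(
    "SELCON-style deconvolution: %d/%d solutions kept, %d iterations\n",
    x$diagnostics$n_surviving, x$diagnostics$n_candidates,
    x$diagnostics$iterations))
  cat(sprintf("  H(r) %.1f%%  H(d) %.1f%%  S(r) %.1f%%  S(d) %.1f%%  turn %.1f%%  unord %.1f%%\n",
              f[1], f[2], f[3], f[4], f[5], f[6]))
  tc <- total_contents(x$fractions)
  cat(sprintf("  helix %.1f%%  strand %.1f%%  other %.1f%%\n",
              100 * tc["helix"], 100 * tc["strand"], 100 * tc["other"]))
  invisible(x)
}

#' Collapse six fractions to helix / strand / other totals
#'
#' Helix = ordered + distorted helix; strand = ordered + distorted strand;
#' other = turn + unordered (turns and unordered structures are grouped as
#' "other structures" downstream of the deconvolution).
#'
#' @param f A clean [fraction_vector()] or named numeric of 6.
#' @return Named numeric `c(helix =, strand =, other =)`, summing to 1.
#' @examples
#' f <- fraction_vector(0.067, 0.104, 0.159, 0.113, 0.25, 0.307)
#' round(100 * total_contents(f), 1) # helix 17.1, strand 27.2
#' @export
total_contents <- function(f) {
  f <- as.numeric(f)
  validate_fractions(f, clean = TRUE)
  c(helix = f[1] + f[2], strand = f[3] + f[4], other = f[5] + f[6])
}
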