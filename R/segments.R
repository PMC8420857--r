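#' Round half away from zero
#'
#' Commercial rounding, unlike [round()]'s round-half-to-even. Used wherever
#' fractional residue counts are converted to integers, so that e.g. 2.5
#' distorted-helix segments become 3.
#' @param x Numeric.
#' @return Numeric of the same length, integral values.
#' @keywords internal
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate helix and strand segment numbers from distorted fractions
#'
#' In the six-class scheme, each alpha-helix segment contributes about four
#' distorted (terminal) residues and each beta-strand segment about two, so
#' the distorted contents carry the segment counts:
#' \deqn{N_{helix} = \mathrm{round}(h_d \cdot N_{res} / 4), \qquad
#'       N_{strand} = \mathrm{round}(s_d \cdot N_{res} / 2)}
#' with rounding half away from zero. (Exact .5 cases never arise in typical
#' data; the convention is documented rather than empirically fixed.)
#'
#' @param f A clean [fraction_vector()], or any object from which `h_d` and
#'   `s_d` can be taken by name (a named numeric works).
#' @param n_res Residue count of the chain (>= 1).
#' @return A list of class `segment_estimate`: `n_helix`, `n_strand`,
#'   `n_res`.
#' @examples
#' f <- fraction_vector(0.067, 0.104, 0.159, 0.113, 0.25, 0.307)
#' estimate_segments(f, 238) # 6 helices, 13 strands
#' @export
estimate_segments <- function(f, n_res) {
  if (!is.numeric(n_res) || length(n_res) != 1L || n_res < 1) {
    stop("n_res must be a single integer >= 1", call. = FALSE)
  }
  fv <- as.numeric(f)
  names(fv) <- names(f) %||% ss_classes
  validate_fractions(fv, clean = TRUE)
  h_d <- fv[["h_d"]]
  s_d <- fv[["s_d"]]
  n_helix <- as.integer(round_half_up(h_d * n_res / 4))
  n_strand <- as.integer(round_half_up(s_d * n_res / 2))
  # caps implied by the 4/2 distorted residues per segment
  n_helix <- min(n_helix, as.integer(ceiling(n_res / 4)))
  n_strand <- min(n_strand, as.integer(ceiling(n_res / 2)))
  structure(list(n_helix = n_helix, n_strand = n_strand,
                 n_res = as.integer(n_res)),
            class = "segment_estimate")
}

#' @export
print.segment_estimate <- function(x, ...) {
  cat(sprintf("Segment estimate: %d helices, %d strands over %d residues\n",
              x$n_helix, x$n_strand, x$n_res))
  invisible(x)
}
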