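#' Published VUVCD secondary-structure contents for the NCYM constructs
#'
#' The reported six-class deconvolution results for the 238-residue
#' SUMO-tagged NCYM construct (129-residue SUMO tag + 109-residue NCYM) and
#' the 129-residue isolated SUMO tag, each measured in hydrogenated (`H_`)
#' and perdeuterated (`D_`) form, together with the reported helix and
#' strand segment counts. Fractions are percent of residues.
#'
#' These rows are the worked reference for the segment estimator and the
#' content reduction: `round(h_d/100 * n_res / 4)` and
#' `round(s_d/100 * n_res / 2)` reproduce every printed `n_helix` and
#' `n_strand`, and `h_r + h_d` / `s_r + s_d` give the reported helix and
#' strand totals (17.1/27.2, 16.3/27.0, 14.2/29.2, 13.9/28.7 percent).
#'
#' @return A data frame with columns `sample`, `n_res`, `h_r`, `h_d`,
#'   `s_r`, `s_d` (percent), `n_helix`, `n_strand`.
#' @examples
#' ncym_contents()
#' @export
ncym_contents <- function() {
  path <- system.file("extdata", "ncym_vuvcd_contents.tsv", package = "vuvcd")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Six-class fraction vector from a printed contents row
#'
#' The published table prints only the four helix/strand classes; for
#' operations needing a full clean fraction vector the remainder is booked
#' as unordered (`turn = 0`), which leaves the helix and strand totals --
#' the quantities the table supports -- unchanged.
#'
#' @param row One row of [ncym_contents()].
#' @return A clean [fraction_vector()].
#' @export
fractions_from_row <- function(row) {
  four <- c(row$h_r, row$h_d, row$s_r, row$s_d) / 100
  fraction_vector(four[1], four[2], four[3], four[4],
                  turn = 0, unordered = 1 - sum(four))
}
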