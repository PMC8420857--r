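#' End-to-end pipeline: spectrum to per-residue secondary structure
#'
#' Runs the whole inference chain: deconvolve the query spectrum against
#' the reference set into six fractions, collapse to helix/strand/other
#' totals, estimate segment numbers from the distorted fractions, derive
#' assignment targets, and position the helix/strand segments along the
#' sequence with the constrained assignment. The pipeline is a pure
#' function of its inputs, configuration, and seed: identical reruns give
#' byte-identical reports.
#'
#' @param spectrum A [cd_spectrum()] or path to a spectrum file
#'   ([read_spectrum()] format).
#' @param sequence An amino-acid string or path to a FASTA file.
#' @param refset A [reference_set()] or path to a manifest
#'   ([read_reference_set()]).
#' @param scores Optional [propensity_profile()] or path to an `.ss2`-style
#'   score file; by default windowed Chou-Fasman propensities of the
#'   sequence are used ([table_propensity()]).
#' @param selcon A [selcon_config()].
#' @param assign An [assign_config()].
#' @param window Smoothing window for the default propensities.
#' @param seed Integer recorded in the report (the pipeline itself is
#'   deterministic; the seed documents upstream simulation provenance).
#' @param name Sample name for the report.
#' @return A list of class `vuvcd_report`: `name`, `n_res`,
#'   `fractions_pct` (six fractions in percent, 1 decimal), `totals_pct`
#'   (helix/strand/other in percent), `segments` (`n_helix`, `n_strand`),
#'   `targets`, `assignment` (label string), `discrepancy`, `diagnostics`,
#'   `config`, `seed`, `version`.
#' @export
run_pipeline <- function(spectrum, sequence, refset, scores = NULL,
                         selcon = selcon_config(), assign = assign_config(),
                         window = 5L, seed = 1L, name = NULL) {
  if (is.character(spectrum)) spectrum <- read_spectrum(spectrum)
  if (is.character(refset) && (file.exists(refset) || dir.exists(refset))) {
    refset <- read_reference_set(refset)
  }
  if (is.character(sequence) && file.exists(sequence)) {
    sequence <- read_protein_fasta(sequence)
  }
  sequence <- toupper(as.character(sequence))
  n_res <- nchar(sequence)
  name <- name %||% spectrum$meta$name %||% "query"

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }

  dec <- stage("deconvolution", selcon_deconvolve(spectrum, refset, selcon))
  f <- dec$fractions
  totals <- total_contents(f)
  seg <- stage("segments", estimate_segments(f, n_res))
  targets <- stage("targets", targets_from_vuvcd(f, seg, n_res))
  profile <- if (is.null(scores)) {
    stage("propensity", table_propensity(sequence, window = window))
  } else if (is.character(scores)) {
    stage("propensity", read_external_scores(scores, sequence = sequence))
  } else {
    scores
  }
  if (profile$n_res != n_res) {
    stop("[propensity] score profile length does not match the sequence",
         call. = FALSE)
  }
  ass <- stage("assignment", constrained_assign(profile, targets, assign))

  structure(list(
    name = name,
    n_res = n_res,
    fractions_pct = round(100 * as.numeric(f), 1) |>
      stats::setNames(ss_classes),
    totals_pct = round(100 * totals, 1),
    segments = list(n_helix = seg$n_helix, n_strand = seg$n_strand),
    targets = unclass(targets)[c("n_h_residues", "n_e_residues",
                                 "n_h_segments", "n_e_segments")],
    assignment = ass$labels,
    discrepancy = ass$provenance$discrepancy,
    diagnostics = dec$diagnostics,
    config = list(selcon = unclass(selcon), assign = unclass(assign),
                  window = window),
    seed = seed,
    version = as.character(utils::packageVersion("vuvcd"))
  ), class = "vuvcd_report")
}

#' @export
print.vuvcd_report <- function(x, ...) {
  cat(sprintf("VUVCD pipeline report for '%s' (%d residues)\n", x$name, x$n_res))
  f <- x$fractions_pct
  cat(sprintf("  H(r) %.1f  H(d) %.1f  S(r) %.1f  S(d) %.1f  turn %.1f  unordered %.1f (%%)\n",
              f[1], f[2], f[3], f[4], f[5], f[6]))
  cat(sprintf("  totals: helix %.1f%%  strand %.1f%%  other %.1f%%\n",
              x$totals_pct[["helix"]], x$totals_pct[["strand"]],
              x$totals_pct[["other"]]))
  cat(sprintf("  segments: %d helices, %d strands; assignment discrepancy %g\n",
              x$segments$n_helix, x$segments$n_strand, x$discrepancy))
  invisible(x)
}

#' Write / read a pipeline report as JSON
#'
#' @param report A `vuvcd_report`.
#' @param path Output path.
#' @return `path` invisibly (`write_report`); a `vuvcd_report`
#'   (`read_report`).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "vuvcd_report")
}

#' Compare two pipeline runs (e.g. hydrogenated vs perdeuterated)
#'
#' @param report_a,report_b `vuvcd_report`s over constructs of equal length.
#' @param offset Tag length subtracted from construct positions to report
#'   untagged-protein numbering (e.g. 129 for a 129-residue N-terminal tag).
#' @return A list of class `vuvcd_diff`: `positions` (data frame from
#'   [diff_assignments()]), `content_delta_pct` (six-class, percent),
#'   `totals_delta_pct`, `segment_delta` (`n_helix`, `n_strand`), and the
#'   two run names.
#' @export
compare_runs <- function(report_a, report_b, offset = 0L) {
  if (report_a$n_res != report_b$n_res) {
    stop("reports cover constructs of different lengths", call. = FALSE)
  }
  pos <- diff_assignments(report_a$assignment, report_b$assignment,
                          offset = offset)
  structure(list(
    name_a = report_a$name, name_b = report_b$name,
    positions = pos,
    content_delta_pct = report_a$fractions_pct - report_b$fractions_pct,
    totals_delta_pct = report_a$totals_pct - report_b$totals_pct,
    segment_delta = list(
      n_helix = report_a$segments$n_helix - report_b$segments$n_helix,
      n_strand = report_a$segments$n_strand - report_b$segments$n_strand),
    offset = as.integer(offset)
  ), class = "vuvcd_diff")
}

#' @export
print.vuvcd_diff <- function(x, ...) {
  cat(sprintf("Comparison %s vs %s: %d differing position(s)\n",
              x$name_a, x$name_b, nrow(x$positions)))
  if (nrow(x$positions) > 0) print(x$positions)
  invisible(x)
}
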