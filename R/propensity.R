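#' Chou-Fasman-type helix and strand propensities
#'
#' Classic per-residue conformational propensities (P-alpha, P-beta),
#' bundled as the default score source for the assignment stage. These are a
#' deliberately simple, score-agnostic stand-in for sequence-profile-based
#' predictors: the assignment machinery only consumes ranks, so any
#' per-residue real scores (e.g. read from a `.ss2` file with
#' [read_external_scores()]) can replace them.
#'
#' @return A data frame with columns `residue`, `helix`, `strand` (20 rows).
#' @export
chou_fasman_table <- function() {
  data.frame(
    residue = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    helix = c(1.42, 0.98, 0.67, 1.01, 0.70, 1.11, 1.51, 0.57, 1.00, 1.08,
              1.21, 1.16, 1.45, 1.13, 0.57, 0.77, 0.83, 1.08, 0.69, 1.06),
    strand = c(0.83, 0.93, 0.89, 0.54, 1.19, 1.10, 0.37, 0.75, 0.87, 1.60,
               1.30, 0.74, 1.05, 1.38, 0.55, 0.75, 1.19, 1.37, 1.47, 1.70),
    stringsAsFactors = FALSE
  )
}

#' Per-residue propensity profile
#'
#' @param sequence Amino-acid string.
#' @param h_score,e_score Numeric vectors of per-residue helix and strand
#'   scores, same length as the sequence. Scale-free: only ranks matter
#'   downstream.
#' @return An object of class `propensity_profile`: list with `sequence`,
#'   `h_score`, `e_score`, `n_res`.
#' @export
propensity_profile <- function(sequence, h_score, e_score) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (length(h_score) != n || length(e_score) != n) {
    stop("score arrays must match the sequence length", call. = FALSE)
  }
  if (any(!is.finite(h_score)) || any(!is.finite(e_score))) {
    stop("scores must be finite", call. = FALSE)
  }
  structure(list(sequence = sequence, h_score = as.numeric(h_score),
                 e_score = as.numeric(e_score), n_res = n),
            class = "propensity_profile")
}

#' Windowed table propensities for a sequence
#'
#' Looks up each residue's helix/strand propensity in `table` and smooths
#' with a centered moving average of width `window` (shrinking to the
#' available residues at the chain ends). Window 1 returns the raw values.
#' `X` is accepted as unknown and scored 1.0 for both classes.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`.
#' @param table Data frame with columns `residue`, `helix`, `strand`
#'   (default [chou_fasman_table()]).
#' @param window Odd integer >= 1.
#' @return A [propensity_profile()].
#' @examples
#' table_propensity("MAEEV", window = 3)
#' @export
table_propensity <- function(sequence, table = chou_fasman_table(),
                             window = 5L) {
  sequence <- toupper(as.character(sequence))
  if (window < 1 || window %% 2 == 0) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, table$residue)
  unknown <- is.na(idx) & aa != "X"
  if (any(unknown)) {
    stop("invalid residue character(s): ",
         paste(unique(aa[unknown]), collapse = ", "), call. = FALSE)
  }
  h <- ifelse(is.na(idx), 1.0, table$helix[idx])
  e <- ifelse(is.na(idx), 1.0, table$strand[idx])
  half <- (window - 1) / 2
  smooth <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      lo <- max(1, i - half)
      hi <- min(n, i + half)
      mean(v[lo:hi])
    }, numeric(1))
  }
  propensity_profile(sequence, smooth(h), smooth(e))
}

#' Read a per-residue 3-class score table (.ss2 dialect)
#'
#' Parses the de facto layout of per-residue secondary-structure score
#' files: one row per residue with columns index, residue letter, label,
#' C-score, H-score, E-score; `#` comment lines and blank lines are
#' ignored.
#'
#' @param path File path.
#' @param sequence Optional reference sequence (e.g. from
#'   [read_protein_fasta()]); if given, residue letters are cross-checked
#'   and any mismatch raises an error naming the first offending position.
#' @return A [propensity_profile()] with `h_score`, `e_score` from the H and
#'   E columns.
#' @export
read_external_scores <- function(path, sequence = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  rows <- rows[vapply(rows, length, integer(1)) >= 6]
  if (length(rows) == 0L) stop("no score rows in ", path, call. = FALSE)
  res <- vapply(rows, `[`, character(1), 2)
  h <- as.numeric(vapply(rows, `[`, character(1), 5))
  e <- as.numeric(vapply(rows, `[`, character(1), 6))
  if (any(is.na(h)) || any(is.na(e))) {
    stop("non-numeric H/E score fields in ", path, call. = FALSE)
  }
  seq_file <- paste(res, collapse = "")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length(res)) {
      stop(sprintf("score table has %d residues but sequence has %d",
                   length(res), nchar(sequence)), call. = FALSE)
    }
    seq_chars <- strsplit(sequence, "")[[1]]
    bad <- which(toupper(res) != seq_chars)
    if (length(bad) > 0) {
      stop(sprintf(
        "score table residue '%s' disagrees with sequence residue '%s' at position %d",
        res[bad[1]], seq_chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  propensity_profile(seq_file, h, e)
}

#' Write a propensity profile in the .ss2-style layout
#'
#' Columns: index, residue, label (`C` placeholder), C-score (0), H-score,
#' E-score. Scores are written with 6 decimals.
#'
#' @param p A [propensity_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_external_scores <- function(p, path) {
  stopifnot(inherits(p, "propensity_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-residue secondary-structure scores (idx res label C H E)", con)
  aa <- strsplit(p$sequence, "")[[1]]
  writeLines(sprintf("%4d %s C   %.6f  %.6f  %.6f",
                     seq_len(p$n_res), aa, 0, p$h_score, p$e_score), con)
  invisible(path)
}
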