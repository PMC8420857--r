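#' Construct a CD spectrum
#'
#' A `cd_spectrum` holds per-mean-residue molar circular dichroism values
#' \eqn{\Delta\epsilon} (M\eqn{^{-1}} cm\eqn{^{-1}}) on a wavelength grid in
#' nanometres, plus acquisition metadata. Wavelengths are stored ascending
#' internally regardless of input order.
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly monotone,
#'   all within 160--320 nm, length >= 2. The grid may be irregular.
#' @param values Numeric vector of \eqn{\Delta\epsilon} values, same length
#'   as `wavelengths`, finite, `|value| < 100`.
#' @param meta Named list of metadata (e.g. `name`, `path_length_cm`,
#'   `concentration_mg_ml`, `mrw`, `n_accumulations`). Free-form.
#'
#' @return An object of class `cd_spectrum`: a list with elements
#'   `wavelengths`, `values`, `meta`.
#' @examples
#' s <- cd_spectrum(seq(175, 240), rep(0, 66), meta = list(name = "blank"))
#' range(s$wavelengths)
#' @export
cd_spectrum <- function(wavelengths, values, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  d <- diff(wavelengths)
  if (!all(d > 0) && !all(d < 0)) {
    stop("wavelengths must be strictly monotone", call. = FALSE)
  }
  if (any(wavelengths < 160 | wavelengths > 320)) {
    stop("wavelengths must lie within [160, 320] nm", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  if (any(abs(values) >= 100)) {
    stop("|delta epsilon| >= 100 M^-1 cm^-1 fails the sanity bound; check units",
         call. = FALSE)
  }
  if (all(d < 0)) { # store ascending
    wavelengths <- rev(wavelengths)
    values <- rev(values)
  }
  structure(list(wavelengths = wavelengths, values = values, meta = meta),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  nm <- x$meta$name %||% "<unnamed>"
  cat(sprintf("CD spectrum '%s': %d points, %.1f-%.1f nm, delta-epsilon in [%.3g, %.3g]\n",
              nm, length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$values), max(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize raw ellipticity to molar circular dichroism
#'
#' Converts an ellipticity series theta (millidegrees) into per-mean-residue
#' molar circular dichroism via the standard chain: mean-residue ellipticity
#' \eqn{[\theta] = \theta \cdot MRW / (10\, l\, c)} (deg cm\eqn{^2}
#' dmol\eqn{^{-1}}), then \eqn{\Delta\epsilon = [\theta]/3298}. Collapsed:
#' \deqn{\Delta\epsilon(\lambda) = \theta(\lambda) \cdot MRW /
#'   (32980\, l\, c)}
#' with path length `l` in cm and concentration `c` in mg/mL.
#'
#' @param wavelengths Wavelength grid (nm).
#' @param theta_mdeg Ellipticity values in millidegrees, same length.
#' @param path_length Optical path length in cm (e.g. 0.005 for a 50 um cell).
#' @param concentration Protein concentration in mg/mL.
#' @param mrw Mean residue weight in g/mol (molecular weight / residue count).
#' @param meta Extra metadata merged into the result's `meta`.
#'
#' @return A [cd_spectrum()] in \eqn{\Delta\epsilon} units; the conversion
#'   parameters are recorded in `meta`.
#' @examples
#' normalize_to_delta_epsilon(c(200, 222), c(5, -8),
#'   path_length = 0.005, concentration = 1.1, mrw = 110)
#' @export
normalize_to_delta_epsilon <- function(wavelengths, theta_mdeg, path_length,
                                       concentration, mrw, meta = list()) {
  if (!is.numeric(path_length) || length(path_length) != 1L || path_length <= 0) {
    stop("path_length must be a single positive number (cm)", call. = FALSE)
  }
  if (!is.numeric(concentration) || length(concentration) != 1L || concentration <= 0) {
    stop("concentration must be a single positive number (mg/mL)", call. = FALSE)
  }
  if (!is.numeric(mrw) || length(mrw) != 1L || mrw <= 0) {
    stop("mrw must be a single positive number (g/mol)", call. = FALSE)
  }
  de <- theta_mdeg * mrw / (32980 * path_length * concentration)
  meta <- utils::modifyList(
    list(path_length_cm = path_length, concentration_mg_ml = concentration,
         mrw = mrw, units = "delta_epsilon"),
    meta)
  cd_spectrum(wavelengths, de, meta = meta)
}

#' Protein concentration from absorbance at 280 nm
#'
#' Uses the E 1% convention: the absorbance of a 1% (10 mg/mL) solution in a
#' 1 cm cell. Concentration in mg/mL is
#' \deqn{c = 10 \cdot A_{280} / (E^{1\%}_{280} \cdot l).}
#'
#' @param a280 Absorbance at 280 nm (dimensionless, >= 0).
#' @param e1pct E 1% extinction coefficient ((mg/mL)\eqn{^{-1}} cm\eqn{^{-1}}
#'   times 10).
#' @param path_length Cuvette path length in cm (default 1).
#' @return Concentration in mg/mL.
#' @examples
#' concentration_from_absorbance(0.4114, e1pct = 3.74) # 1.1 mg/mL
#' @export
concentration_from_absorbance <- function(a280, e1pct, path_length = 1) {
  if (!is.numeric(e1pct) || length(e1pct) != 1L || e1pct <= 0) {
    stop("e1pct must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(path_length) || length(path_length) != 1L || path_length <= 0) {
    stop("path_length must be a single positive number (cm)", call. = FALSE)
  }
  if (any(a280 < 0)) stop("a280 must be non-negative", call. = FALSE)
  10 * a280 / (e1pct * path_length)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`, which must lie within the span of the
#' spectrum's own wavelengths (no extrapolation). Metadata are preserved.
#'
#' @param s A [cd_spectrum()].
#' @param grid Target wavelengths (nm), strictly monotone.
#' @return A [cd_spectrum()] on `grid`.
#' @examples
#' s <- cd_spectrum(c(175, 185), c(0, 10))
#' resample_to_grid(s, c(175, 180, 185))$values
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "cd_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(s$wavelengths) - 1e-9 ||
      max(grid) > max(s$wavelengths) + 1e-9) {
    stop(sprintf(
      "grid [%.3f, %.3f] nm extends beyond the spectrum span [%.3f, %.3f] nm",
      min(grid), max(grid), min(s$wavelengths), max(s$wavelengths)),
      call. = FALSE)
  }
  v <- stats::approx(s$wavelengths, s$values, xout = grid, rule = 1)$y
  cd_spectrum(grid, v, meta = s$meta)
}

#' Default shared analysis grid
#'
#' 1 nm spacing over the analysis window (default 175--240 nm, the range
#' where helix/strand/coil bands discriminate best and where VUVCD data are
#' routinely available).
#'
#' @param range_nm Length-2 numeric, inclusive window in nm.
#' @param step Grid spacing in nm.
#' @return Numeric vector of wavelengths.
#' @export
analysis_grid <- function(range_nm = c(175, 240), step = 1) {
  seq(range_nm[1], range_nm[2], by = step)
}

#' Read a CD spectrum from a two-column text file
#'
#' The format is whitespace- or tab-separated `wavelength value` lines, with
#' optional header lines starting with `#` carrying `key value` metadata
#' pairs (recognized keys: `name`, `path_length_cm`, `concentration_mg_ml`,
#' `mrw`, `units`, `n_accumulations`). If `units` is `mdeg` the values are
#' normalized to \eqn{\Delta\epsilon} using the metadata; the default is
#' `delta_epsilon`.
#'
#' @param path File path.
#' @return A [cd_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^\\s*#\\s*", "", h), "\\s+")[[1]]
    if (length(kv) >= 2) {
      val <- paste(kv[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      meta[[kv[1]]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x) {
    as.numeric(x[1:2])
  }))
  units <- meta$units %||% "delta_epsilon"
  if (identical(units, "mdeg")) {
    for (k in c("path_length_cm", "concentration_mg_ml", "mrw")) {
      if (is.null(meta[[k]])) {
        stop(sprintf("units=mdeg requires metadata key '%s'", k), call. = FALSE)
      }
    }
    normalize_to_delta_epsilon(m[, 1], m[, 2], meta$path_length_cm,
                               meta$concentration_mg_ml, meta$mrw, meta = meta)
  } else {
    cd_spectrum(m[, 1], m[, 2], meta = meta)
  }
}

#' Write a CD spectrum to a two-column text file
#'
#' @param s A [cd_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_spectrum()]
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "cd_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(s$meta)) {
    v <- s$meta[[k]]
    if (is.numeric(v)) v <- format(v, digits = 17)
    writeLines(sprintf("# %s %s", k, v), con)
  }
  writeLines(sprintf("%.6f\t%s", s$wavelengths, format(s$values, digits = 17,
                                                       scientific = FALSE,
                                                       trim = TRUE)), con)
  invisible(path)
}

#' Read an amino-acid sequence from a FASTA file
#'
#' @param path FASTA file (single or multiple records).
#' @param id Optional record name; by default the first record is used.
#' @return A single character string (one-letter amino-acid codes).
#' @export
read_protein_fasta <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (!is.null(id)) {
    hit <- which(vapply(names(set), function(n) {
      strsplit(n, "\\s+")[[1]][1] == id
    }, logical(1)))
    if (length(hit) == 0L) stop("no FASTA record named '", id, "'", call. = FALSE)
    set <- set[hit[1]]
  }
  as.character(set[[1]])
}
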