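# Shared helpers: independent oracles and small constructors used across
# test files. Everything here is deliberately written by a different route
# than the package code it checks.

# assignment_targets directly from a label string's own counts
targets_from_labels <- function(labels) {
  lab <- strsplit(labels, "")[[1]]
  n <- length(lab)
  runs <- function(cls) {
    r <- rle(lab == cls)
    sum(r$values)
  }
  structure(list(n_h_residues = sum(lab == "H"), n_e_residues = sum(lab == "E"),
                 n_h_segments = runs("H"), n_e_segments = runs("E"),
                 n_res = n, adjusted = FALSE),
            class = "assignment_targets")
}

make_targets <- function(rh, re, kh, ke, n) {
  structure(list(n_h_residues = rh, n_e_residues = re,
                 n_h_segments = kh, n_e_segments = ke,
                 n_res = n, adjusted = FALSE),
            class = "assignment_targets")
}

# independent recount of an assignment (simple loop, no rle)
recount_labels <- function(labels) {
  lab <- strsplit(labels, "")[[1]]
  nh <- ne <- sh <- se <- 0L
  prev <- "C"
  for (x in lab) {
    if (x == "H") { nh <- nh + 1L; if (prev != "H") sh <- sh + 1L }
    if (x == "E") { ne <- ne + 1L; if (prev != "E") se <- se + 1L }
    prev <- x
  }
  c(n_h = nh, n_e = ne, seg_h = sh, seg_e = se)
}

# brute-force enumeration oracle: per-n cache of the count tuples of all
# 3^n labelings (0 = C, 1 = H, 2 = E)
.tuple_cache <- new.env(parent = emptyenv())

enumerate_tuples <- function(n) {
  key <- as.character(n)
  if (!is.null(.tuple_cache[[key]])) return(.tuple_cache[[key]])
  m <- as.matrix(expand.grid(rep(list(0:2), n), KEEP.OUT.ATTRS = FALSE))
  is_h <- m == 1L
  is_e <- m == 2L
  seg_count <- function(x) {
    s <- x[, 1, drop = FALSE]
    if (n > 1) {
      s <- cbind(s, x[, 2:n, drop = FALSE] & !x[, 1:(n - 1), drop = FALSE])
    }
    rowSums(s)
  }
  out <- cbind(n_h = rowSums(is_h), n_e = rowSums(is_e),
               seg_h = seg_count(is_h), seg_e = seg_count(is_e))
  .tuple_cache[[key]] <- out
  out
}

brute_min_discrepancy <- function(t, lambda = 1) {
  tup <- enumerate_tuples(t$n_res)
  min(abs(tup[, "n_h"] - t$n_h_residues) + abs(tup[, "n_e"] - t$n_e_residues) +
        lambda * (abs(tup[, "seg_h"] - t$n_h_segments) +
                    abs(tup[, "seg_e"] - t$n_e_segments)))
}

# a standard small noiseless synthetic world shared by several tests
test_basis <- function() make_basis_spectra(analysis_grid())
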