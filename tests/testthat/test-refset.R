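test_that("fraction vectors enforce the cleanup and floor invariants", {
  f <- fraction_vector(0.067, 0.104, 0.159, 0.113, 0.25, 0.307)
  expect_s3_class(f, "fraction_vector")
  expect_equal(sum(f), 1)

  expect_error(fraction_vector(0.5, 0.6, 0, 0, 0, 0), "sum")
  expect_error(fraction_vector(-0.01, 0.4, 0.2, 0.1, 0.1, 0.21), "\\[0, 1\\]")
  # raw (pre-cleanup) solutions may dip to the -0.025 floor but not below
  expect_silent(vuvcd:::validate_fractions(
    c(-0.02, 0.4, 0.2, 0.1, 0.1, 0.2), clean = FALSE))
  expect_error(vuvcd:::validate_fractions(
    c(-0.05, 0.4, 0.2, 0.1, 0.1, 0.2), clean = FALSE), "floor")

  cl <- cleanup_fractions(c(-0.02, 0.42, 0.2, 0.1, 0.1, 0.2))
  expect_equal(sum(cl), 1)
  expect_true(all(cl >= 0))
  expect_equal(as.numeric(cl)[1], 0)
})

test_that("reference sets require 6 members and share a grid", {
  basis <- test_basis()
  rs <- make_reference_set(8, basis, noise_sigma = 0, seed = 11)
  expect_error(reference_set(rs$proteins[1:5]), "at least 6")
  m <- build_matrices(rs)
  expect_equal(dim(m$spectra), c(length(rs$grid), 8))
  expect_equal(dim(m$fractions), c(6, 8))

  # permuting members permutes columns of both tables identically
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  m2 <- build_matrices(reference_set(rs$proteins[perm], grid = rs$grid))
  expect_equal(m2$spectra, m$spectra[, perm])
  expect_equal(m2$fractions, m$fractions[, perm])
})

test_that("reference sets round-trip through the manifest format", {
  rs <- make_reference_set(7, test_basis(), noise_sigma = 0.01, seed = 5)
  dir <- withr::local_tempdir()
  write_reference_set(rs, dir)
  rs2 <- read_reference_set(dir)
  m1 <- build_matrices(rs)
  m2 <- build_matrices(rs2)
  expect_equal(m2$spectra, m1$spectra, tolerance = 1e-12)
  expect_equal(m2$fractions, m1$fractions, tolerance = 1e-12)
  expect_equal(vapply(rs2$proteins, `[[`, integer(1), "n_res"),
               vapply(rs$proteins, `[[`, integer(1), "n_res"))
})

test_that("leave-one-out on an exact-basis set reaches the noiseless limit", {
  rs <- make_reference_set(12, test_basis(), noise_sigma = 0, seed = 42)
  ev <- loo_evaluate(rs)
  expect_lte(ev$delta, 0.01)
  expect_gt(ev$r, 0.95)
  expect_false(ev$degenerate_correlation)
  expect_error(loo_evaluate(reference_set(rs$proteins[1:6], grid = rs$grid)),
               "at least 7")
})

test_that("identical-fraction sets flag the degenerate correlation", {
  basis <- test_basis()
  f <- c(h_r = 0.12, h_d = 0.08, s_r = 0.11, s_d = 0.09, turn = 0.2,
         unordered = 0.4)
  prot <- lapply(1:8, function(i) {
    reference_protein(paste0("same", i),
                      make_query_spectrum(f, basis, noise_sigma = 0.01,
                                          seed = i),
                      f, 100 + i)
  })
  rs <- reference_set(prot, grid = basis$grid)
  ev <- suppressWarnings(loo_evaluate(rs))
  expect_true(ev$degenerate_correlation)
  expect_true(is.na(ev$r))
})

test_that("LOO error grows with spectral noise in expectation", {
  basis <- test_basis()
  # well-separated levels so the expectation trend dominates seed noise
  levels <- c(0, 0.02, 0.05)
  mean_delta <- vapply(levels, function(sig) {
    deltas <- vapply(1:10, function(seed) {
      rs <- make_reference_set(12, basis, noise_sigma = sig, seed = seed)
      suppressWarnings(loo_evaluate(rs)$delta)
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  expect_true(all(diff(mean_delta) >= 0))
})
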