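test_that("cd_spectrum enforces its invariants and normalizes ordering", {
  s <- cd_spectrum(c(240, 200, 175), c(1, -2, 3))
  expect_true(all(diff(s$wavelengths) > 0)) # stored ascending
  expect_equal(s$values, c(3, -2, 1))       # values follow the reordering

  expect_error(cd_spectrum(c(175, 175, 180), c(1, 2, 3)), "monotone")
  expect_error(cd_spectrum(c(150, 200), c(1, 1)), "160")
  expect_error(cd_spectrum(c(175, 200), c(1, NaN)), "finite")
  expect_error(cd_spectrum(c(175, 200), c(1, 150)), "sanity")
  expect_error(cd_spectrum(175, 1), "at least 2")
  expect_error(cd_spectrum(c(175, 200), c(1, 2, 3)), "equal length")
})

test_that("ellipticity normalization matches an independent unit conversion", {
  # hand conversion: [theta]_MRE = theta * MRW / (10 * l * c) deg cm^2/dmol,
  # delta-eps = [theta]/3298; theta = 10 mdeg, MRW 110, l 50 um, c 1.1 mg/mL
  mre <- 10 * 110 / (10 * 0.005 * 1.1)
  expected <- mre / 3298
  s <- normalize_to_delta_epsilon(c(200, 222), c(10, 10),
                                  path_length = 0.005, concentration = 1.1,
                                  mrw = 110)
  expect_equal(s$values, rep(expected, 2), tolerance = 1e-12)

  # zero signal stays zero
  z <- normalize_to_delta_epsilon(c(200, 222), c(0, 0), 0.005, 1.1, 110)
  expect_equal(z$values, c(0, 0))

  # linear in theta, inversely linear in path and concentration
  s1 <- normalize_to_delta_epsilon(c(200, 222), c(4, -6), 0.005, 1.1, 110)
  s2 <- normalize_to_delta_epsilon(c(200, 222), 2 * c(4, -6), 0.005, 1.1, 110)
  s3 <- normalize_to_delta_epsilon(c(200, 222), c(4, -6), 0.005, 2.2, 110)
  s4 <- normalize_to_delta_epsilon(c(200, 222), c(4, -6), 0.010, 1.1, 110)
  expect_equal(s2$values, 2 * s1$values)
  expect_equal(s3$values, s1$values / 2)
  expect_equal(s4$values, s1$values / 2)

  expect_error(normalize_to_delta_epsilon(c(200, 222), c(1, 1), -1, 1, 110),
               "path_length")
  expect_error(normalize_to_delta_epsilon(c(200, 222), c(1, 1), 1, 0, 110),
               "concentration")
})

test_that("concentration from A280 follows the E 1% convention both ways", {
  expect_equal(concentration_from_absorbance(0, 3.74), 0)
  # algebraic inversion: a280 such that c = 1.1 mg/mL at E1% = 3.74
  expect_equal(concentration_from_absorbance(0.4114, 3.74), 1.1,
               tolerance = 1e-12)
  # isolated-tag coefficient: 0.1194 absorbance -> 0.6 mg/mL stock
  expect_equal(concentration_from_absorbance(0.1194, 1.99), 0.6,
               tolerance = 1e-12)
  expect_error(concentration_from_absorbance(0.5, -1), "e1pct")
  expect_error(concentration_from_absorbance(-0.1, 3.74), "non-negative")
})

test_that("resampling interpolates linearly and refuses to extrapolate", {
  s <- cd_spectrum(c(175, 185), c(0, 10))
  expect_equal(resample_to_grid(s, c(175, 180, 185))$values, c(0, 5, 10))

  # identity on own grid
  r <- cd_spectrum(seq(175, 240, 5), sin(seq(175, 240, 5) / 10))
  expect_equal(resample_to_grid(r, r$wavelengths)$values, r$values)

  # piecewise-linear functions are recovered exactly after refine + restrict
  pw <- cd_spectrum(seq(175, 240, 5), c(seq(0, 6, length.out = 7),
                                        seq(5, 0, length.out = 7)))
  fine <- resample_to_grid(pw, seq(175, 240, 1))
  back <- resample_to_grid(fine, pw$wavelengths)
  expect_equal(back$values, pw$values, tolerance = 1e-12)

  # idempotent on its own output grid
  again <- resample_to_grid(fine, fine$wavelengths)
  expect_identical(again$values, fine$values)

  expect_error(resample_to_grid(s, c(170, 180)), "beyond")
})

test_that("spectrum files round-trip with metadata, including mdeg units", {
  s <- cd_spectrum(seq(175, 240), sin(seq(175, 240) / 9),
                   meta = list(name = "probe", mrw = 110.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_equal(s2$meta$name, "probe")
  expect_equal(s2$meta$mrw, 110.5)

  # a raw-ellipticity file is normalized on read
  lines <- c("# units mdeg", "# path_length_cm 0.005",
             "# concentration_mg_ml 1.1", "# mrw 110",
             "200\t10", "222\t-5")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, p2)
  s3 <- read_spectrum(p2)
  expect_equal(s3$values[1], 10 * 110 / (32980 * 0.005 * 1.1))
})

test_that("FASTA reading picks the first or a named record", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one desc", "MAEEV", ">two", "GGHHKL"), p)
  expect_equal(read_protein_fasta(p), "MAEEV")
  expect_equal(read_protein_fasta(p, id = "two"), "GGHHKL")
  expect_error(read_protein_fasta(p, id = "zzz"), "no FASTA record")
})
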