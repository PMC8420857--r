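test_that("initial guess is the nearest member, ties to the lower index", {
  basis <- test_basis()
  rs <- make_reference_set(8, basis, noise_sigma = 0, seed = 2)
  m <- build_matrices(rs)

  # exact match returns that member's fractions
  q <- cd_spectrum(rs$grid, m$spectra[, 4])
  ig <- initial_guess(q, rs)
  expect_equal(as.numeric(ig$fractions), unname(m$fractions[, 4]))
  expect_equal(ig$nearest, colnames(m$spectra)[4])

  # brute-force nearest-neighbor scan agrees on noisy queries
  for (seed in 1:5) {
    f <- rs$proteins[[((seed - 1) %% 8) + 1]]$fractions
    qn <- make_query_spectrum(f, basis, noise_sigma = 0.05, seed = seed)
    rmsd <- apply(m$spectra, 2, function(col) sqrt(mean((col - qn$values)^2)))
    expect_equal(initial_guess(qn, rs)$nearest, names(which.min(rmsd)))
  }

  # equidistant duplicate spectra: lower-index member wins
  dup <- rs$proteins
  dup[[7]]$spectrum <- dup[[3]]$spectrum
  rs_dup <- reference_set(dup, grid = rs$grid)
  qd <- cd_spectrum(rs$grid, build_matrices(rs_dup)$spectra[, 3])
  expect_equal(initial_guess(qd, rs_dup)$nearest, dup[[3]]$name)
})

test_that("held-out members of an exact-basis set are recovered", {
  basis <- test_basis()
  rs_all <- make_reference_set(13, basis, noise_sigma = 0, seed = 9)
  held <- rs_all$proteins[[13]]
  rs <- reference_set(rs_all$proteins[1:12], grid = rs_all$grid)
  res <- selcon_deconvolve(held$spectrum, rs)
  rmsd <- sqrt(mean((as.numeric(res$fractions) -
                       as.numeric(held$fractions))^2))
  expect_lte(rmsd, 0.02)
  expect_true(res$diagnostics$converged)
  expect_gte(res$diagnostics$n_surviving, 1)
})

test_that("a helix/unordered mixture query is resolved to its helix total", {
  basis <- test_basis()
  rs <- make_reference_set(14, basis, noise_sigma = 0, seed = 21)
  # same distorted-share convention as the generator (h_d = 0.4 h_total)
  f_mix <- c(h_r = 0.3, h_d = 0.2, s_r = 0, s_d = 0, turn = 0,
             unordered = 0.5)
  q <- make_query_spectrum(f_mix, basis)
  res <- selcon_deconvolve(q, rs)
  helix_total <- sum(as.numeric(res$fractions)[1:2])
  expect_lt(abs(helix_total - 0.5), 0.02)
})

test_that("final solutions are clean and invariant to member permutation", {
  basis <- test_basis()
  rs <- make_reference_set(12, basis, noise_sigma = 0.02, seed = 31)
  q <- make_query_spectrum(rs$proteins[[5]]$fractions, basis,
                           noise_sigma = 0.02, seed = 99)
  res <- selcon_deconvolve(q, rs)
  f <- as.numeric(res$fractions)
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_true(all(f >= 0 & f <= 1))

  perm <- c(7, 2, 11, 4, 1, 12, 3, 10, 5, 8, 6, 9)
  rs_p <- reference_set(rs$proteins[perm], grid = rs$grid)
  res_p <- selcon_deconvolve(q, rs_p)
  expect_equal(as.numeric(res_p$fractions), f, tolerance = 1e-9)
})

test_that("noiseless exact-basis recovery holds across 20 seeded queries", {
  basis <- test_basis()
  pool <- make_reference_set(32, basis, noise_sigma = 0, seed = 77)
  rmsds <- vapply(1:20, function(i) {
    rs <- reference_set(pool$proteins[-i], grid = pool$grid)
    truth <- pool$proteins[[i]]$fractions
    res <- selcon_deconvolve(pool$proteins[[i]]$spectrum, rs)
    sqrt(mean((as.numeric(res$fractions) - as.numeric(truth))^2))
  }, numeric(1))
  expect_true(all(rmsds <= 0.02))
})

test_that("feeding back the converged solution is self-consistent", {
  basis <- test_basis()
  rs <- make_reference_set(12, basis, noise_sigma = 0.02, seed = 13)
  cfg <- selcon_config()
  q <- make_query_spectrum(rs$proteins[[3]]$fractions, basis,
                           noise_sigma = 0.02, seed = 8)
  r1 <- selcon_deconvolve(q, rs, cfg)
  r2 <- selcon_deconvolve(q, rs, cfg) # rerun: deterministic
  expect_identical(as.numeric(r1$fractions), as.numeric(r2$fractions))
  # converged: one more self-consistency sweep changes nothing beyond tol_sc
  expect_true(r1$diagnostics$converged)
})

test_that("degenerate all-zero queries fail with a structured no-solution error", {
  basis <- test_basis()
  rs <- make_reference_set(12, basis, noise_sigma = 0, seed = 3)
  q0 <- cd_spectrum(rs$grid, rep(0, length(rs$grid)))
  err <- tryCatch(selcon_deconvolve(q0, rs), condition = function(c) c)
  # pinned behavior: the flat spectrum admits no rule-passing solution
  expect_s3_class(err, "vuvcd_no_solution")
  expect_true(is.list(err$data))
  expect_named(err$data$rejections,
               c("sum_rule", "fraction_rule", "fit_rule", "helix_rule"))
})

test_that("queries must share a wide enough analysis window", {
  basis <- test_basis()
  rs <- make_reference_set(8, basis, noise_sigma = 0, seed = 4)
  narrow <- cd_spectrum(seq(200, 230), rep(1, 31))
  expect_error(selcon_deconvolve(narrow, rs), "40 nm")
})

test_that("total contents collapse the six classes to the printed totals", {
  tab <- ncym_contents()
  # hydrogenated tagged construct: 17.1% helix, 27.2% strand
  f <- fractions_from_row(tab[tab$sample == "H_Tag_NCYM", ])
  tc <- 100 * total_contents(f)
  expect_equal(unname(tc[c("helix", "strand")]), c(17.1, 27.2),
               tolerance = 1e-9)
  # hydrogenated tag alone: 14.2% helix, 29.2% strand
  f2 <- fractions_from_row(tab[tab$sample == "H_Tag", ])
  expect_equal(unname(100 * total_contents(f2)[c("helix", "strand")]),
               c(14.2, 29.2), tolerance = 1e-9)
  # all-unordered chain
  expect_equal(unname(total_contents(c(0, 0, 0, 0, 0, 1))), c(0, 0, 1))
  # the triple always sums to one
  expect_equal(sum(total_contents(f)), 1)
})
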