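test_that("targets derive from contents and segments, with feasibility repair", {
  # printed tagged-construct row: helix 17.1%, strand 27.2% of 238 residues
  tab <- ncym_contents()
  row <- tab[tab$sample == "H_Tag_NCYM", ]
  f <- fractions_from_row(row)
  seg <- estimate_segments(f, row$n_res)
  t <- targets_from_vuvcd(f, seg, row$n_res)
  # independent arithmetic: 0.171*238 = 40.698 -> 41; 0.272*238 = 64.736 -> 65
  expect_identical(t$n_h_residues, 41L)
  expect_identical(t$n_e_residues, 65L)
  expect_identical(t$n_h_segments, 6L)
  expect_identical(t$n_e_segments, 13L)
  expect_false(t$adjusted)

  # zero fractions give all-zero targets
  f0 <- fraction_vector(0, 0, 0, 0, 0.5, 0.5)
  t0 <- targets_from_vuvcd(f0, estimate_segments(f0, 50), 50)
  expect_identical(c(t0$n_h_residues, t0$n_e_residues,
                     t0$n_h_segments, t0$n_e_segments), rep(0L, 4))

  # other = 0 on a 10-residue chain: rounding kept feasible, n_h + n_e = 10
  f1 <- fraction_vector(0.33, 0.22, 0.25, 0.20, 0, 0)
  t1 <- suppressWarnings(targets_from_vuvcd(f1, estimate_segments(f1, 10), 10))
  expect_identical(t1$n_h_residues + t1$n_e_residues, 10L)
  expect_true(vuvcd:::is_feasible_tuple(t1$n_h_residues, t1$n_e_residues,
                                        t1$n_h_segments, t1$n_e_segments, 10))
})

test_that("the feasibility characterization matches exhaustive enumeration", {
  # ground truth: which (r_h, r_e, k_h, k_e) tuples occur among all 3^n strings
  for (n in c(4, 6)) {
    tup <- enumerate_tuples(n)
    seen <- unique(as.data.frame(tup))
    all_tuples <- expand.grid(r_h = 0:n, r_e = 0:n, k_h = 0:n, k_e = 0:n)
    pred <- mapply(vuvcd:::is_feasible_tuple, all_tuples$r_h, all_tuples$r_e,
                   all_tuples$k_h, all_tuples$k_e, MoreArgs = list(n = n))
    truth <- mapply(function(rh, re, kh, ke) {
      any(seen$n_h == rh & seen$n_e == re & seen$seg_h == kh & seen$seg_e == ke)
    }, all_tuples$r_h, all_tuples$r_e, all_tuples$k_h, all_tuples$k_e)
    expect_identical(unname(pred), unname(truth), label = paste("n =", n))
  }
})

test_that("all-zero targets yield an all-C assignment", {
  p <- propensity_profile(strrep("A", 15), rnorm(15), rnorm(15))
  t <- make_targets(0L, 0L, 0L, 0L, 15L)
  a <- constrained_assign(p, t)
  expect_equal(a$labels, strrep("C", 15))
  expect_equal(a$provenance$discrepancy, 0)
})

test_that("assignment discrepancy equals the exhaustive-search minimum", {
  set.seed(2024)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    t <- make_targets(sample(0:n, 1), sample(0:n, 1),
                      sample(0:5, 1), sample(0:5, 1), n)
    p <- propensity_profile(strrep("A", n), rnorm(n), rnorm(n))
    a <- constrained_assign(p, t)
    expect_equal(a$provenance$discrepancy, brute_min_discrepancy(t),
                 label = sprintf("instance %d (n=%d)", i, n))
    # the reported discrepancy is honest: recount independently
    tup <- recount_labels(a$labels)
    expect_equal(discrepancy(a, t), a$provenance$discrepancy)
    expect_equal(unname(tup), unname(vuvcd:::label_tuple(a$labels)))
  }
})

test_that("feasible targets are met exactly and planted truths recovered", {
  for (seed in 1:20) {
    lab <- random_labels(80, 20, 16, seed = seed)
    t <- targets_from_labels(lab)
    # margin far above noise: exact label recovery
    p <- make_planted_profile(lab, margin = 2, noise_sigma = 0.1, seed = seed)
    a <- constrained_assign(p, t)
    expect_identical(a$labels, lab, label = paste("seed", seed))
    expect_identical(a$provenance$discrepancy, 0)
  }
})

test_that("reconciliation never regresses below the greedy phase", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    lab <- random_labels(n, sample(0:(n %/% 3), 1), sample(0:(n %/% 3), 1),
                        seed = i)
    t <- targets_from_labels(lab)
    p <- propensity_profile(strrep("A", n), rnorm(n), rnorm(n))
    a <- constrained_assign(p, t)
    expect_lte(a$provenance$discrepancy, a$provenance$phase1_discrepancy)
  }
})

test_that("assignment is deterministic", {
  lab <- random_labels(50, 12, 10, seed = 1)
  t <- targets_from_labels(lab)
  p <- make_planted_profile(lab, margin = 0.5, noise_sigma = 0.5, seed = 2)
  a1 <- constrained_assign(p, t)
  a2 <- constrained_assign(p, t)
  expect_identical(a1$labels, a2$labels)
})

test_that("margin-zero profiles recover at chance level only", {
  hits <- vapply(1:20, function(seed) {
    lab <- random_labels(60, 15, 15, seed = seed)
    t <- targets_from_labels(lab)
    p <- make_planted_profile(lab, margin = 0, noise_sigma = 1, seed = seed + 100)
    a <- constrained_assign(p, t)
    mean(strsplit(a$labels, "")[[1]] == strsplit(lab, "")[[1]])
  }, numeric(1))
  # with 15/15/30 class counts, chance agreement is ~37.5%; the constraint
  # machinery adds a little structure but must stay far from recovery
  expect_gt(mean(hits), 0.2)
  expect_lt(mean(hits), 0.75)
})

test_that("assignment diffs report exactly the planted positions", {
  a <- "CCHHHHCEECC"
  expect_equal(nrow(diff_assignments(a, a)), 0)

  b <- "CCHHHHCEHCC" # one planted difference at position 9 (E vs H)
  d <- diff_assignments(a, b)
  expect_equal(d$position, 9)
  expect_equal(d$label_a, "E")
  expect_equal(d$label_b, "H")

  set.seed(5)
  lab <- strsplit(random_labels(40, 10, 8, seed = 6), "")[[1]]
  lab2 <- lab
  planted <- c(3, 17, 30)
  lab2[planted] <- vapply(lab[planted],
                          function(x) setdiff(c("H", "E", "C"), x)[1], "")
  d2 <- diff_assignments(paste(lab, collapse = ""), paste(lab2, collapse = ""))
  expect_equal(d2$position, planted)

  # offset maps construct numbering to untagged-protein numbering
  d3 <- diff_assignments(strrep("C", 238),
                         paste0(strrep("C", 218), "H", strrep("C", 19)),
                         offset = 129)
  expect_equal(d3$position, 219)
  expect_equal(d3$protein_position, 90)

  expect_error(diff_assignments("HC", "HCE"), "length")
})

test_that("region summaries count clipped runs once", {
  a <- "CCHHHHCEEC"
  r <- region_summary(a, c(3, 8))
  expect_equal(r$helix_segments, 1)
  expect_equal(r$strand_segments, 1)
  expect_equal(r$n_h_residues, 4)
  expect_equal(r$n_e_residues, 1)

  whole <- region_summary(a, c(1, 10))
  expect_equal(whole$helix_segments, 1)
  expect_equal(whole$strand_segments, 1)

  none <- region_summary(a, c(1, 2))
  expect_equal(none$helix_segments, 0)
  expect_equal(none$strand_segments, 0)

  expect_error(region_summary(a, c(0, 5)), "invalid range")
  expect_error(region_summary(a, c(8, 3)), "invalid range")
})

test_that("assignments write a string file and TSV", {
  a <- ss_assignment("CHHEC")
  base <- withr::local_tempfile()
  paths <- write_assignment(a, base, sequence = "MAEEV", name = "demo")
  expect_true(all(file.exists(paths)))
  lines <- readLines(paths[1])
  expect_equal(lines[2], "CHHEC")
  tsv <- read.delim(paths[2])
  expect_equal(tsv$label, c("C", "H", "H", "E", "C"))
  expect_equal(tsv$residue, c("M", "A", "E", "E", "V"))
})
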