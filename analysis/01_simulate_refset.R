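#!/usr/bin/env Rscript
# Build the synthetic study world: six Gaussian-band basis spectra, a
# 31-protein reference set at 2% spectral noise (the working stand-in for a
# measured VUVCD reference database), and one held-out query protein with
# known fractions. Everything is written under results/world/ in the same
# text formats the pipeline reads back.

suppressPackageStartupMessages(library(vuvcd))
seed <- 2026

basis <- make_basis_spectra()
pool <- make_reference_set(31, basis, noise_sigma = 0.02, seed = seed)

query <- pool$proteins[[31]]
refset <- reference_set(pool$proteins[1:30], grid = pool$grid)

dir.create("results/world", showWarnings = FALSE, recursive = TRUE)
write_reference_set(refset, "results/world/refset")
write_spectrum(query$spectrum, "results/world/query.cd.tsv")
utils::write.table(
  data.frame(class = names(query$fractions),
             true_fraction = as.numeric(query$fractions)),
  "results/world/query_true_fractions.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("reference set: %d proteins on %d-point grid (%g-%g nm)\n",
            length(refset), length(refset$grid), min(refset$grid),
            max(refset$grid)))
cat(sprintf("held-out query '%s': %d residues, true helix %.1f%%, strand %.1f%%\n",
            query$name, query$n_res,
            100 * sum(query$fractions[1:2]), 100 * sum(query$fractions[3:4])))
cat("wrote results/world/\n")
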