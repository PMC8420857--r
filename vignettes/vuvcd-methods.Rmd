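---
title: "Methods: from CD spectra to per-residue secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from CD spectra to per-residue secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vuvcd)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what its synthetic benchmarks do and do not
show about measured data.

## The inference problem

Circular dichroism (CD) spectroscopy measures the differential absorption of
left- and right-circularly polarized light by a protein solution. In the
far- and vacuum-UV range (here 175–240 nm), the CD signal is dominated by
the peptide backbone and is strongly shaped by secondary structure:
\alpha-helices produce a positive band near 192 nm and negative bands near
208 and 222 nm, \beta-strands a positive band near 198 nm and a negative
band near 216 nm, and unordered chains a deep negative band near 198 nm.
Synchrotron vacuum-UV CD (VUVCD) extends the accessible range below 190 nm,
which adds enough information to resolve more than the classic three
classes.

The package infers, from one query spectrum:

1. **Contents** — six secondary-structure fractions: ordered and distorted
   \alpha-helix $h_r, h_d$, ordered and distorted \beta-strand $s_r, s_d$,
   turn, and unordered. "Distorted" residues are the terminal/irregular
   residues of a segment.
2. **Segment numbers** — how many helix and strand segments the chain
   contains.
3. **Positions** — a per-residue H/E/C labeling consistent with 1 and 2,
   guided by per-residue propensity scores.

## Units

Spectra are handled as molar circular dichroism per mean residue,
$\Delta\epsilon$ (M$^{-1}$ cm$^{-1}$). Raw ellipticity $\theta$ in
millidegrees converts through the mean-residue ellipticity
$[\theta] = \theta \cdot \mathrm{MRW} / (10\, l\, c)$ and
$\Delta\epsilon = [\theta] / 3298$, collapsed in
`normalize_to_delta_epsilon()` to
$\Delta\epsilon = \theta\,\mathrm{MRW} / (32980\, l\, c)$ with the path
length $l$ in cm and the mass concentration $c$ in mg/mL. Concentrations
follow the E 1% convention, $c = 10 A_{280} / (E^{1\%}_{280}\, l)$.

## Self-consistent SVD deconvolution

`selcon_deconvolve()` implements the SELCON3-style scheme. Let $C$ be the
$m \times n$ matrix of reference spectra on the shared grid and $F$ the
$6 \times n$ matrix of their known fractions. The query spectrum $c$ is
prepended as column 1 of $A = [c\,|\,C]$ and the current guess $f$ (initially
the fractions of the reference protein nearest to the query in spectral
RMSD) as column 1 of $F_x = [f\,|\,F]$. With the SVD $A = U S V^\top$, the
rank-$k$ solution for the query's fractions is the projection

$$ f^{(k)} = F_x V_k V_k^\top e_1 , $$

the reconstruction of the fractions matrix's first column in the rank-$k$
spectral row space. The guess is replaced by $f^{(K)}$ (the highest rank
considered) and the procedure repeats until no class changes by more than
`tol_sc`. At convergence the candidates $f^{(1)}, \dots, f^{(K)}$ are
filtered by four selection rules, and the survivors are averaged, clipped to
non-negative values, and renormalized to sum to 1.

Two implementation details are the package's own choices:

* **Rank cap.** $K$ is `k_max` capped at the numerical rank of $A$
  (singular values above $10^{-8}$ of the largest). On noise-free synthetic
  sets the spectra matrix is exactly low-rank, and the discarded components
  are numerically arbitrary null-space directions; projecting onto them
  produces meaningless "solutions" that would corrupt the candidate pool
  and the helix-stability anchor.
* **Guess renormalization.** Every reference column of $F_x$ sums to 1, so
  the prepended guess is renormalized to sum to 1 each iteration. Without
  this, the projection's shrinkage of the query coefficient feeds back into
  the iteration and systematically deflates all candidate sums, pushing
  borderline (noisy) queries below the sum rule for no physical reason. A
  degenerate near-zero guess falls back to uniform fractions.

### Selection rules and defaults

| rule | survives if | default |
|------|-------------|---------|
| sum rule | $\sum_j f^{(k)}_j \in [1 - \texttt{tol\_sum},\, 1 + \texttt{tol\_sum}]$ | `tol_sum = 0.05` |
| fraction rule | every $f^{(k)}_j \ge$ `frac_floor` | `frac_floor = -0.025` |
| spectral fit | RMSD(rank-$k$ reconstruction, measured query) $\le$ `fit_max` | `fit_max = 0.25` $\Delta\epsilon$ |
| helix stability | helix total within `helix_tol` of the converged rank-$K$ solution | `helix_tol = 0.03` |

Other knobs: `tol_sc = 1e-3` (self-consistency), `max_iter = 100`,
`k_max = 8`, analysis window 175–240 nm (1 nm grid) intersected with the
available data; a query must share at least 40 nm of window with the
reference set. The slightly negative `frac_floor` is deliberate: raw SVD
solutions legitimately dip a little below zero, and clipping intermediates
would hide that from the fraction rule, so cleanup (clip + renormalize) is
applied only to the final average.

If no candidate survives, the function raises a structured
`vuvcd_no_solution` error carrying per-rule rejection counts. Leave-one-out
evaluation (`loo_evaluate()`) records such members, skips them with a
warning, and pools the rest; it reports the pooled RMSD $\delta$ over all
(protein, class) pairs and the Pearson $r$ over the same pairs — one scalar
each, the way reference databases are usually benchmarked (measured VUVCD
databases of ~31 soluble proteins report $\delta \approx 0.058$,
$r \approx 0.85$). Whether those published figures pool classes or average
per class is not stated; pooling is this package's convention.

## Segment numbers from distorted fractions

Each helix segment contributes roughly four distorted (terminal) residues
and each strand segment roughly two, so the distorted contents carry the
segment counts:

$$ N_{helix} = \mathrm{round}(h_d N_{res} / 4), \qquad
   N_{strand} = \mathrm{round}(s_d N_{res} / 2), $$

rounding half away from zero. On the published contents for the SUMO-tagged
NCYM construct and the isolated SUMO tag (bundled via `ncym_contents()`),
this reproduces all eight reported segment counts exactly — the package's
test suite asserts all eight integer equalities. Exact .5 cases never occur
in those rows, so the rounding convention is documented rather than
empirically pinned.

## Constrained per-residue assignment

`constrained_assign()` places the helix and strand segments along the
sequence. Its inputs are a per-residue propensity profile (any real scores;
only ranks matter) and integer targets from `targets_from_vuvcd()`:
$\hat n_H = \mathrm{round}(\text{helix total} \cdot N_{res})$,
$\hat n_E = \mathrm{round}(\text{strand total} \cdot N_{res})$, plus the
segment counts $\hat s_H, \hat s_E$ from the segment estimator. The
objective is the discrepancy

$$ D = |n_H - \hat n_H| + |n_E - \hat n_E|
     + \lambda_{seg} \left( |s_H - \hat s_H| + |s_E - \hat s_E| \right), $$

with $\lambda_{seg} = 1$ by default so one segment mismatch weighs like one
residue mismatch.

The algorithm has three phases:

1. **Greedy ranking.** Residues are labeled H (resp. E) in descending
   helix (resp. strand) score until the residue targets are met. The two
   rankings are merged, so a residue wanted by both classes goes to the
   class scoring it higher and the loser takes its next-ranked free
   residue; ties break to the lower sequence index, then H before E.
2. **Segment reconciliation.** Local moves adjust segment counts: merging
   the two closest same-class segments across an all-C gap, deleting the
   lowest-total-score segment, or splitting the longest segment at its
   lowest-scoring interior residue; after each segment move, residue counts
   are restored by trimming the worst segment-end residues or extending
   segments at their best flanking C (moves that never change segment
   counts). A compound move is kept only if it lowers the discrepancy.
3. **Minimal-difference fallback.** A labeling over $\{H, E, C\}$ with
   counts $(n_H, n_E, s_H, s_E)$ exists iff each class has between 1 and
   $n$ residues per segment ($s_c \le n_c$, $s_c = 0 \Leftrightarrow
   n_c = 0$) and $n_H + n_E + \max(0, |s_H - s_E| - 1) \le N_{res}$ — the
   last term counts the single-C separators forced between same-class
   segments after maximal interleaving. (The test suite validates this
   characterization against exhaustive enumeration of all $3^n$ strings for
   small $n$.) Using it, the discrepancy-optimal *achievable* tuple is
   found exactly, and if the search result is still above that optimum a
   labeling realizing it is constructed directly. The returned labeling
   therefore always attains the minimum achievable discrepancy; in
   particular, feasible targets are always met exactly.

Phase 2 is allowed to relabel residues chosen in phase 1 (the moves above
can give a residue to the other class indirectly, via delete + extend);
this is an interpretation — the alternative, freezing phase-1 residues, can
strand the search — and is stated here as such. No minimum segment length
is imposed.

Determinism: every tie-break is fixed (score, then index, then class), so
identical inputs give identical labelings.

## Propensity scores

The bundled default is a Chou–Fasman-type table of helix/strand
propensities smoothed with a centered moving average (`window = 5`,
shrinking at the ends). This is an intentionally simple stand-in for
profile-based neural-network predictors, which are out of scope; the
assignment stage is score-agnostic, and externally computed per-residue
scores can be supplied in the common `.ss2`-style layout
(`read_external_scores()`, with residue-letter cross-checking against the
FASTA). Because only ranks are consumed, no normalization is imposed on
scores.

## The synthetic world

All benchmarks run against generated data (`make_basis_spectra()`,
`make_reference_set()`, `make_planted_profile()`):

* **Basis curves** are sums of Gaussian bands at literature-standard
  positions (helix +192/−208/−222 nm, strand +198/−216 nm, unordered
  −198 nm, weak broad turn features; distorted classes attenuated). They
  reproduce the qualitative band structure, not any measured database.
* **Reference sets** draw four-class totals (helix, strand, turn,
  unordered) from three Dirichlet archetypes — helix-rich $(8,2,2,3)$,
  strand-rich $(2,8,2,3)$, mixed $(4,4,2.5,3.5)$ — then split totals into
  ordered/distorted at fixed shares ($h_d = 0.4\,h_{tot}$,
  $s_d = 0.45\,s_{tot}$), add white noise scaled to each spectrum's peak
  amplitude (default 2%, a realistic synchrotron-CD error scale), and
  assign residue counts uniformly in 80–350. The default set size, 30
  plus a held-out query, mirrors the size of real VUVCD reference
  databases.
* **Planted profiles** give in-class residues `base + margin + noise` and
  others `base + noise`, the minimal statistical structure the assignment
  stage assumes.

One consequence of the fixed distorted shares deserves emphasis: they make
the fraction matrix rank 4 (each distorted row is proportional to its
ordered row) and the noiseless spectra matrix rank 5, so the
ordered/distorted split is only identifiable for queries that follow the
same convention. Recovery benchmarks therefore use held-out members of the
same generative family. This is also why the rank cap matters.

What passing these benchmarks does **not** show: real spectra contain
baseline drift, wavelength-dependent noise, aromatic side-chain
contributions, and deviations from the linear mixing model, none of which
are simulated; and real fraction uncertainties inherit the stated ~5%
spectral error in ways the package does not propagate. Quantities that
depend on unpublished inputs (a measured reference database, trained
network weights) are reproduced at the level of schema and properties, not
numerically.

## Problem sizes used in the test suite

The shipped tests use reference sets of 12–31 proteins on the 66-point
175–240 nm grid, leave-one-out over 30 members at 0% and 2% noise,
exhaustive assignment oracles up to $N_{res} = 12$ (all $3^{12}$
labelings), 100 feasible assignment instances up to $N_{res} = 120$, and
20-seed planted-recovery runs at $N_{res} = 100$ — sizes chosen so the
whole suite exercises every claim in seconds while matching the scale of
the real use case (a 238-residue construct against a 31-protein database).

## Interfaces

The package is organized as a library plus numbered analysis drivers under
`analysis/` (simulate the world, benchmark the deconvolution, reduce the
published contents table, run and compare full pipelines). `run_pipeline()`
and `compare_runs()` are the programmatic entry points; reports serialize
to JSON (`write_report()`), assignments to a FASTA-like string file plus a
per-residue TSV (`write_assignment()`), reference sets to a YAML manifest
with two-column spectrum files (`write_reference_set()`). Percentages in
reports are printed to one decimal, matching the precision of published
content tables.

## Known limitations

* The exact SELCON3 variant and thresholds used by synchrotron-facility
  pipelines are not public; the defaults here are literature-standard and
  fully surfaced in `selcon_config()`, but published fraction tables from
  such pipelines are not expected to be reproduced bit-exactly (they also
  require the unpublished measured spectra).
* The sum/fit/helix rules can reject all candidates for noisy queries;
  this surfaces as a structured error rather than a silent bad estimate,
  and leave-one-out reports such members explicitly.
* Spectral error is not propagated into fraction uncertainties; users
  needing error bars should resample their spectra externally.
* The segment-number divisors (4 distorted residues per helix, 2 per
  strand) are a convention validated here against published integer counts,
  not fitted quantities.
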