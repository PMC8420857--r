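# vuvcd

Secondary-structure inference from (vacuum-UV) circular dichroism spectra.

## What problem this solves, and for whom

Far- and vacuum-UV circular dichroism (CD) spectra of proteins are shaped by
backbone secondary structure, and synchrotron VUVCD (usable down to
~175 nm) carries enough information to resolve six structure classes. This
package is for spectroscopists and structural bioinformaticians who have a
measured CD spectrum of a protein — often one that resists crystallography,
such as a small, partially disordered, or *de novo* evolved protein like
NCYM — and want to go from that spectrum to:

1. **contents**: six secondary-structure fractions — ordered/distorted
   α-helix *h<sub>r</sub>*, *h<sub>d</sub>*, ordered/distorted β-strand
   *s<sub>r</sub>*, *s<sub>d</sub>*, turn, unordered;
2. **segment numbers**: how many helices and strands the chain contains;
3. **positions**: a per-residue H/E/C labeling consistent with 1 and 2;
4. **comparisons**: residue-level differences between two runs, e.g.
   hydrogenated vs perdeuterated forms of the same protein.

## The methods at its core

**Deconvolution** (`selcon_deconvolve()`) is a self-consistent SVD scheme of
the SELCON3 family. The query spectrum *c* is prepended to the reference
spectra matrix *A* = [*c* | *C*] and the current fraction guess to the
fractions matrix *F<sub>x</sub>* = [*f* | *F*]; with *A* = *USV*ᵀ, the
rank-*k* candidate solution is the row-space projection

&nbsp;&nbsp;&nbsp;&nbsp;*f*⁽ᵏ⁾ = *F<sub>x</sub>* *V<sub>k</sub>V<sub>k</sub>*ᵀ *e*₁ ,

iterated to self-consistency and then filtered by the classic selection
rules (sum rule, fraction rule ≥ −0.025, spectral-fit rule, helix-stability
rule); survivors are averaged, clipped, and renormalized.

**Segment numbers** come from the distorted contents: each helix contributes
~4 distorted (terminal) residues and each strand ~2, so

&nbsp;&nbsp;&nbsp;&nbsp;*N*<sub>helix</sub> = round(*h<sub>d</sub>* · *N*<sub>res</sub> / 4), &nbsp;
*N*<sub>strand</sub> = round(*s<sub>d</sub>* · *N*<sub>res</sub> / 2).

**Positioning** (`constrained_assign()`) labels residues H/E/C from
per-residue propensity scores (bundled Chou–Fasman-type table, or any
`.ss2`-style score file) under the constraint that residue totals and
segment counts match the spectroscopic estimates, minimizing the
discrepancy |*n*<sub>H</sub> − n̂<sub>H</sub>| + |*n*<sub>E</sub> − n̂<sub>E</sub>| +
λ(|*s*<sub>H</sub> − ŝ<sub>H</sub>| + |*s*<sub>E</sub> − ŝ<sub>E</sub>|); the
returned labeling provably attains the minimum achievable discrepancy, so
feasible targets are always met exactly.

A synthetic-data module (Gaussian-band basis spectra, Dirichlet-sampled
reference sets, planted-truth profiles) generates every input the pipeline
consumes, so all of this is testable without access to a measured reference
database. See `vignettes/vuvcd-methods.Rmd` for the full account.

## Worked example

Deconvolve a held-out protein of a simulated 30-protein reference set
(2% spectral noise) and position its secondary structure:

```r
library(vuvcd)
basis <- make_basis_spectra()
pool  <- make_reference_set(31, basis, noise_sigma = 0.02, seed = 2026)
rs    <- reference_set(pool$proteins[1:30], grid = pool$grid)
query <- pool$proteins[[31]]   # held out; true fractions known
sequence <- substr(strrep("MSDQEAKPSTEDLGDKKEGEYIKLKVIGQDSSEIHFKVKMTTHLKKLKESYCQRQGVPMN", 4),
                   1, query$n_res)
rep <- run_pipeline(query$spectrum, sequence, rs, seed = 1, name = "held-out")
rep
```

```
VUVCD pipeline report for 'held-out' (219 residues)
  H(r) 23.9  H(d) 15.9  S(r) 10.0  S(d) 8.2  turn 3.6  unordered 38.5 (%)
  totals: helix 39.8%  strand 18.2%  other 42.0%
  segments: 9 helices, 9 strands; assignment discrepancy 0
```

Reading this: the six fractions are the deconvolved contents (this
protein's true values are 24.4/16.2/9.2/7.5/4.0/38.6%, so the estimate is
within ~2 points per class); the totals collapse them to helix/strand/other;
the segment counts follow from the distorted fractions
(round(0.159·219/4) = 9 helices, round(0.082·219/2) = 9 strands); and
discrepancy 0 means the per-residue labeling in `rep$assignment` meets the
residue and segment targets exactly. `compare_runs(rep_a, rep_b,
offset = 129)` diffs two such reports residue by residue, reporting
positions both in construct numbering and (via the tag offset) in the
untagged protein's numbering.

The numbered scripts under `analysis/` run the full study: `01` simulates
the reference world, `02` benchmarks leave-one-out deconvolution (pooled
RMSD δ = 0.0038 noiseless, 0.0093 at 2% noise, r > 0.99 — a measured
31-protein VUVCD database reports δ ≈ 0.058, r ≈ 0.85), `03` reduces the
published NCYM/SUMO-tag contents table to totals and segment counts, and
`04` runs and compares a hydrogenated/perdeuterated-style pair of
pipelines. Outputs land in `results/`.

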