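---
title: "Screening L1000 signatures for suppressors of a target gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening L1000 signatures for suppressors of a target gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapscreen)
```

## The problem and the data

The Connectivity Map's L1000 platform profiles the transcriptional response
of cell lines to tens of thousands of perturbagens. Its level-5 data are
replicate-collapsed differential-expression signatures: for each signature
(one perturbagen in one cell line at one dose and time) and each of 12,328
genes, a z-score-like value describing how far that gene moved relative to
the plate-control background. 978 landmark genes are measured directly;
the rest are computationally inferred, a subset of them (the
"well-inferred" tier, which includes *CROT*) with validated correlation to
measurement.

`cmapscreen` asks a deliberately narrow question of these data: *which
small molecules reliably push one chosen gene down (or up)?* This is a
single-gene query, not signature connectivity matching — no KS or weighted
connectivity score is involved, because the scientific target is a gene,
not an expression signature.

## The model and the statistic

Level-5 values are differential expression against the plate control, so
"no effect on the target gene" corresponds to a mean of zero. For compound
$c$ with $n_c$ pooled signatures and target-gene values
$z_{c1},\dots,z_{cn_c}$, the screen computes

$$\bar z_c = \frac{1}{n_c}\sum_i z_{ci}, \qquad
  t_c = \frac{\bar z_c}{s_c/\sqrt{n_c}},$$

and a p-value from the Student $t$ distribution with $n_c - 1$ degrees of
freedom. A compound is selected when $\bar z_c < 0$ (for a downward screen)
**and** $p_c < 10^{-6}$; the two conditions are a conjunction, so their
order of application is immaterial. Candidates are ranked by $\bar z_c$
ascending, with ties broken by p-value and then perturbagen id so output is
fully deterministic.

Design choices worth making explicit:

* **Test family.** The published description of this kind of screen says
  only that p-values are computed "comparing to the control". Because
  level-5 values are *already* differences versus control, we read this as
  a one-sample location test of mean zero and default to the two-sided
  Student t. A one-sided variant (`test = "t_one_sided"`, testing in the
  screen's direction) is available by configuration. The choice moves
  p-values by at most a factor of two and never changes the means, so
  ranking by mean is unaffected; reproduction of any particular published
  p-value is contingent on this unstated choice, which is why our
  file-level comparisons treat printed p-values as order-of-magnitude
  quantities.
* **Degenerate groups.** With $n_c < 2$ or a sample of exactly zero
  dispersion the t statistic is undefined or infinite. We flag the p-value
  as undefined (`NA`) and never select such compounds, rather than
  reporting $p = 0$ and producing spurious infinite-t hits. The replicate
  floor (`min_profiles = 5`, i.e. at least five level-5 signatures per
  compound) makes this rare on real data.
* **Pooling.** All cell lines, doses and times of a perturbagen are pooled
  into one group, because the screen aggregates per small molecule with no
  stratification. The pooled test therefore asks for an effect that is
  consistent *across* contexts — a feature for repurposing, where
  context-robust suppression is what one wants.
* **Multiple testing.** Selection uses the raw $10^{-6}$ threshold. An
  informational Benjamini–Hochberg `q_value` column is attached to screen
  output but never participates in selection under the default preset;
  with ~20,000 compounds tested, $10^{-6}$ is already close to a
  Bonferroni-style family bound.
* **Curation.** Literature-driven exclusions are a separate, explicit step
  (`apply_exclusions()`): matches by perturbagen id (exact) or name
  (case-insensitive), with a warning for any exclusion that matched
  nothing, and consecutive re-ranking afterwards.

## File formats and memory

The level-5 matrix is consumed as GCTX (an HDF5 container with the matrix
at `0/DATA/0/matrix`, stored signatures × genes in HDF5 dimension order,
and gene/signature ids under `0/META`) or as GCT text, version 1.3 only —
other version lines are rejected rather than guessed at. Row and column
order are preserved exactly as stored. Metadata TSVs use the deposited
dialects, with the conventional `-666` sentinel mapped to missing.

A screen needs one gene row of a genes × 473,647 matrix. `read_signature_matrix()`
therefore takes a `gene_subset`: for GCTX the rows are read through an HDF5
hyperslab selection, and for GCT the file is scanned line by line, so the
full gene dimension is never materialised. The subset read is tested
element-for-element against rows of a full load.

GCTX round-trips are bit-exact. GCT text is written with four decimal
places (ample for z-scores of magnitude a few), so its round-trip tolerance
is $10^{-4}$.

## The synthetic generator

`simulate_dataset()` emulates the *structure* the screen consumes: a gene
× signature matrix of z-score-like values, per-signature metadata with
`pert_type = "trt_cp"` and round-robin cell-line labels, and a gene table
with landmark/well-inferred tiers at the real platform's proportions
(978 : 9,196 : 2,154). Null compounds and all off-target genes draw from
Normal(0, σ) with σ = 1, matching the z-score-like scale of level-5 data;
a fraction `frac_effect` of compounds carries a planted shift δ on the
target gene row only (default δ = −0.6 z-units, a typical magnitude for a
real suppressor hit). Everything is reproducible from one integer seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: heavy-tailed or skewed level-5 value
distributions, inter-cell-line heterogeneity of drug response, correlated
off-target structure, and the upstream assay itself (bead deconvolution,
inference of non-landmark genes, replicate collapsing). Effects are
planted only on the target gene because the screen reads exactly one row;
off-target realism would not change any tested behaviour. Cell-line labels
are cosmetic (the screen pools them) but are generated to exercise the
metadata plumbing.

Under this generator the per-compound p-values are exactly
t-distributed-null, so calibration checks are sharp: the empirical
rejection rate at α over $N$ null compounds is binomial, and the test
suite requires it to sit within $3\sqrt{\alpha(1-\alpha)/N}$ of α with
$N = 10{,}000$. Power checks use the noncentral-t power of the two-sided
one-sample test as the oracle: at δ = −1, σ = 1, $n = 100$ profiles and
α = $10^{-6}$ the noncentrality is $-10$ and the power is 0.999996, so the
screen's measured sensitivity must reach at least 0.95 (and in practice
reaches 1 at this size).

## Verification strategy and problem sizes

* Every screen run is checked against an independent naive
  re-implementation (an explicit loop over compounds calling
  `stats::t.test`) on simulated instances of roughly 50 genes × 200
  signatures — small enough to run in seconds, large enough to exercise
  grouping, filtering and tie-handling.
* Permutation invariance (shuffling matrix columns and metadata rows),
  conservation (group sizes summing to the filtered signature count) and
  selection soundness (every emitted row satisfies the replicate floor,
  the p threshold and the sign constraint) are asserted as properties.
* Calibration uses 10,000 null compounds × 10 profiles; the power grid for
  monotonicity uses 150 compounds per cell over 3 effect sizes × 3
  replicate depths. These sizes put the whole suite in the tens of seconds
  on one CPU while leaving the binomial error bands narrow enough to be
  meaningful.
* The worked examples from the published 16-candidate table (ranking
  position of niclosamide, the selection rule retaining all 16 rows, the
  three curated exclusions leaving 13) run from a typed copy shipped in
  `inst/extdata/`, so they need no download. The full-cohort reproduction
  against the public GSE92742 release is a separate opt-in script
  (`scripts/integration_gse92742.R`) because it requires a multi-gigabyte
  download and one to two hours of I/O.

## Known limitations

* The screen tests each compound marginally; it does not model dose or
  time response, cell-line interactions, or shared-moiety structure among
  compounds.
* Pooled replicates are treated as independent; real signatures of one
  compound share batches and cell lines, so real p-values are likely
  anti-conservative relative to the idealised null. The calibration
  machinery exists precisely to quantify this on simulated deviations.
* The GCT reader accepts only version 1.3; the GCTX writer emits the
  standard minimal layout (ids plus matrix) without optional per-axis
  metadata blocks.
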