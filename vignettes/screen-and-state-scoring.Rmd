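---
title: "Scoring pooled CRISPRi drug-modifier screens and single-cell tumor states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled CRISPRi drug-modifier screens and single-cell tumor states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenstate)
```

# Overview

`screenstate` implements two analysis procedures that are typically run
together when a genome-wide CRISPR interference (CRISPRi) screen for drug
modifiers is paired with single-cell profiling of the same tumor model:

1. **Screen phenotype scoring.** From an sgRNA count table over a T0, a
   vehicle and a drug arm, it computes the three standard pooled-screen
   phenotypes — growth (gamma), drug (tau) and drug/growth ratio (rho) —
   centered on non-targeting controls and normalized per population
   doubling, aggregates elements to gene scores, tests genes against the
   non-targeting control distribution, controls the false discovery rate,
   and integrates conserved hits across a human and a mouse screen.
2. **Cell-state scoring.** From a log-normalized single-cell expression
   matrix, it scores the four glioblastoma meta-module signatures
   (MES-like, AC-like, OPC-like, NPC-like) and the two cell-cycle
   signatures per cell with bin-matched control genes, assigns each tumor
   cell to a state, flags cycling cells, and compares signature scores
   between cell groups with Wilcoxon rank-sum tests.

Both halves ship with seeded synthetic-data generators so that every
stage can be validated against planted ground truth without any external
download.

# The screen model

## Phenotype definitions

For element $i$, let $f_i^{(c)}$ denote its relative abundance in
condition $c$ (counts divided by the sample total, with a pseudocount —
see below). With $d_v$ and $d_d$ the population doublings of the vehicle
and drug arms, and $\tilde m_\gamma$ etc. the median over non-targeting
control (NTC) elements of the corresponding raw log ratio:

$$
\gamma_i = \frac{\log_2\!\big(f_i^{\mathrm{veh}}/f_i^{T0}\big) - \tilde m_\gamma}{d_v},
\qquad
\tau_i = \frac{\log_2\!\big(f_i^{\mathrm{drug}}/f_i^{T0}\big) - \tilde m_\tau}{d_d},
\qquad
\rho_i = \frac{\log_2\!\big(f_i^{\mathrm{drug}}/f_i^{\mathrm{veh}}\big) - \tilde m_\rho}{d_d}.
$$

Gamma isolates the fitness cost of repressing a gene, tau the combined
growth-plus-drug effect, and rho the drug–gene interaction alone: a
negative rho means repression sensitizes cells to the drug, a positive
rho confers resistance. Each phenotype is retained in four
representations (raw log ratio, NTC-centered, per-doubling, and
standardized by the NTC phenotype SD) so downstream consumers can pick
the scale they need. Before centering, the raw log ratios obey the exact
identity $\rho_{\text{raw}} = \tau_{\text{raw}} - \gamma_{\text{raw}}$,
which the test suite asserts to $10^{-12}$.

## Numerical choices

* **Pseudocount on the frequency scale.** Ratios use
  $f_i = (x_i + p)/(N + p\,n)$ with default $p = 1$. Applying the
  pseudocount after normalization to relative abundance makes ratios
  invariant to sequencing depth; applying it to raw counts would not.
* **Replicate handling.** Replicates of one condition are summed into a
  single pseudo-sample for the gamma/tau/rho point estimates; the
  replicate-resolved ratios feed only the per-element Wald test
  (`wald_test_replicates()`). This mirrors the common practice of
  reporting one phenotype per screen while testing across replicates.
* **Downsampling.** `downsample_counts()` subsamples each sample column
  without replacement (multivariate hypergeometric, drawn sequentially
  with `rhyper`) so every column hits the target depth exactly; a
  mandatory seed makes the draw reproducible.
* **Gene aggregation.** Gene scores are the mean of the top 3 elements
  ranked by absolute phenotype with sign preserved. Ranking by the signed
  value would systematically favor one direction; ranking by magnitude
  keeps sensitizing and resistance effects on an equal footing.
  Magnitude ties are broken by element id lexicographic order so results
  are deterministic.
* **Statistics.** Gene-level significance uses the two-sided Mann-Whitney
  U test of a gene's element phenotypes against the NTC phenotype
  distribution (exact by enumeration when the combined sample size is at
  most 12 and tie-free; normal approximation with continuity and tie
  correction otherwise). The Mann-Whitney route suits single-replicate
  mouse-style screens; for multi-replicate dual-guide screens the
  per-element Wald test is additionally available: $z$ is the replicate
  mean over its standard error with a normal reference, and
  zero-variance elements receive a variance floor equal to the median
  replicate SD of the NTC elements. Multiple testing uses
  Benjamini-Hochberg step-up (the conventional reading of "adjusted P"),
  and hits are genes with $q < 0.05$ split by score sign.

## Hit integration across species

`conserved_hits()` intersects two screens: a gene pair is conserved only
if it is significant at the chosen FDR *and* has the same effect
direction in both screens. Intersection rather than meta-analytic pooling
was chosen because the scientific claim being supported — a hit is
reproducible across an NF1-mutant human model and an Nras-mutant mouse
model — is a claim about each screen separately. Ortholog pairing
defaults to case-insensitive symbol identity (SHOC2/Shoc2), which is how
most human/mouse symbol pairs relate; an explicit two-column map
overrides it and rejects one-to-many pairs rather than guessing.
`consensus_signature()` applies the same rule to gamma scores with a
negative-sign requirement, yielding the set of genes required for growth
in both screens, sorted by mean standardized score.

# The single-cell model

## Module scores

`module_score()` follows the bin-matched control-gene convention
established for tumor cell-state scoring: all genes are ranked by mean
expression across cells and cut into 25 equal-size bins; for each
signature gene, 100 control genes are sampled from its bin (with
replacement when a bin is smaller than the control count); the score is
the per-cell mean expression of the signature genes minus the mean of
the pooled controls. Because both terms shift equally under a per-cell
additive offset, the score is exactly invariant to per-cell depth or
complexity shifts — the property the control genes exist to provide, and
one the test suite checks directly. Defaults (`n_bins = 25`,
`n_ctrl = 100`) are the convention's usual values; both are exposed, and
all scores are bit-reproducible under a fixed seed.

## State assignment and cycling

Cells are assigned to the argmax of the four state scores, with a fixed
tie-break order (MES, AC, OPC, NPC) so assignment is deterministic. The
two-dimensional hierarchy visualization sometimes drawn from these
scores is deliberately not implemented: it is a display, not a
classifier. A cell is called cycling when the larger of its G1/S and
G2/M scores exceeds a threshold, default 0.1. The threshold is exposed
as a parameter because no canonical value exists; 0.1 sits well above
the score noise floor of non-cycling cells at realistic noise levels
while catching planted cycling cells with sensitivity and specificity
above 0.9 in the recovery experiments.

Group comparisons of any per-cell score (for example a MEK-activation
signature between MES-like and non-MES cells) use the same rank-sum
engine as the screen side.

# What the synthetic generators emulate

`simulate_screen()` draws initial element abundances from
LogNormal(0, 0.5) (library skew), grows them exponentially with
per-doubling log2 fitness offsets ($1 + k_i\varphi$ per doubling, where
$k_i$ is the element's knockdown efficiency and $\varphi$ the gene's
planted effect: growth in vehicle, growth + drug under drug, zero for
NTCs), renormalizes to proportions, and draws counts negative-binomial
with variance $\mu + \theta\mu^2$. The default overdispersion
$\theta = 0.05$ reflects typical library-prep noise; $\theta = 0$ gives
Poisson counts, under which the per-sample totals concentrate within
$3\sqrt{N}$ of depth × elements. The default doublings (10 vehicle, 5
drug) match a mouse screen design in which drug roughly halves the
number of doublings. Dual-guide pairs are treated as single elements —
one count per pair — which is how such libraries are tabulated.

The generator does **not** simulate FASTQ reads, PCR duplicates, or
guide-level off-target effects, so passing recovery tests demonstrates
the correctness of the scoring chain, not robustness to upstream
sequencing artifacts.

`simulate_cells()` works directly on the log-normalized scale (baseline
|Normal(0, noise_sd)| per gene per cell, an additive `effect_size` on a
cell's own-state signature genes, and on one cycling signature for the
planted cycling fraction, default 20%). It skips UMI sampling, doublets
and ambient RNA because every in-scope scoring operation consumes
normalized expression; conclusions about raw-count preprocessing cannot
be drawn from these tests. With `effect_size = 1`, `noise_sd = 0.5` and
200 cells per state, assignment accuracy is at least 0.95; with
`effect_size = 0` it falls to chance (0.25), which the acceptance checks
verify.

# Problem sizes and runtime

The validation experiments are sized so the full suite runs in well
under a minute of compute per module: null calibration uses 1,000 genes
× 5 elements with 200 NTCs over 5 seeds; sensitizer recovery plants 20
sensitizers among 500 genes at depth 1,000 with 3 replicates; the
cross-species consensus uses two 300-gene screens sharing 31 planted
essential genes; cell-state recovery uses 800 cells over 10 seeds.
Paper-scale libraries (about 48,000 or 107,000 elements) simulate and
score in seconds to minutes and are exercised once in the tests at
library-construction level.

# Known limitations

* The Wald test uses a normal reference; with very few replicates it is
  anti-conservative relative to a t reference, which is why gene-level
  calls default to the Mann-Whitney route.
* Gene-level Mann-Whitney p-values are discrete for small element counts,
  so very small FDR thresholds can be unreachable for genes with few
  elements.
* The top-3-by-magnitude gene score has a small away-from-zero selection
  bias (about half the element-level noise SD), measured at under 0.02
  per-doubling units in the recovery experiments at depth 1,000.
* Ortholog mapping by case-insensitive symbol identity misses genuine
  orthologs with diverged names; supply an explicit map for rigorous
  cross-species work.
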