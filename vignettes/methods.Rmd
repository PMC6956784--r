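---
title: "dockrf: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dockrf: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dockrf` predicts protein–ligand binding affinity on the p-scale
(pKi / pIC50 = −log10 of a molar constant; higher = tighter binding) by
combining two information channels:

1. **Structure channel.** A ligand is docked into an ensemble of receptor
   templates (default 20), each selected by the Tanimoto similarity between
   the candidate's fingerprint and the template's co-crystallized anchor
   ligand. Every pose is scored by a battery of 19 evaluation metrics —
   docking scores, rescoring functions, their pKa-calibrated forms, a
   four-way consensus (`AtomeScore`), anchor similarity, and
   receptor/complex quality measures. Per ligand and representation, each
   metric's distribution over the poses is summarized by its median and
   sample standard deviation (a "unified instance", 38 features). The
   median captures the ensemble's central affinity estimate; the SD
   captures how sensitive a ligand's scoring is to receptor conformation.
2. **Ligand channel.** 11 classical molecular descriptors (size, volume,
   counts, polarity, lipophilicity, hybridization), an engineered
   flexibility ratio `nRotB.nB = nRotBond / nBond` (a proxy for the
   entropic cost of binding), and optionally 166-bit MACCS keys.

A random-forest regressor maps the assembled features to p-affinity.
Random forests fit this problem well: they handle monotone-but-nonlinear
score→affinity relationships, mixed feature scales without normalization,
are invariant to each score's sign convention, and expose a single
influential hyperparameter (`mtry`).

Assumptions inherited by the design: poses are pre-aligned into a common
frame (template superposition happens upstream); scores arrive in native
units and orientation and are never sign-flipped; descriptors are 2D
properties, shared across all representation tags of a ligand.

## Feature sets

Six frozen feature modes: `structure_only` (38), `ligand_only` (11),
`combined` (49), `combined_engineered` (48; the raw `nRotBond`/`nBond`
counts replaced by `nRotB.nB`, which proved the stronger variable),
`maccs_only` (166) and `combined_maccs` (215). Feature order is fixed:
structure features in metric-registry order with `_Med` before `_SD`,
then descriptors in table order, then MACCS bits.

## Affinity transforms and units

Ki and IC50 are taken in nM by default (`units` accepts M/µM/nM) and
mapped to `9 − log10(value_nM)`. Relative binding activity (RBA, a
cell-assay potency with estradiol = 100) maps to `pIC50 = log10(RBA) − 8`,
so RBA 100 → −6 on this scale. Values ≤ 0 are rejected rather than
clamped: they signal unit errors.

## Splitting and cross-validation

Stratification cuts the label into `n_bins = 5` equal-count quantile bins
(a common ML-framework default; the method is insensitive to the exact
count at these sizes). The hold-out draws per-bin quotas by largest
remainder so the test set has exactly `floor(test_fraction · n)` units —
the rule reproduces a 56/225 split at n = 281 and is fully deterministic
from the seed. CV deals each bin's ligands round-robin over folds, so
fold sizes differ by at most one per bin.

Splitting operates on **ligands**, not rows: when five representation
variants of one ligand appear in a combined dataset, all of them stay on
one side of every split and inside one fold. This is stricter than
row-wise stratification, which would leak near-duplicates from training
into test and inflate combined-representation performance. An
`grouped = FALSE` escape hatch restores row-wise behavior.

## The random forest

No random-forest package is available in the deployment environment, so
the ensemble is implemented natively (Rcpp): CART regression trees,
variance-reduction splits over `mtry` features sampled per node, bootstrap
resampling, and a self-contained mt19937 RNG so a fit is bit-reproducible
from one integer seed regardless of R's RNG state.

Defaults: `n_trees = 500` (predictions stabilize well before that at these
dataset sizes), `min_node = 5` (regression convention), bootstrap with
replacement at fraction 1. The tuning grid is
`{⌊p/3⌋, ⌊√p⌋, ⌊p/2⌋}` — `p/3` is the classical regression default, the
other two bracket it. CV fits use a reduced `cv_trees = 150` for speed;
tree count affects variance, not the ranking of `mtry` candidates.
Tuning uses repeated stratified CV (default 3 repeats for tuning; the
full 10×10 protocol is available and used by the hygiene tests). A
leakage assertion inside the training loop verifies no ligand straddles a
fold boundary.

Importance is the accumulated SSE decrease per feature, normalized so the
top feature reads 100 — matching the usual 0–100 presentation of forest
importance plots. A plug-in engine interface (`fit`/`predict`/optional
`importance`) lets any regressor reuse the surrounding protocol.

Predictions are averages of training-label leaf means and hence always lie
within the training label range; extrapolation beyond the training
affinity window is structurally impossible and should be kept in mind
when screening far outside it.

## Chemistry backend and descriptor conventions

Descriptors, MACCS keys and structure parsing are delegated to RDKit,
called through the `python` interpreter (`options(dockrf.python = ...)`
overrides). Conventions the package freezes (the source descriptors'
upstream defaults are unstated, so any self-consistent convention works
as long as it is fixed and tested):

- `nAtom` counts all atoms **including implicit hydrogens**; `nBond`
  counts heavy–heavy bonds only. `VABC` (Zhao–Abraham–Zissimos additive
  van der Waals volume) uses explicit hydrogens.
- Rotatable bond: non-ring single bond between two heavy atoms each with
  ≥ 2 heavy neighbours, excluding amide C–N (SMARTS-equivalent
  `[!D1;!$(*#*)]-!@[!D1;!$(*#*)]` minus `[NX3]-[CX3]=[OX1]`).
- `HybRatio = nSP3 / (nSP2 + nSP3)` over carbons; 0 when the denominator
  is 0. Fully aromatic hydrocarbons → 0, saturated acyclic alkanes → 1.
- The `XLogP` column carries Wildman–Crippen logP: the named atom-type
  XLogP algorithm is not available in the backend, and logP enters only
  as a regression feature where cross-method drift (≲ 0.5 log units) is
  immaterial. The substitution is deliberate and documented here.
- Tanimoto of two empty fingerprints is defined as 0 with a warning
  (rather than NaN), keeping similarity rankings total.
- A ligand with a single heavy atom has `nBond = 0` and an undefined
  flexibility ratio (NA); `flexibility_ratio()` treats it as a
  degenerate-input error.

## Consensus and calibration

`AtomeScore` is the arithmetic mean of the four pKa-scale scores
(calibrated PLANTS, XScore, calibrated MedusaScore, calibrated DSX). The
upstream definition is ambiguous about raw vs calibrated components; since
the consensus is labelled pKa, the calibrated forms are used — an
interpretation, recorded here. Strict mode errors on any missing
component; `allow_partial = TRUE` averages what is present and flags the
result, because averaging silently over different component sets changes
the score's meaning.

Calibration lines map raw scores affinely onto the pKa scale. Users with
their own (score, affinity) reference pairs fit them by OLS
(`fit_calibration`), which the tests pin against the closed-form normal
equations at 1e-9.

## Pose clustering

Representative-pose selection clusters the ensemble's poses by
coordinate RMSD (identical atom ordering, no symmetry correction) under
single linkage, threshold 2.0 Å — the upstream heuristic is unspecified,
so this documented surrogate was chosen; it only affects which pose is
*reported*, never the affinity model, which uses all-pose medians. The
winner is the best-consensus pose of the largest cluster; size ties break
by higher mean consensus, then first appearance. Median for even pose
counts is the midpoint of the central pair; SD uses the n−1 denominator
(statistical-software convention; unstated upstream).

## Evaluation

R² is computed **against the identity line**: `1 − Σ(obs − pred)² /
Σ(obs − mean(obs))²`. It may be negative and is deliberately not the
square of rP; a model can correlate well yet sit far from the diagonal.
RMSE is the root-mean-square error (the conventional definition, despite
looser verbal glosses of "average deviation"). Spearman uses average
ranks on ties. Argument order is pinned — predictions first — and a
regression test keeps it that way, because R² is direction-sensitive.
Degenerate inputs (zero-variance observations or constant predictions)
yield NA correlations with an explicit flag instead of dropped cells, so
cross-evaluation matrices stay complete.

Raw lower-is-better scores correlate *negatively* with affinity in
`median_score_correlation()`; no signs are flipped, and users should read
the orientation column of `metric_schema()`.

## The synthetic benchmark: stated world

The generator emulates the statistical structure of ensemble-docking
output, with defaults fixed once:

- latent pKa ~ Uniform(4, 14) — roughly ten orders of magnitude, mirroring
  the affinity span of real estrogen-receptor datasets;
- a 60-template library with anchor similarities ~ Uniform(0.05, 0.95),
  top-20 selected per ligand;
- pKa-scale scoring metrics `m = a·(θ·T + (1 − θ))·pKa + b + jitter +
  noise` with slope a = 1, similarity coupling θ = 0.3, score noise
  σ = 0.8 pKa units and shared per-pose jitter τ = 0.5 — noise on the
  order of what separates calibrated scoring functions from experiment;
- raw-scale scores derived from their calibrated forms by inverting fixed
  calibration lines (negative slopes: raw scores are lower-is-better);
- auxiliary metrics (receptor quality, ligand internal energy, …) with
  weak or no affinity signal;
- descriptors drawn from drug-like ranges, with XLogP, MW and the
  flexibility latent carrying an independent ligand-channel signal of
  strength 0.5 (structure stronger than ligand by default — the regime
  the model-ordering acceptance check requires);
- multiple representation tags share the latent pKa and redraw all noise,
  a proxy for conformer/charge-model variation.

What it does **not** emulate: real chemistry (synthetic descriptor rows
are numbers, not molecules — real-molecule tests use an in-code fixture
set of ~20 drug-like and xenobiotic SMILES), 3D pose geometry (the
clustering tests build their own toy coordinates), heavy-tailed scoring
errors, activity cliffs, or assay heterogeneity. A green recovery test
therefore establishes that the pipeline's plumbing, splitting hygiene and
learner are sound — not that any particular real-data accuracy will be
reached.

## Frozen thresholds

Acceptance thresholds (held-out rP ≥ 0.9 in the low-noise regime
σ = 0.3/τ = 0.2 at n = 400; permuted-label |rP| ≤ 0.15 seed-averaged;
mode orderings in ≥ 8/10 seeds) were frozen after one pilot run
(`scripts/pilot.R`), which measured mean rP 0.999 (low noise), −0.04
(null), and 10/10 for both orderings — comfortable margins, not tuned
boundaries. The noise-free oracle limit (held-out RMSE < 0.05) is checked
at n = 800 with fully grown trees, where the forest's nearest-neighbour
averaging error is well below the bound.

## Known limitations

- The pKa-calibration of raw scores ships with synthetic default lines;
  fitting against a real affinity-annotated complex collection is the
  user's responsibility (`fit_calibration`).
- MACCS feature modes require real structures and are unavailable for
  purely synthetic studies.
- Per-ligand aggregation of predictions across representation tags is
  left to the caller (predictions are per row); a mean over tags is a
  one-liner but the choice is reporting policy, not model substance.
- The CLI covers the pipeline loop; template selection and
  cross-evaluation are R-level APIs.
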