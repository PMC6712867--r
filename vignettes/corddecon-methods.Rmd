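---
title: "Methods: constrained-projection deconvolution of cord blood methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained-projection deconvolution of cord blood methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corddecon)
```

## The model

Bulk DNA methylation of a blood sample is, to a good approximation, a
convex combination of the methylation profiles of its constituent cell
types. For a sample with beta values $y \in [0,1]^P$ over a library of $P$
probes, and a reference matrix $X \in [0,1]^{P \times K}$ whose columns are
per-cell-type mean profiles measured on sorted cells, `corddecon` estimates
the composition $w$ by constrained projection (CP/QP):

$$\hat w \;=\; \arg\min_w \; \lVert Xw - y\rVert^2
\quad\text{s.t.}\quad w_k \ge 0,\;\; \textstyle\sum_k w_k \le 1 .$$

The inequality $\sum_k w_k \le 1$ (rather than equality) is deliberate: the
reference panel never spans every cell population in a real sample, and the
unassigned remainder $1 - \sum_k \hat w_k$ is informative. Renormalising to
a sum of one is a separate, explicit step (`rescale_excluding()`), used
when estimates must be compared against leukocyte-only cell counts that
lack, e.g., nucleated red blood cells (nRBC).

Assumptions worth stating: (i) linearity of beta values in cell
proportions, which holds well away from the intensity saturation limits;
(ii) the reference means represent the cell types as they occur in the
mixtures — the whole point of the QC stage below is that for public
cord-blood references this is not automatic; (iii) probes behave
independently in the least-squares sense (no attempt is made to model
probe-probe error covariance).

### The solver

The QP is tiny ($K \le 7$ in practice), so exactness is cheap. The solver
(`solve_constrained_projection()`) enumerates candidate active sets in
increasing size, solves each equality-constrained KKT system directly, and
returns the first point satisfying the full KKT conditions — for a convex
objective any KKT point is the global optimum, so early exit is sound. The
unconstrained minimiser is tried first, which resolves most calls in a
single $K \times K$ solve. Numerical choices:

* KKT feasibility/stationarity tolerance `tol = 1e-8` (argument), scaled by
  the magnitude of $X^\top y$;
* rank deficiency of $X^\top X$ is detected upfront by an eigenvalue test
  at relative tolerance `1e-10`; in that case the optimum may be
  non-unique, so all active sets are examined and the **minimum-norm**
  optimiser is returned with a `degenerate` flag (deterministic
  tie-break);
* probes with missing values are dropped per sample (complete case, no
  imputation); a sample sharing fewer probes than cell types is an error —
  or, inside `deconvolve()`, a per-sample error entry while the run
  continues.

The test suite checks the solver against an independent coarse-to-fine
simplex grid search (final step $10^{-4}$, again sound by convexity) on one
hundred random instances.

## Projection-based reference QC

Sorted "pure" reference samples are themselves deconvolved against an
external reference (in real studies, an adult flow-sorted panel; in the
synthetic study, the generator's true profiles) and classified by their raw
(unrescaled) estimate for the labelled cell type:

* estimate for the expected type $\ge$ cutoff → **keep**;
* estimate for a *different* type $>$ cutoff → **reclassify** to that type
  (precedence over removal — a sample that fails its own label but cleanly
  matches another type is a mislabelled tube, not a mixture);
* otherwise, expected estimate $<$ cutoff → **remove**;
* labels in the exempt set bypass QC entirely.

Defaults: `purity_cutoff = 0.70` and `exempt_cell_types = "nRBC"` — nRBCs
have no adult counterpart, so a projection against an adult panel cannot
judge them. Comparisons are strict in the directions stated above, so a
sample estimated at exactly 0.70 for its own label is kept. The cutoff is
moderate on purpose: cord and adult profiles of the same cell type differ
physiologically (naive T cells especially), and a stricter cutoff would
discard samples for being cord-like rather than impure. Raw rather than
rescaled estimates are compared against the cutoff because rescaling would
inflate the dominant fraction and silently change the cutoff's meaning; a
strict variant that removes instead of reclassifying is available
(`reclassify = FALSE`). Reclassified samples are evaluated once — no
re-projection after relabelling.

Cleaned datasets are combined by probe intersection (complete-case across
all datasets, lexicographic probe order for platform-independent
determinism) and averaged per cell type, each sorted sample contributing
equally within its type.

## Library selection

Both strategies start from per-probe statistics (`per_probe_statistics()`):
for each probe, a Welch (unequal-variance) one-vs-rest $t$ per cell type —
group sizes and variances differ substantially across pooled references, so
the pooled-variance test would be anti-conservative — and a one-way ANOVA
$F$ across the $K$ groups. Constant probes are reported as $t = 0$, $F = 0$,
$p = 1$ rather than `NaN`.

**Automatic top-N** (`select_automatic()`): per cell type, probes passing
the $F$-test threshold (`p_threshold = 1e-8`) are ranked by $|t|$ (ties
broken lexicographically by probe ID, making selection fully deterministic
and sample-order invariant) and the top `n_per_type = 100` taken — either
direction-agnostic (`mode = "any"`, the behaviour automatic selection
exhibits on cord blood) or balanced half hyper- / half hypomethylated
(`mode = "both"`, the adult-blood behaviour). Ranking by $p$-value instead
of $|t|$ is exposed as `rank_by = "p"` since either reading is defensible;
the two orders differ only through the Welch degrees of freedom.

**IDOL-style optimisation** (`idol_candidate_set()`, `idol_optimize()`):
the candidate pool takes, per cell type, the `m_top = 150` most positive
and `m_top` most negative one-vs-rest $t$ probes. For each requested
library size (default 150–700 by 50) a seeded stochastic search is run for
`n_iterations = 500` iterations, scoring each candidate subset by
deconvolving training mixtures of known composition and averaging per-cell-
type squared Pearson correlation (ties broken by mean RMSE). The search:

* starts from the per-cell-type balanced top-$|t|$ subset of the pool;
* proposes swap moves replacing `swap_fraction = 0.01` of the subset
  (at least one probe) with candidates drawn with probability proportional
  to per-candidate inclusion weights, themselves initialised proportional
  to $|t|$;
* accepts a proposal only if it improves the training objective by at
  least `min_improvement = 5e-4` (mean $R^2$ units), and multiplicatively
  re-weights: members of accepted subsets $\times 1.1$, members of subsets
  scoring in the worst decile seen so far $\times 0.95$.

Two of these choices deserve justification because the design space is
genuinely open. First, the informed start and $|t|$-proportional proposals:
a search initialised uniformly over a pool that is mostly uninformative
probes has no gradient to climb — whole-subset reward updates credit
informative and uninformative members identically — and does not
concentrate within a realistic iteration budget; ranking candidates by
marginal evidence before the combinatorial refinement is also how the
original iterative-optimisation idea is set up. Second, the acceptance
margin: the training set is small (typically a dozen mixtures), and
accepting arbitrarily small improvements lets chance-aligned null probes
accumulate — the optimiser overfits its own scoring set. The margin keeps
only moves that improve the objective beyond scoring noise; the package's
planted-truth tests show the margin is what keeps the optimised library
composed of genuinely informative probes while also improving held-out
RMSE. The per-size winners are compared on held-out test mixtures, and the
best size is chosen by test $R^2$ with test RMSE as tie-break.

The train/test split of the known-composition mixtures is a seeded random
half split (`train_fraction = 0.5`).

## Evaluation

`evaluate_proportions()` reports, per cell type, the squared Pearson
correlation between estimated and true columns and the RMSE (in percentage
points by default, matching how cell fractions are usually quoted). These
two metrics dissociate by construction: a constant +5-point bias keeps
$R^2 = 1$ while RMSE reports 5. That dissociation is the reason both are
reported — $R^2$ measures relative ordering, RMSE absolute accuracy, and a
method chosen for prediction should be judged on RMSE. An identity-line
variant $1 - SS_{res}/SS_{tot}$ (`r2_method = "identity"`), which does
punish bias, is provided because the two definitions differ exactly for
biased estimators. $R^2$ is flagged undefined (not fabricated) when truth
or estimate has zero variance, and fewer than three matched samples is an
error. Bland-Altman limits of agreement use the conventional
$\pm 1.96\,\mathrm{SD}$ multiplier. `leave_one_out()` repeats
combine–select–deconvolve–evaluate with each reference excluded, flagging
cell types that lose their only carrier.

When leukocyte-only comparisons require dropping nRBC, rescaling is applied
to both estimates and truth *before* computing the metrics; the other
ordering (metrics on raw estimates) is available simply by not rescaling,
since rescaling is an explicit operation.

## The synthetic study

The generator (`sim_config()` and friends) emulates the structure the
pipeline is designed to exploit, with every quantity knowable:

* **Profiles**: baseline probe means from an equal-weight mixture of
  Beta(2, 10) and Beta(10, 2) — the genome-wide bimodality of methylation —
  clipped to $[0.01, 0.99]$; per cell type, `n_dmr_per_type = 40` disjoint
  marker probes shifted by `dmr_effect = 0.4` beta units, half up and half
  down, planted on probes far enough from the boundary that the full
  contrast survives (markers look like real L-DMRs: the target type sits in
  the opposite methylation mode).
* **Sorted samples**: purity defaults to 0.98 (sorted-fraction purities
  reported for public references sit near 0.97–0.99); a configurable
  fraction is contaminated at purity 0.6, the contaminant being a single
  random other cell type — matching the observed failure mode of real
  references, where one sorted fraction carries a large admixture of one
  other population — plus logit-scale Gaussian replicate noise
  (`ref_noise_sd = 0.15`), which keeps values in $(0,1)$ naturally.
  Mislabelled tubes (right profile, wrong label) are planted separately.
* **Mixtures**: true proportions from a Dirichlet whose mean follows
  typical cord-blood differentials (granulocyte-dominated, nRBC a few
  percent) with total concentration 15, giving realistic between-infant
  spread; measurement noise is additive Gaussian on the beta scale
  (`mixture_noise_sd = 0.015`, the order of array technical noise),
  clipped to $[0,1]$. The two noise models are intentionally different so
  replicate variation and measurement error remain distinguishable.
* **Platforms**: `split_platforms()` produces two probe universes with a
  configurable overlap fraction, exercising the probe-intersection path.

One global seed drives a derived per-operation seed, so each stage
reproduces independently. What the generator does **not** emulate: batch
and dye-bias structure, SNP-affected or cross-reactive probes,
sex-chromosome structure, probe-probe correlation, and cell types absent
from the reference panel. Passing tests therefore demonstrate correctness
of the algorithms under the stated generative model, not robustness to
every artefact of real arrays.

## Problem sizes

The test suite runs the full four-arm pipeline (automatic/IDOL ×
raw/filtered) across twenty seeds at a reduced scale chosen so the whole
suite completes in well under a minute per property: 600–2,200 probes,
4–5 cell types, 8–12 sorted samples per type, 20–24 mixtures, IDOL at
25–500 iterations with sizes 40–100. `scripts/acceptance.R` runs one
larger study — 5,000 probes, the seven cord-blood cell types, two sorted
datasets, IDOL sizes 150–400 at 150 iterations — in about a minute. These
sizes are the package's desk-scale defaults; all algorithms scale linearly
in probes and samples, and the solver's cost is dominated by a single
$K \times K$ factorisation per sample.

## Known limitations

* The CP/QP model cannot see cell types missing from the reference; their
  mass is absorbed by the most similar represented type.
* The IDOL-style optimiser is a behavioural reimplementation: it is seeded,
  deterministic, beats random libraries of the same size and recovers
  planted markers, but it will not reproduce any published library
  probe-for-probe.
* QC against an external reference inherits that reference's biology;
  types that genuinely differ between cord and adult blood (naive T cells)
  are exactly the ones the moderate cutoff is protecting.
* R² comparisons across arms are descriptive; no formal test of R²
  differences is implemented.
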