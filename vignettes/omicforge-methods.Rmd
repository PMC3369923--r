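---
title: "Linear steady-state multi-omics models and in silico genome redesign with omicforge"
author: "omicforge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear steady-state multi-omics models and in silico genome redesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicforge)
```

## The model

omicforge works with panels of recombinant inbred lines (RILs): near-isogenic
plant lines derived from an interspecific cross, each measured for gene
expression (a nested subset of lines, on arrays, in replicate), metabolite
levels and agronomic traits. The package fits a three-layer *effective linear
steady-state model*:

* **gene layer** — the steady-state expression of gene $i$ satisfies
  $g_i = \sum_{j \ne i} w_{ij}\, g_j + b_i + \varepsilon$, a sparse linear
  fixed point with per-gene intercepts and a calibration term;
* **metabolite layer** — $m_k = \sum_i v_{ki}\, g_i + b_k + \varepsilon$;
* **trait layer** — $a_p = \sum_k u_{pk}\, m_k + b_p + \varepsilon$.

Degradation constants are absorbed into the coefficients (time is rescaled so
the steady state is dimensionless), and all data are z-scored per feature
across lines before fitting, so coefficients are on a common standardized
scale. Each gene's expression is confined to the interval between its
observed minimum and maximum across the arrayed lines ("the range of
diversity" of the panel); a tunable fraction `delta` shrinks that interval
symmetrically about its midpoint, the default being `delta = 0` (no shrink).

A *knockout* (KO) replaces a gene's equation by its range minimum and an
*over-expression* (OE) by the maximum. Downstream genes are re-solved
self-consistently (a one-pass propagation mode is also available, since the
data alone cannot distinguish the two conventions): the projected, damped
fixed-point iteration

$$ g \leftarrow (1-\lambda)\, g + \lambda\, \Pi_{[\ell, u]}(W g + b), \qquad
   \lambda = 0.5, $$

run until the maximum absolute change falls below $10^{-10}$ (at most $10^4$
sweeps), where $\Pi$ projects each free gene into its shrunk range and
clamped genes stay fixed. When no bound is active this equals the direct
linear solve of $(I - W)\,g = b$ on the free block; the implementation
computes the same projected fixed point through a cached sparse LU
factorization of $I - W$ with low-rank row-replacement (active-set) updates,
and verifies every solution with a projected sweep, falling back to the
plain damped iteration if the active set fails to settle. Damping 0.5 is a
robust default for spectral radii near 1.

### Calibration terms

The model carries one perturbation/calibration term per layer. During
training it is fitted per line, but its across-line variation is small by
construction (the intercepts absorb the feature means of z-scored data), so
the *stored* model freezes it at the training mean and uses that constant for
novel lines. When predictions are anchored to a specific panel line —
as in all perturbation scans — the per-line residual calibration is used
instead, which makes the empty perturbation reproduce the line's observed
state exactly. That choice turns the "wild-type efficiency is exactly zero"
property into an identity rather than an approximation.

## Inference

Each layer is inferred independently with the same two-stage chain:

1. **CLR mutual-information screening.** Mutual information between every
   (target, predictor) pair is estimated by equal-frequency binning with
   $\lceil \sqrt{n} \rceil$ bins (capped at $n/5$); each pair's MI is
   z-scored against its row and column background and combined as
   $z = \sqrt{\max(0, z_r)^2 + \max(0, z_c)^2}$ (the context likelihood of
   relatedness convention). Predictors with $z \ge z^\*$ become candidates;
   the default $z^\* = 2$ reduces the predictor space by roughly an order of
   magnitude. Self-pairs are excluded in the gene layer.
2. **LASSO support selection with OLS refit.** Within the candidates, an L1
   penalty selects the support; ordinary least squares on that support then
   de-biases the coefficients ("multiple regressions" after selection). The
   penalty is either a fixed value or chosen per target by 5-fold
   cross-validation; the default uses the parsimonious `lambda.1se` rule,
   `"cv_min"` the predictive-optimal `lambda.min`. `sweep_inference()`
   reproduces the classical threshold sweep — CV performance as a function
   of $(z^\*, t_{\mathrm{LASSO}})$ — for choosing an operating point on a
   given panel, the default grid being $z \in \{2, 3\}$.

Reliability is quantified three ways: per-target training Pearson r; honest
k-fold cross-validation in which screening and selection are re-run inside
every training fold (`cross_validate()`, 5-fold for genes/metabolites,
10-fold for traits); and, when a reference edge set exists, positive
predictive value and false-positive rate of the support with a
10000-replicate bootstrap null that redraws same-size random predictor lists
with replacement (`bootstrap_ppv_fpr()`). `degree_powerlaw()` reports the
in-degree distribution and a zeta-normalized maximum-likelihood power-law
exponent ($x_{\min} = 1$), and `noise_robustness()` traces how the mean
prediction correlation decays as Gaussian noise is added to the measured
targets — a specificity diagnostic.

## Optimization of objectives

An `objective_spec()` is a signed, weighted combination of metabolites
and/or traits; unweighted sets get balanced weights $1/|{\rm set}|$ per
side. Modes: maximize, minimize, or tune to a target value (score
$-|x - x^\*|$). A bi-objective couples two specs as
$\alpha\, z(\text{primary}) + (1-\alpha)\, z(\text{secondary})$ with
z-scores relative to the wild-type population across lines; $\alpha$
defaults to 0.5 and the endpoints reduce exactly to one spec alone.

The *efficiency* of a perturbation in a line is the normalized relative
change $100\,(s_{\rm pert} - s_{\rm wt})/|s_{\rm wt}|$, in percent. Because
z-scored objectives cross zero routinely, wild-type scores below $10^{-9}$
in magnitude fall back to the wild-type population standard deviation as
denominator (flagged on the result). The exact normalization of the ratio is
a convention; it is isolated in `efficiency()`.

`scan_single()` enumerates every gene under both clamp modes, per line;
`scan_pairs()` evaluates unordered pairs under the four mode combinations
(optionally a seeded random sample under a budget, and including the
degenerate gene-plus-wild-type rows so the pair landscape contains the
single landscape); `greedy_multi()` sweeps genes, committing per round the
single KO/OE/wild-type change that most improves the *mean* score across
the supplied lines — matching the across-RIL framing of the landscape
analyses — with ties broken by gene id order and a non-decreasing
trajectory by construction. `rank_perturbations()` sorts stably by (i) mean
efficiency across lines or (ii) the maximum objective value reached in any
line ("best-line property"; the alternative reading of the criterion as a
per-line maximum is a line statistic, not a perturbation ranking, and was
therefore not used). `landscape_stats()` reports, per efficiency threshold,
the mean ± sd count of qualifying perturbations across lines and the
selection probability of each perturbation across lines.

## Validation by perturbation signatures

For each metabolite, the *perturbation signature* collects the single-gene
perturbations that move it by more than a relative threshold
$\epsilon = 1\%$ — relative to the metabolite's wild-type population
standard deviation — split into a raising set $\Omega^+$ and a lowering set
$\Omega^-$. The predicted correlation of two metabolites is
$S_{\rm same} - S_{\rm opp}$: the larger normalized intersection among
same-sign set pairs minus the larger among cross-sign pairs. The printed
form of the normalization is not recoverable from the source material, so
both natural readings are implemented: division by the smaller set (default;
a subset relationship scores 1) and Jaccard. Predicted and empirical
correlation matrices are compared by precision, recall and
$F = 2PR/(P+R)$ over pairs called at a cutoff $k$ (optionally restricted to
pairs with empirical $|r| \ge 0.5$), by average-linkage dendrograms
(`signature_dendrogram()`, Newick output via `as_newick()`; undefined
distances imputed to the maximum finite distance and flagged), and by a
Mantel permutation test (`mantel_test()`, wrapping the standard vegan
implementation with explicit seeding). `overlap_enrichment()` scores
direction-consistent overlap between proposed perturbations and genes
observed altered in engineered lines (KO matches under-expression, OE
over-expression) against random same-size selections, with a Mann-Whitney U
test and an empirical p-value.

## The synthetic panel generator

Because no public accession accompanies the study design this package
implements, every stage is exercised against *planted* synthetic panels with
full knowledge of the truth. The generator draws a sparse three-layer linear
system and simulates lines from it:

* in-degrees are Poisson around the configured means — defaults 26
  regulators per gene and 18 genes per metabolite, the documented densities
  of the fitted tomato models, and ~70% of metabolites per trait;
* coefficient magnitudes are uniform on $[0.2, 1]$ with random sign — the
  floor keeps planted edges detectable, the generative distribution itself
  being a convention (the original study used real data and states none);
* the gene-gene matrix is rescaled to spectral radius 0.8, guaranteeing a
  unique steady state;
* per line, every gene receives an independent standard-normal exogenous
  input plus gene-layer noise inside the steady-state equation — the
  simplest mechanism producing cross-line variance in the z-scored regime;
* metabolites and traits add Gaussian noise at their layers' `noise_sd`
  (default 0.3 in z-score units);
* replicates add Gaussian noise at one third of the line-level sd,
  emulating triplicate fruit samples without modelling array chemistry;
* the panel mirrors the nesting of the motivating design: 169
  metabolome/phenome lines, 50 of them with triplicate expression arrays.

`make_engineered_lines()` simulates introgression-line-style validation
material: lines whose listed genes are clamped at their range limits inside
the *true* system. Clamped genes take exactly their clamp value in every
replicate, since the lesion is genetic rather than a measurement.

What the generator does *not* emulate: two-channel array chemistry and
intensity-dependent bias — and for that reason the LOWESS step and the
replicate-CV mask, which correct intensity artefacts of real arrays, should
be disabled on synthetic panels (`preprocess_panel(..., lowess = FALSE)`):
with no intensity dimension present, the flexible local fit would remove
genuine covariance instead of bias, and the CV is undefined around zero.
Also not emulated: genetic linkage among lines (lines are exchangeable,
whereas real RILs share recombination structure), nonlinear regulation and
metabolite chemistry. Passing tests on planted panels
therefore demonstrate correctness of the machinery and identifiability under
the linear model's own assumptions, not performance on real fruit data.

## Numerical conventions and degenerate inputs

* Ties in equal-frequency binning are broken by first occurrence; constant
  features get MI 0 and screening z 0, and are dropped (with a warning) by
  standardization.
* LOWESS detrending uses the across-sample mean profile as reference
  (span 0.3); a reference without spread (already-standardized data) is a
  no-op, which makes the preprocessing pipeline idempotent after one pass.
* Replicate CVs are computed on the pre-log scale, where the CV is well
  defined; cells with zero mean but nonzero spread are masked as unreliable.
* Presence filtering is strictly greater than the threshold (a feature seen
  in exactly 80% of arrays at threshold 0.8 is removed); surviving missing
  cells are imputed by the feature median, a deterministic and robust
  convention.
* Supports larger than $n - 2$ are truncated to the largest coefficients
  (warned); empty candidate sets yield intercept-only models, flagged in the
  fit metadata.
* The steady-state solver errors on non-convergence when called directly and
  flags (without dropping) non-converged records inside scans.
* Model stacks serialize to JSON with 17 significant digits, so predictions
  after a save/load round trip are bit-identical.

## Choices made where the design was open

* Whether z-scoring preceded or followed the presence filter is not
  documented; this pipeline filters first, then standardizes.
* The printed screening and penalty thresholds are not recoverable from the
  source text; $z^\* = 2$ and CV-chosen penalties are package conventions,
  with `sweep_inference()` provided to re-derive an operating point per
  panel.
* Self-consistent re-solution of downstream genes after a clamp is the
  default; one-pass propagation is a flag.
* The acceptability-style composite objective is configuration, not code:
  no formula is documented, so the package ships only the generic weighted
  objective machinery.
* Reference-based PPV/FPR uses the planted-truth sense when a reference is
  supplied (synthetic work); with no reference the bootstrap machinery can
  be pointed at any edge list, e.g. a stability selection.

## Problem sizes used in the shipped analyses

The bundled end-to-end script (`scripts/acceptance.R`) and the test suite
run on planted panels of 300 genes, 30 metabolites and 5 traits over 160
lines (60 with expression, triplicate), with noise sd 0.3 — large enough to
show the documented qualitative regime while keeping a full run to minutes
on a single CPU. Unit fixtures are much smaller (5–40 genes). Pair scans in
the script sample 150 pairs; the greedy search runs on the top 25 genes of
the single scan for 5 rounds.

## Known limitations

With 18 near-equal planted predictors per metabolite among hundreds of
cross-correlated genes and only ~60 expression lines, marginal
(screening-based) statistics separate true from proxy predictors only
weakly; support recovery in that regime is under-determined for any
screen-then-select chain, and the package reports it honestly (PPV around
0.3–0.4 against the planted truth, with false-positive rates near 1–2% and
bootstrap p-values at the resolution floor). Cross-validated prediction is
the more robust currency of model quality in this regime. Linearity is
assumed throughout; saturating or switch-like regulation is outside the
model class, as are time courses and stochastic expression.
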