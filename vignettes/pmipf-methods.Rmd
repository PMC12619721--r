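---
title: "Age-constrained PLS for post-mortem interval estimation: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-constrained PLS for post-mortem interval estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmipf)
```

## The problem

Estimating the post-mortem interval (PMI) beyond the first one or two days
after death is one of the hard open problems of forensic practice. Pericardial
fluid (PF) is attractive for this purpose: it sits deep in the body, is
buffered against early environmental insults, and its small-molecule
composition drifts measurably over days. A quantitative ^1^H-NMR assay of a PF
sample yields a concentration table of roughly 46-50 metabolites, and the
statistical task is to calibrate a regression of PMI (hours) on that table,
with two complications:

* **age is a confounder** — in autopsy series, older subjects tend to be found
  at longer PMIs (Pearson r around 0.35 in the packaged covariate table), and
  some metabolites vary with age for reasons unrelated to decomposition;
* **n is small and K is comparable to n** — typically 50-65 cases against
  46-50 metabolites, so ordinary regression overfits and variable selection
  must be stabilised against sampling noise.

`pmipf` implements the full analysis pipeline: age-constrained projection to
latent structures (oCPLS2) and its two-class variant (oCPLS2C), VIP-based
stability selection over Binary-Matrix-Sampling subsets, repeated
cross-validation with permutation gating, a cluster-representative train/test
split, univariate screens, and a two-batch cosine-similarity reproducibility
check. Because the original concentration data are not public, the package
also ships a synthetic-data generator whose structure matches what the
analysis assumes, so every stage is testable end to end.

## The constrained PLS model

With autoscaled concentrations $X\ (N \times K)$, autoscaled response $y$, and
centred constraint matrix $Z\ (N \times C)$ (here: age), PLS extracts score
components $t_a = X w_a$ by NIPALS: the weight $w_a$ is the dominant left
singular vector of $X^\top Y$ (for a single response, the normalised
$X^\top y$), followed by loadings $p_a = X^\top t_a / t_a^\top t_a$, response
loadings $c_a = Y^\top t_a / t_a^\top t_a$, and deflation
$X \leftarrow X - t_a p_a^\top$. The regression coefficients are
$B = W (P^\top W)^{-1} C^\top$.

The orthogonal constraint is imposed by *restriction*: weights are confined to
the null space of $Z^\top X$. If $G$ is an orthonormal basis of
$\mathrm{null}(Z^\top X)$, PLS runs on $XG$ and everything is mapped back
through $G$. Every score then satisfies $Z^\top t_a = (Z^\top X G)\,w_a = 0$
*exactly* — the defining contract, asserted to $10^{-8}$ in the tests. When
the constraint is vacuous, $G$ is the identity and the code path is
bit-identical to unconstrained PLS2. Published descriptions of oCPLS2 differ
in deflation bookkeeping; this package treats the orthogonality and
reduction contracts, not the bookkeeping, as the specification.

Two consequences of hard in-sample orthogonality are worth knowing:

* if the response is reachable *only* through the constrained direction
  (e.g. predicting age under an age constraint), every score has exactly zero
  covariance with the response; the package then refuses to extract a
  component and cross-validation falls back to the training-mean prediction,
  giving $Q^2 = 0$ exactly — the age-blindness property;
* metabolites driven by age alone are *not* excluded by the constraint — on
  the contrary, the constrained optimum often weights them as "age sinks"
  that cancel the constraint while letting genuine PMI predictors keep their
  weight. The synthetic world deliberately contains such columns (see below),
  and removing them measurably *degrades* recovery of the true PMI panel.

Classification (oCPLS2C) codes two classes as $-1$ ("low") / $+1$ ("high"),
centres the coding, fits the same constrained regression, and thresholds the
predicted centred response at zero (ties to "low"; with the balanced training
sets used throughout, the zero threshold equals the midpoint rule).

VIP scores use the original-space weights:
$\mathrm{VIP}_j = \sqrt{K \sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a \mathrm{SSY}_a}$
with $\mathrm{SSY}_a = (c_a^\top c_a)(t_a^\top t_a)$; squared VIPs average to
1 by construction.

## Validation conventions

`repeated_cv()` runs R-times-repeated k-fold CV (defaults 20 x 5-fold for
regression, 10 x 5-fold for classification), stratifying folds by response
quantiles (or class). *Everything* is re-estimated inside each training fold:
column means/SDs, response scaling, and the constraint null-space basis —
held-out samples are only ever projected. Per repeat,

$$Q^2 = 1 - \mathrm{PRESS} / \mathrm{TSS},$$

with TSS taken about the *training-fold means composed per fold*, so a model
that predicts the training mean scores exactly $Q^2 = 0$; the reported Q² and
SDECV (root of PRESS/n) are means over repeats. SDEC and SDEP are the same
root-mean-square error computed on training and independent test samples.

The randomisation test permutes the response, keeping $X$ and $Z$ fixed, and
recomputes the statistic identically; $p = (1 + \#\{\text{perm} \ge
\text{obs}\})/(1 + n_\text{perm})$, never zero. The component count is chosen
as the $A$ maximising mean Q² (or cross-validated MCC) among those passing the
test at $\alpha = 0.05$, with an explicit failure state when none passes. For
Q²-statistic permutations each evaluation runs a single 5-fold CV rather than
the full 20 repeats (a pure cost/benefit decision, configurable via
`cv_repeats`).

MCC is computed from the 2x2 confusion matrix with the convention that any
zero factor in the denominator yields 0.

## Training-set extraction

The PMI range is cut into equal-frequency segments (default 4; 65 cases split
17/16/16/16). Within each segment the concentrations are autoscaled and
projected onto principal components covering at least 80% of variance (capped
at 10), Ward clustering (`ward.D2` on Euclidean score distances) is cut at
round(0.70 x segment size) clusters — round-half-up, since base R rounds half
to even — and the sample nearest each cluster mean (ties: lowest index) joins
the training set. Two amendments:

* the samples with the global minimum and maximum PMI are always swapped into
  the training set (within their own clusters), so test-set prediction never
  extrapolates;
* `training_size` forces an exact training total by trimming representatives
  from, or promoting runners-up in, the segments with the most training
  (respectively test) samples — the published splits (45/20 from 65, 40/17
  from 57, 35/15 from 50, 17/6 from 23) are not all reachable from a single
  per-segment rounding rule, so forced totals are first-class.

The segment count, PCA depth and rounding rule are not dictated by any
published description; the defaults above are the package's documented
choices and all are exposed as arguments.

## Stability selection

200 subsets are drawn by Binary Matrix Sampling: independent Bernoulli(0.7)
masks over both samples and metabolites (subsets with fewer than 10 samples
or 2 metabolites are redrawn). In each subset a constrained model is fitted,
sampled metabolites are ranked by VIP, and nested head-sets (top-m for every
m up to 25 columns, else 25 log-spaced sizes) are compared by 5-fold CV on a
*shared* fold assignment; NIPALS component nestedness lets one fit serve all
component counts.

Choosing the literal argmax-Q² candidate over-selects badly: beyond the true
panel the Q² curve is flat, its maximum drifts over the flat region, and at
n = 200 that costs around eight spurious selections per run. The package
therefore keeps the *smallest* candidate whose CV error is within one
standard error of the best (the usual 1-SE parsimony rule), which is also the
only meaningful reading of "ties go to the smaller set" on continuous CV
estimates. A subset in which no candidate reaches Q² > 0 contributes an empty
selection — a model that cannot beat the mean has found nothing.

Selection frequency is normalised per metabolite by the number of subsets in
which it was *sampled* (column sampling at 0.7 would otherwise cap frequency
and distort the null). Two null models are available:

* **binomial** (default, fast): success probability equal to the mean
  selected-fraction over subsets. Caveat: on a fixed dataset, chance
  correlations recur across overlapping subsets, so this null is optimistic —
  in an all-noise world of n = 100, K = 46 it admits about 6 false positives
  instead of the nominal alpha*K = 2.3;
* **empirical permutation** (`null_method = "empirical"`): the entire
  per-subset selection is rerun `n_null` times with the response permuted
  over the same masks. By exchangeability the resulting per-metabolite
  p-values are exactly calibrated (measured: 0-1 false positives in the same
  all-noise world), at `n_null` times the cost.

In the synthetic world the three age-driven columns are selected in
essentially every run. That is correct behaviour, not error: an
age-constrained model demonstrably benefits from them (see above), so the
package's recovery tests count "false positives" as selected columns carrying
*no* generating signal at all and report age-driven selections separately.

## The synthetic world

`synthetic_spec()` states the emulated study once, as defaults:

| parameter | default | why |
|---|---|---|
| `n_metabolites` | 46 | the high-reproducibility panel size |
| `planted` | 8 columns, slopes +-0.08 units/h | 5 increasing, 3 decreasing PMI predictors |
| `noise_sd` | 5 units | per-metabolite correlation with PMI about 0.6 — "moderate" noise |
| `age_confound` | 0.35 | the observed PMI-age correlation |
| `age_driven` | 3 columns, 0.15 units/year | age must have real variation to remove |
| `pmi_range` | 16-199 h | the sampled PMI span |
| age distribution | mean 52, SD 20, truncated 15-90 | the autopsy-series demographics |
| sex / site | 2:1 M:F, 2:1 CA:RM | the series' composition |
| `batch_noise_sd` | 0.1 x column SD | a mild replicate batch; 5x for unstable columns |

Concentrations are `baseline + slope*PMI + gamma*age + N(0, noise_sd)`,
clipped at zero, so planted trends stay exactly linear wherever unclipped.
All randomness derives from one integer seed via R's default Mersenne-Twister
generator (sub-seeds seed+1/seed+2 for concentrations and the replicate
batch), so every object is bit-reproducible across platforms.

What the generator does *not* emulate: spectral deconvolution artefacts,
non-linear or saturating post-mortem kinetics, heavy-tailed or correlated
measurement noise, missing values, cause-of-death structure. A green recovery
test therefore establishes that the pipeline recovers linear-in-PMI signal
under Gaussian noise with an age confounder — not that it would recover the
metabolites of any particular real study.

Cosine batch similarity is computed on raw (not autoscaled, not centred)
concentrations — centring would collapse cosine into Pearson correlation —
and flagged at 0.90 (configurable). Because raw columns share a large
positive baseline, pushing a column below 0.90 requires replicate noise of
about half the column's root-mean-square; the reproducibility tests tune
`batch_noise_sd` accordingly.

## Numerical and policy decisions

* PMI windows are inclusive on both bounds (the 130 h case belongs to the
  16-130 h window); the "low" class is PMI <= 48 h inclusive — both choices
  are forced by the published subset sizes (57/50 and 20/30).
* The study covariate fixture is transcribed verbatim; decimal commas are
  read as decimal points. Its one known internal inconsistency (an age of 15
  against a stated adult range) is preserved, not repaired. The printed
  PMI-age correlations 0.35/0.37/0.23 are *training-set* statistics — their
  printed p-values match the training sizes 45/40/35, not the windows — and
  cannot be recomputed from the covariate table; the corresponding acceptance
  test is intentionally left failing with this explanation.
* Constant columns abort `autoscale()` with the metabolite named; inside CV
  folds and subset models they are instead centred with unit scale (zero
  influence) so a single degenerate fold cannot abort a 1000-permutation run.
* Component requests beyond the predictor rank are truncated with a warning;
  a response with zero variance is an error.
* `M = 1` responses (PMI, or the class coding) at every public interface; the
  core handles `M >= 1`.
* Seeds: every stochastic stage takes an explicit seed and restores the
  caller's RNG state; pipeline stages derive sub-seeds from the master seed
  by fixed offsets.

## Known limitations

The binomial stability null is optimistic under strong sample-level chance
correlation (use the permutation null when false-positive calibration
matters). The hard orthogonality constraint can be severe in very small
predictor panels or training sets, where cancelling the constraint consumes
most of the admissible space — even a cleanly separable two-class problem is
capped well below MCC 1 when the classes correlate with age and only ~20
training samples inform the constraint. No multi-class extension, no O-PLS filtering, and no
attempt to reproduce the original study's model metrics, which would require
its undeposited concentration data.
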