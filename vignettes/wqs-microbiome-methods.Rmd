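---
title: "Mixture modelling of the microbiome with random-subset WQS regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modelling of the microbiome with random-subset WQS regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixbiome)
```

## The model

Standard microbiome analyses either summarize a community into a diversity
scalar or test taxa one at a time; neither treats the community as what it
is — a large set of correlated, zero-inflated predictors. `mixbiome`
instead models the joint ("mixture") association between a health variable
and the whole community through a weighted quantile sum (WQS) index,

$$g(\mu) = \alpha + \beta_1 \, \mathrm{WQS} + \delta Z, \qquad
  \mathrm{WQS}_j = \sum_{i=1}^{p} w_i \, q_{ij},$$

where $q_{ij}$ is the quantile score of taxon $i$ in sample $j$, the
weights $w_i$ are nonnegative and sum to 1, $Z$ are covariates and $g$ is a
binomial or gaussian link. $\beta_1$ is the effect of the community acting
as one exposure; the estimated $w_i$ say which taxa carry that effect.

Three adaptations make this workable for 16S abundance tables:

* **Zero-anchored ranking.** Plain quantiles are degenerate when 35–90% of
  a taxon's values are zero. `zero_anchored_rank()` keeps exact zeros at
  score 0 and splits only the positive values into `levels - 1` quantile
  groups (the default, `levels = 4`, is "0 then tertiles above 0";
  `levels = 3` with `split = "median"` is the coarser below/at-or-above
  median scheme; `levels = 2` degrades gracefully to presence/absence).
  Ties at a quantile cut point take the lower score — a deterministic
  dialect the estimator documents rather than inherits silently; the median
  rule keeps its conventional $\ge$.

* **Random subsets.** With $p \approx 868$ taxa and $n \approx 210$
  subjects a single joint fit is hopeless, so weights are estimated on `B`
  random subsets of `m` taxa (`draw_random_subsets()`), each fit on the
  training partition only. Subset-level weights are pooled by a
  signal-weighted average: each subset contributes to the taxa it contains
  with averaging weight $f(t)$, a *signal function* of the Wald $t$ of its
  $\beta_1$ — $t^2$ (default), $e^{|t|}$ (more severe) or $|t|$ (less
  severe). The pooled $p$-vector is renormalized to the simplex. Averaging
  is over the subsets *containing* each taxon; a taxon in no converged
  subset gets weight 0 with a warning.

* **Repeated holdouts.** A single 40/60 train/validation split makes the
  result hostage to one partition. `wqs_rsrh()` repeats the whole pass over
  `repeats` independent stratified partitions and reports the mean weight
  vector, the distribution of the validation-set $\beta_1$ (2.5–97.5
  percentile interval, sign fractions) and per-holdout odds ratios.

## Estimation details

The subset fit maximizes the GLM likelihood jointly over
$(\alpha, \beta_1, \delta, w)$ with $w$ on the simplex and optionally
$\mathrm{sign}(\beta_1)$ fixed. We parameterize $w$ as a softmax of $m-1$
free reals and a sign-constrained $\beta_1$ as $\pm e^{\phi}$, removing
both constraints, and run BFGS with analytic gradients (compiled), one
equal-weight start plus random restarts (default 3 starts total), relative
tolerance $10^{-10}$ with up to three polish restarts from the incumbent
optimum (quasi-Newton steps stall on the flat softmax surface near
boundary optima; restarting the Hessian approximation recovers them), at
most 500 iterations per start. The reported $t$ is
$\beta_1/\mathrm{SE}$ from the observed information of
$(\alpha, \beta_1, \delta)$ at the constrained optimum with $w$ held
fixed. Subsets that fail to converge are dropped from the average and
counted; they are not redrawn, so `B` keeps its meaning and runs stay
deterministic. $e^{|t|}$ is clipped at $|t| = 30$ to avoid overflow.

The validation fit is an ordinary, *unconstrained* GLM of the outcome on
the index plus covariates, so the validation $\beta_1$ may oppose the
constraint direction — that is diagnostic information, not an error. A
detected separation (binomial) triggers a Jeffreys-penalized (Firth)
refit, flagged with a warning.

With `direction = "auto"` the constraint sign is fixed once, before the
repetitions, as the majority sign of subset coefficients in one
unconstrained pass (an exact tie defaults to negative, with a warning).
Fixing once keeps the `repeats` holdouts answering the same question; a
per-holdout re-determination is available by running `wqs_rs()` manually.

Partitioning is outcome-variability-preserving: training size is exactly
`round(train_fraction * n)` and every level of a categorical outcome and
of each categorical covariate must appear on both sides (resampled up to
100 times, then an error naming the offending level). Sub-seeds for the
repetitions derive from the master seed by a counter scheme, so an
ensemble is bit-reproducible from one integer.

Weight vectors at every stage (subset, holdout, ensemble mean, genus
pools) are nonnegative and sum to 1 within $10^{-8}$; tests enforce this
as an invariant.

## Interpreting weights

The reference point for "important" is the equi-weight threshold $1/c$
(`equi_weight_threshold()`): a component above it contributes more than it
would under uniform weighting. For genus-level reading,
`aggregate_weights_by_genus()` sums taxon weights within genus per holdout
(conserving total weight 1), pools unclassified genera per phylum as
`"unclassified (<phylum>)"`, and flags genera whose mean exceeds $1/c$
with $c$ the number of genera.

## The outcome simulator

`assign_signal_taxa()` plants 2 strong / 8 medium / 10 weak signal taxa
(effect sizes 8/4/2) among taxa passing a 10% prevalence floor;
`simulate_test_variable()` draws a binary outcome from
$\mathrm{logit}\,P = \beta_0 + \sum \beta_s\,\mathrm{pot}(x) - 1\cdot
\mathrm{female}$, with $\beta_0 = -5$ and the potency adjustment
$\mathrm{pot}(x) = \log_2\!\big(\log_{10}(x+1)/\log_{10}(\max+1)\big)$
evaluated on the percent relative-abundance scale (the formula is not
scale-invariant, so the scale is fixed and documented; maxima are the
observed per-taxon maxima).

The potency formula is $\le 0$ and diverges at $x = 0$, while the printed
constants ($\beta_0 = -5$, positive $\beta$s) are supposed to yield logits
of roughly $\pm 3.5$ and 13% prevalence — arithmetically impossible as
stated. The simulator therefore exposes the whole decision surface rather
than guessing a single resolution:

* `zero_handling = "zero_contribution"` (default): an absent taxon
  contributes 0 to the logit. This keeps logits finite but makes the
  score–outcome relation non-monotonic (zeros sit *above* small positive
  abundances), which in practice buries the planted signal.
* `zero_handling = "as_formula"`: the literal formula, clipped at $-50$
  per zero. Zeros then dominate the logit, the association between scores
  and outcome is monotone *positive*, and the planted signal is
  recoverable — this is the regime consistent with an all-positive
  direction across holdouts and is what the package's own
  reproduction study (`scripts/acceptance.R`) uses.
* `calibrate_prevalence`: re-solves $\beta_0$ by bisection so the mean
  fitted probability hits a target (13% by convention here) within 0.005;
  the calibrated intercept is recorded on the returned outcome. Under
  `as_formula` the calibrated model is effectively a threshold on the
  weighted potency sum, so outcomes are near-deterministic given the
  table; realized prevalence still varies by table seed.

`synthesize_abundance_table()` generates the community itself: per-taxon
zero fractions uniform in 0.35–0.88, lognormal positive abundances with
per-taxon scale heterogeneity (`meanlog` sd 1.5, within-taxon `sdlog` 1 —
chosen so the largest closed relative abundances reach the ~20% range of
real stool communities), row closure, a generated taxonomy (50 genera in 5
phyla, 10% unclassified) and a two-level `sex` column. Defaults are 210
samples by 868 taxa, the dimensions of a first-visit adult stool 16S
working set after 10% prevalence filtering. Taxa are generated
independently before closure: real inter-taxon correlation, phylogenetic
structure and sequencing-depth artifacts are *not* emulated, so passing
recovery tests here says the estimator finds planted independent signals —
not that it untangles correlated real communities.

## Numerical and design choices

* Relative abundances are fractions in $[0,1]$ internally; percent values
  appear only in display and in the potency formula (which is defined on
  the percent scale). Conversion to relative abundance happens *after*
  prevalence filtering, so proportions are relative to retained taxa;
  filtering an already-relative table re-closes the rows.
* Prevalence filtering keeps taxa with nonzero abundance in $\ge$ 10% of
  samples by default (the usual "absent from >90%" reduction, which also
  guarantees enough positives for tertiles).
* BIOM input is restricted to the JSON dialect (no HDF5 dependency for a
  desk-scale tool).
* Scores are computed on the full dataset before splitting — ranking is a
  preprocessing step, and per-partition re-ranking would make holdout
  weights incomparable.
* The evaluation of identification performance
  (`evaluate_identification()`) defaults to averaging per-holdout
  sensitivity/specificity (matching "averaged across repeated holdouts");
  evaluating the ensemble mean weights once is available as
  `mode = "mean-weights"`. Ties at a cutoff count toward neither
  sensitivity nor specificity ("exceeding"/"below" taken strictly), which
  matters exactly at the equi-weight value.
* Comparators are deliberately delegated where they are commodity:
  Shannon/Bray–Curtis/PERMANOVA/SIMPER to vegan (`adonis2` with
  sequential terms and free permutations; SIMPER contributions on
  relative abundances, and the decomposition identity — contributions sum
  to the mean between-group dissimilarity — is the tested contract), the
  importance screen to randomForest (100 trees; we own only the
  normalization to proportions and the $1/(\text{predictors})$ cutoff).
  The Aitchison distance is computed directly (pseudocount, closure, clr,
  Euclidean) since the delegated interface lacks a pseudocount.

## Problem sizes used in the shipped studies

The package's own reproduction study (`scripts/acceptance.R`) and the
heavier tests run the full 210 × 868 configuration with 30 holdouts but
200 random subsets per holdout rather than 1000, and the test suite's
multi-seed study uses 5 seeds; these sizes were chosen to make the studies
routinely re-runnable on a laptop while leaving every per-taxon
appearance count high enough (about 200 across an ensemble) for stable
weight averages. Null-calibration studies (PERMANOVA uniformity, control
ensembles covering zero) run on deliberately small communities for the
same reason.

## Known limitations

* The simulator's independent-taxon generator understates the difficulty
  of real data (correlated taxa can share or steal weight).
* Sign-constrained subset fits on near-deterministic outcomes can sit on
  the $\beta_1 \to 0$ boundary or separate; non-converged fits are
  dropped, and heavy separation in validation falls back to Firth — both
  are reported, not hidden.
* No bootstrap-classic WQS, no interactions inside the index, no
  stratified or Bayesian variants; genus is the only tested pooling rank.
* Diversity values computed on a prevalence-filtered, closed table are
  comparable within a study but not portable across studies.
* The holdout percentile interval quantifies split-to-split variability,
  not sampling variability: all repetitions see the same realized dataset,
  so a *sign-constrained* analysis of a truly null outcome inherits a
  common selection bias (the constraint harvests same-signed chance
  correlations) that every holdout shares, and the interval can sit off
  zero. Negative-control analyses should therefore run unconstrained —
  the package's own null studies do — and a constrained interval
  excluding zero is evidence of association only in the pre-determined
  direction.
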