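---
title: "Signal implantation for benchmarking differential abundance tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal implantation for benchmarking differential abundance tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicbench)
library(dplyr)
```

## Why implant signals instead of simulating counts?

Benchmarks of differential abundance (DA) tests need data with a known ground
truth. The classical route is parametric: fit a multinomial, negative
binomial or Dirichlet model to a real taxonomic profile, perturb some
parameters, and sample counts. But taxonomic count tables from shotgun
metagenomics are extremely sparse (typically 60–95% zeros per sample),
heavy-tailed across features, and overdispersed in a way that simple
parametric families do not capture. A benchmark built on unrealistic nulls
can certify a method's error control for data that never occur in practice.

`mimicbench` takes the opposite route: start from a *real* (or realistically
synthetic) count table, split the samples into two mock groups at random, and
*edit* the table to create known effects, leaving everything else — sparsity
pattern, correlation structure, library-size variation — untouched. Two edit
operations are composed per selected feature:

* **abundance scaling** — non-zero counts of the feature in its target group
  are multiplied by a factor in {1, 1.25, 1.5, 2, 5, 10, 20};
* **prevalence shift** — a fraction (0–0.3) of the feature's non-zero
  entries in the donor group is exchanged against zero entries of the target
  group, where possible, so the feature's total zero count is conserved.

By default the target group alternates across implanted features (sorted by
feature id), so the two groups keep near-identical library sizes and no
global compositional artefact is introduced. A one-sided mode
(`implant_compositional()`) deliberately breaks this: all signals go into
one group and each modified sample is rarefied back to its original depth,
producing the spurious background depletions that compositional data are
feared for.

## Design choices in the implantation engine

Several details are deliberate choices where more than one convention is
defensible:

* **Order of effects.** The prevalence shift is applied before the abundance
  scaling, both toward the same per-feature target group. This way entries
  that were just moved into the target group also carry the abundance
  effect, keeping the effect direction coherent within each feature.
* **Rounding of scaled counts.** Scaled non-zero counts are rounded half-up
  with a floor of 1 (`7 * 2 -> 14`, `1 * 1.25 -> 1`). The floor guarantees
  abundance scaling can never zero out an entry, which would silently mix an
  (unintended) prevalence effect into an abundance-only configuration. The
  policy is exposed (`rounding =`) because fractional handling is a
  convention, not a law.
* **Ground-truth bookkeeping.** After implantation the realized generalized
  fold change (gFC) of every selected feature is recorded; features with
  |gFC| < 0.001 are kept in the record but flagged `rejected` — they are
  mostly low-prevalence features where the edit had no measurable effect,
  and treating them as ground truth would punish tests for missing
  unmeasurable signals. At the null grid point (scale 1, shift 0) nothing is
  edited and *all* selected features are rejected; those repeats serve as
  internal negative controls.
* **gFC convention.** gFC is the mean difference of the groups' quantiles
  (grid 0.05–0.95 in steps of 0.05, type-7 interpolation) of
  log10(relative abundance + 1e-5). Grid and pseudocount are configurable;
  the defaults are fixed here for reproducibility.

## The synthetic baseline

All examples, tests and the acceptance script run on a built-in generator
(`generate_baseline()`) so that nothing needs downloading. Its model:
per-feature log10 mean abundances are normal with sd 1.5 (heavy right tail
after exponentiation); per-sample compositions are a softmax of those means
plus per-sample lognormal noise (sd 0.6 in log10); counts are negative
binomial (size 0.3) at a lognormal library depth (median 2e4, sdlog 0.5);
finally extra zeros are masked with probability `zero_inflation * med/(m + med)`
for a feature of mean relative abundance `m` — rare features lose entries
first, as in real profiles. The defaults were chosen once so that mean
sample sparsity lands near 0.75, inside the range seen for gut shotgun data.

What the generator does *not* reproduce: between-feature correlation
(features are conditionally independent given the composition), phylogenetic
structure, and batch effects. Consequences: a passing benchmark here shows
that a test behaves correctly on sparse overdispersed tables with known
effects, not that it is robust to ecological co-variation. This is also why
`combine_studies()` exists — real heterogeneity can be injected by
concatenating two baselines and using study origin as a confounder.

```{r baseline}
cm <- filter_features(generate_baseline(
  baseline_spec(n_features = 300, n_samples = 400, seed = 42)
))
glance(implant_signal(cm, seed = 7, scale = 2, shift = 0.2))
```

## Confounding by biased resampling

A second, independent signal can be implanted for a fresh binary label on a
feature set disjoint from the main truth (`implant_confounder()`), dividing
the samples into four strata. `biased_resample()` then draws case–control
subsets with stratum quotas `(1 ± bias)/2` within each label arm
(largest-remainder rounding). This mapping was chosen because it makes the
expected phi coefficient of the drawn labels equal the bias parameter
exactly, so "bias 0.6" means "phi 0.6" without calibration curves.
Infeasible quotas raise an error naming the binding stratum and the largest
feasible bias, rather than silently rebalancing.

```{r phi}
ds <- implant_signal(cm, seed = 7, scale = 2, shift = 0.2)
cd <- implant_confounder(ds, scale = 2, shift = 0.2, seed = 9)
rs <- biased_resample(cd, n = 200, bias = 0.6, seed = 1)
phi_coefficient(rs$label, rs$confounder)
```

## The test battery

Every DA test consumes a features × samples matrix and two-level labels and
returns one row per feature; incomputable features (constant data, singular
fits) carry p = 1, the same convention used for missing p-values before BH
adjustment. Default transforms: rank/ECDF tests (Wilcoxon, KS) on TSS
relative abundances; t-test, linear models and the moderated t on TSS.log
(pseudocount 1e-5); the ANCOM W statistic on raw counts (+1).

Confounder-adjusted variants: a stratified (van-Elteren-style) rank-sum test
combining within-stratum statistics with tie-corrected variances; a fixed
effect linear model `feature ~ label + confounder`; and a random-intercept
model `feature ~ label + (1|confounder)` with Satterthwaite degrees of
freedom (falling back to the fixed-effect model on non-convergence, and to
the naive model when the confounder has a single level).

The moderated t-statistic implements empirical-Bayes variance shrinkage
directly: per-feature residual variances are shrunk toward a prior estimated
by moment matching of log variances (trigamma inversion by Newton
iterations, tolerance 1e-8). The unit tests cross-check it against
`limma::eBayes` on the same inputs.

ANCOM's W values are mapped onto a (0, 1] score: W at or above the
conventional threshold 0.7·(m−1) lands strictly below 0.05 (a discovery),
everything else in [0.05, 1], strictly decreasing in W throughout. The exact
monotone map is a convention; only the ordering and the 0.05/threshold
anchors matter downstream. Scores are flagged `is_score` and bypass
multiple-testing adjustment — discoveries are `score < 0.05` directly.

## Evaluation conventions

Discoveries use BH-adjusted p < 0.05 (strict). Observed FDR with zero
discoveries is defined as 0 — a method that discovers nothing makes no false
discoveries; this choice flatters conservative methods in aggregates and is
therefore stated explicitly. Recall is undefined (NA) on the null grid
point, where the truth set is empty; there the observed FDR degenerates to
an any-false-discovery indicator. AUROC uses raw p-values with ties counting
one half. A method's FDR control is "insufficient" when more than 10% of
settings exceed a mean observed FDR of 10%.

## Realism diagnostics

Three complementary checks compare a simulated table against its baseline:
sparsity/log-variance summaries, PERMANOVA (pseudo-F, permutation p) on
log-Euclidean distances (Euclidean on log10(TSS + 1e-5)), and a LASSO
logistic regression classifier separating real from simulated samples,
evaluated by repeated stratified cross-validation with the penalty chosen by
inner cross-validation on each training fold (nested, so the reported AUROC
is honestly held out). The contract is qualitative: parametric simulations
of sparse baselines are separable almost perfectly (AUROC > 0.9), whereas
implantation output stays near chance.

```{r realism, eval = FALSE}
nb <- simulate_parametric(cm, "negative_binomial", n_samples_per_group = 100, seed = 3)
real_vs_sim_auroc(cm, nb$counts, folds = 5, repeats = 2, seed = 11) # ~0.99
imp <- implant_signal(cm, seed = 5, scale = 2, shift = 0.2)
real_vs_sim_auroc(cm, imp$counts[, 1:200], folds = 5, repeats = 2, seed = 11) # ~0.5
```

## Problem sizes used in the shipped checks

The full design (7 scales × 4 shifts × 100 repeats × 7 sizes × 50
subsamples = 980,000 configurations per method) is what
`benchmark_grid()` enumerates by default; running it end to end is a
cluster-scale job. The package's own test suite and acceptance script
exercise the identical code paths at reduced sizes chosen as honest
miniatures: a 300 × 400 baseline, 5–20 implantation repeats, sample sizes
100–200, one subsample per repeat, and 5-fold × 2-repeat classifier
cross-validation. These sizes are stated here so that any reported number
can be tied to its problem size.

## Known limitations

* The Kolmogorov–Smirnov test uses the asymptotic p-value (exact
  computation is impossible under ties, and zeros tie massively in sparse
  data). Its null p-values are therefore markedly conservative — the
  fraction of raw p < 0.05 under the null falls well below the nominal 5%
  (around 1% in our null checks). This is a property of applying KS to
  tied data, not an implementation artefact, and it depresses the KS test's
  apparent power in any benchmark built on sparse counts.
* Only two-group designs with one binary confounder are supported;
  longitudinal designs, continuous phenotypes and multi-level confounders
  are out of scope.
* The parametric comparison simulators are the uncorrelated variants;
  simulators requiring network-inference machinery for feature correlation
  are intentionally absent.
* The store is a plain-text directory layout (TSV bodies, JSON parameter
  records). It trades compactness for portability and diff-ability; for
  very large sweeps, compress or prune stored simulations.
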