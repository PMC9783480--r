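---
title: "Models and methods behind sexplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexplast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexplast)
```

## The scientific question

Insect development time shortens steeply with rearing temperature. Whether
males and females respond *proportionally* — or one sex is thermally more
sensitive — speaks to how evolvable thermal reaction norms are: conspecific
sexes share genes and juvenile environments but face different selection
pressures, so strong sex differences in plastic responses would indicate
room for sex-specific optimization, while near-identical responses point to
shared physiological constraint. `sexplast` implements the full quantitative
pipeline for asking this question with literature-compiled, treatment-level
data: effect sizes, sampling variances, phylogenetic multilevel pooling,
permutation inference, and a temperature-versus-diet reference comparison.

## Effect size: the ln-RMA slope

For each primary dataset (one experiment, one species, `k >= 2` temperature
or diet treatments with male and female mean development times), the effect
size is

$$b = \ln\big(\mathrm{slope}_{RMA}\big), \qquad
  \mathrm{slope}_{RMA} = \mathrm{sign}(r)\,\frac{SD(\ln m)}{SD(\ln f)},$$

the log of the reduced major axis regression slope of log male on log female
mean development time across treatments. RMA is the appropriate symmetric
line fit because both axes carry error. On the log scale, $b = 0$ means the
sexes respond proportionally, $b < 0$ that females are thermally more
sensitive, $b > 0$ males. Two useful exact properties follow from the SD
ratio form and are exploited by the tests:

* **sex-swap antisymmetry** — exchanging the male and female columns maps
  $b \to -b$ exactly;
* **two-point degeneracy** — for `k = 2` the slope reduces to
  $|\Delta \ln m| / |\Delta \ln f|$ with the sign of the product of the
  differences, so two-treatment datasets are usable.

A sex that is invariant across treatments, or a negative male–female
correlation, leaves $\ln(\mathrm{slope})$ undefined; such datasets are
excluded with a logged reason. (In the empirical corpora motivating the
package this never occurs: development time declines with temperature in
both sexes in every dataset.)

Accompanying descriptors per dataset: the sexual development time dimorphism
`SDTD = (longer sex)/(shorter sex) - 1`, signed positive when females
develop longer, averaged over treatments (a Lovich–Gibbons-type index); the
Pearson correlation `r_mf` of the log means (defined for `k >= 3`); and the
gradient length, the max/min fold-change of the development-time means,
pooling the sexes (the most literal reading of "trait values in primary
datasets"; a per-sex variant is available via `per_sex = TRUE`).

## Sampling variance: the uniform-draw bootstrap

Reported treatment means come with standard errors. Each bootstrap replicate
replaces every (sex, treatment) mean by a draw from a uniform distribution
centred on it, recomputes $b$, and the SD over 1000 replicates is the
sampling SD of $b$; its squared inverse is the meta-analytic weight.

The phrase "using its standard error to determine the width" of the uniform
is ambiguous, so both readings are implemented:

* `sd_matched` (default): half-width $\sqrt{3}\,SE$, so the draw's SD equals
  the reported SE — this preserves the second moment the SE reports;
* `half_width_se`: half-width $SE$ (draw SD $= SE/\sqrt 3$).

In the small-SE regime the two differ by an exact factor $\sqrt 3$ in the
resulting `boot_sd` (tested against a delta-method oracle), so weights
differ by a constant factor 3 and weighted means are nearly unaffected;
variance components are scale-sensitive, which is why the rule is recorded
in every output. Replicates yielding an undefined slope (sign flip under
perturbation) are redrawn so exactly `n_reps` values contribute, with the
redraw count logged. All-zero SEs give `boot_sd = 0`, floored at
`degenerate_floor` (default `1e-8`) to avoid infinite weights. Datasets
missing any SE are "qualitative-only": kept for descriptive summaries,
excluded from weighted models, never imputed.

## The phylogenetic multilevel model

Effect sizes are pooled with

$$y_i = \mu + \beta\,\mathrm{SDTD}_i + u_{species(i)} + s_{study(i)} + o_i + e_i,$$

with $u \sim N(0, \sigma^2_{phylo} A)$ ($A$ the Brownian-motion correlation
matrix from the phylogeny), $s \sim N(0, \sigma^2_{study})$ iid,
$o \sim N(0, \sigma^2_{obs})$ iid, and $e_i \sim N(0, v_i)$ with $v_i$ the
known bootstrap variance. The moderator term is present only in the SDTD
model. Choices worth stating:

* **Branch lengths.** Open Tree topologies usually lack branch lengths; the
  default assigns Grafen heights (power 1), giving an ultrametric tree, so
  $A_{ij}$ is the shared root-to-MRCA fraction of total depth. An
  all-branches-equal alternative is available. The source analysis does not
  state its convention; Grafen scaling is the common default in comparative
  methods.
* **One `u` per species**, shared by all of a species' datasets — the
  standard construction when several effect sizes attach to one taxon.
  Multiple populations of a species all attach to the species tip (how the
  original analysis handled this is unstated).
* **REML** on the log-variance scale with analytic gradients
  (`nlminb`, 5 dispersed starts, relative tolerance `1e-10`); fixed effects
  by GLS at the REML variances; non-negativity enforced by the log
  parameterization, with boundary estimates snapped to zero below `1e-12`.
* **Variance shares** divide each $\hat\sigma^2$ by
  $\hat\sigma^2_{phylo} + \hat\sigma^2_{study} + \hat\sigma^2_{obs}$,
  excluding the known $v_i$. A "6% phylogenetic" style statement depends on
  this denominator choice, which the source does not state; we log it and
  keep the components available so any alternative share can be formed.
* The z statistic's normal-approximation p is reported as a diagnostic only;
  primary inference is permutation-based, because bootstrap-derived weights
  make the null distribution of z non-Gaussian.

Subgroup (per-order) fits prune the correlation matrix per group and apply a
table-wide Holm adjustment by default (the original correction is unnamed;
Holm is assumption-free).

## Permutation inference

* **Pooled mean:** within each treatment of each dataset, the male and
  female values (means with their SEs) are swapped with probability 1/2;
  ln-slopes are recomputed and the model refit, recording z. Two-sided
  $p = (1 + \#\{|z^\ast| \ge |z_{obs}|\})/(1 + B)$.
* **SDTD moderator:** dataset-level SDTD values are shuffled across effect
  sizes (the covariate is defined per dataset, so "permuted between
  treatments" is read at the effect level — an interpretation, flagged as
  such), with ln-slopes, variances and grouping fixed.
* **Temperature vs diet:** species with both factors on the same trait
  contribute a pair of absolute standardized ln-slopes; the statistic is the
  mean paired difference and the null flips each species' difference sign.
  For `n <= 12` pairs all $2^n$ patterns are enumerated exactly.

Two implementation details matter for validity. First, the statistic must be
the *same function* of the data for the observed and every permuted
assignment: refits use starting values derived only from `(y, v)`. (A warm
start at the observed optimum — the obvious speed-up — measurably inflates
the type-I error, because null refits then start from a point tuned to the
observed assignment; this was caught by the calibration suite.) Second,
replicates may either re-run the bootstrap on the permuted data (`
recompute_var = TRUE`, the literal reading of permuting means "together with
corresponding standard error values") or reuse observed variances (the fast
null, valid because `boot_sd` is sex-swap invariant in distribution); the
default is the literal reading, the calibration tests use the fast null for
speed.

Standardization for the paired test defaults to `none` (raw
$|\ln\text{-slope}|$); `gradient_scaled` multiplies by
$\ln(\text{gradient length})$, the cumulative log male–female divergence
across the observed gradient, compensating for thermal gradients (~3.27-fold)
being much longer than diet gradients (~1.28-fold). The original appendix's
exact standardization is not recoverable from the main text, so both rules
are exposed and recorded in every output. Outlier exclusion is an explicit,
logged species list — the original excluded one strongly deviating species
without a stated criterion, so no automatic rule is imposed.

## The synthetic corpus: what it states and what it cannot show

The generator is first-class, tested code; its defaults state the world the
analysis assumes:

* treatment counts 2–11 with mean 4 (`2 + Binomial(9, 2/9)`);
* a log-linear thermal decline spanning a 3.27-fold change in development
  time over 12–32 °C (1.28-fold for diet) — curvature is deliberately
  omitted because the RMA slope on the log scale is insensitive to it;
* true ln-slopes built as $\mu + \beta\,\mathrm{SDTD} + u + s + o$ with
  Brownian species effects on a unit-depth pure-birth tree; default variance
  components (0.0015, 0.0015, 0.002) total 0.005, i.e. between-dataset SD
  ~0.07 — slopes cluster near zero as in the real corpus — in shares
  0.3/0.3/0.4; studies contribute up to two datasets so the study component
  is identifiable;
* SDTD ~ Normal(0.05, 0.10), making ~69% of datasets female-longer (the
  observed fraction is 138/199); the drawn SDTD is also *realized* in the
  data as a male baseline offset, and the analysis recomputes SDTD from the
  generated means, so the generator and the analysis cannot drift apart;
* relative SEs of 3% with mean-realization noise of the same size, which
  puts ~95% of `k >= 3` datasets at `r_mf >= 0.98` (the observed fraction is
  159/168);
* diet datasets get 3x the slope dispersion, stating the observation that
  diet-induced sex differences scatter far more widely than thermal ones.

A green test on this corpus establishes internal statistical correctness
(estimator accuracy, type-I error, coverage, power) — not agreement with the
published biological estimates, which would require the archived empirical
corpus. The generator does not simulate digitization error, journal-specific
missingness, or fluctuating temperature regimes.

## Numerical and degenerate-input policy

* `k = 2` datasets use the exact two-point slope; `r_mf` is undefined there.
* Exact SDTD ties contribute 0 with no sign.
* The phylogenetic correlation matrix is eigen-clipped at `-1e-10`;
  anything lower is an error, not a silent repair.
* REML non-convergence after the dispersed restarts returns
  `converged = FALSE` with diagnostics rather than a partial answer.
* Permutation p-values use the +1 correction; the attainable minimum is
  `1/(1 + n_perms)`.
* All randomness flows from explicit seeds recorded in outputs and the run
  manifest; reruns are bit-identical.

## Known limitations

* The `sigma2_study`/`sigma2_obs` split is only identifiable when some
  studies contribute several datasets; corpora of singleton studies return
  an arbitrary split of their (well-identified) sum.
* Interval estimation for the pooled mean is imperfect under strong
  phylogenetic correlation. The plug-in Wald CI covers ~90% at a nominal
  95% on simulated 300-effect corpora (100 species on a Yule tree, true
  shares 0.3/0.3/0.4): the SE ignores the considerable uncertainty in
  `sigma2_phylo`, whose effective information comes from far fewer than 100
  independent lineages. `profile_mu_ci()` inverts the ML likelihood-ratio
  test instead, re-estimating all variance components at each fixed mean;
  it widens intervals by ~2–8% and lifts coverage to ~92–94% on the same
  corpora. The remaining shortfall is a real small-effective-sample effect,
  and it is why the permutation test — not any CI — is the primary
  inference.
* Diet treatments are unordered labels; nothing in the pipeline uses diet
  "levels" quantitatively.
* The moderator permutation shuffles across all effects, not within study
  blocks; with strong study clustering of SDTD this is an approximation
  (the original's blocking, if any, is unstated).
* The sex-swap permutation test is exact under its own null — male and
  female exchangeable within every treatment — and the calibration suite
  confirms nominal size there (and for the moderator test, which is exact
  whenever the moderator is independent of the effects). It is *not* robust
  to an ensemble null in which each dataset carries a nonzero true slope
  with phylogenetically and study-correlated signs averaging to zero:
  independent within-dataset swaps understate the variance of the corpus
  mean, and on small simulated corpora (6 species, 18 datasets) the test
  rejects at ~12% instead of 5%. The distortion shrinks as the number of
  independent lineages grows (the motivating empirical corpus has 161
  species), but users pooling few, related species should treat small
  permutation p-values for the pooled mean with caution. This behaviour is
  inherited from the published design of the test, not introduced by this
  implementation.
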