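# sexplast

Meta-analysis of sex differences in temperature-induced plasticity of insect
development times.

## What it does, and for whom

Experimental studies routinely report male and female mean development times
for several rearing-temperature (or diet) treatments. `sexplast` is for
comparative biologists who compile such treatment-level tables across many
species and want to know whether one sex is systematically more plastic than
the other — a question that bears on how evolvable thermal reaction norms
are, since the sexes share genes and juvenile environments but not selection
pressures.

The pipeline it implements:

1. **Effect size per dataset** — the ln-RMA slope
   `b = ln( sign(r) · SD(ln male DT) / SD(ln female DT) )` of log male on
   log female development time across treatments (`b = 0`: proportional
   responses; `b < 0`: females more thermally sensitive; `b > 0`: males).
   Plus the sexual development time dimorphism
   `SDTD = (longer sex)/(shorter sex) − 1` (signed + when females develop
   longer), the male–female log-scale correlation, and the gradient length.
2. **Sampling variance** — a uniform-draw bootstrap around each reported
   treatment mean, width set by its standard error; weight = `boot_sd^-2`.
3. **Phylogenetic multilevel meta-analysis** — REML fit of
   `y_i = μ [+ β·SDTD_i] + u_species + s_study + o_i + e_i`, with species
   effects correlated by the Brownian-motion matrix of a supplied phylogeny
   (Grafen branch lengths if the tree is topology-only) and known sampling
   variances; variance partition across the three components; per-order
   subgroup tables with Holm correction.
4. **Permutation inference** — sex-label swaps within treatments for the
   pooled mean, moderator shuffles for the SDTD effect, and an exact paired
   sign-flip test comparing temperature- against diet-induced sex
   differences in |standardized ln-slope|.
5. **Synthetic corpora** — a generator stating the corpus structure the
   analysis assumes (2–11 treatments averaging 4, ~3.27-fold thermal vs
   ~1.28-fold diet gradients, phylogenetic signal in true slopes), so the
   whole pipeline is testable offline.

## Worked example

```r
library(sexplast)

# a self-contained simulated analysis: 12 species, two datasets each,
# paired diet data, fast permutation settings
cfg <- list(
  simulate = sim_config(n_species = 12,
                        datasets_per_species = function(n) rep(2L, n)),
  seed = 42, paired = TRUE, n_orders = 2,
  boot = list(n_reps = 300),
  perms = list(n_perms = 499, recompute_var = FALSE))
bundle <- run_pipeline(cfg)
bundle
#> <report_bundle> 48 effects (0 flagged)
#>   total DT: pooled ln-slope -0.0471, permutation p = 0.258, phylo share 54%
#>     SDTD moderator: -0.2715, permutation p = 0.306
#>   paired temp vs diet: mean diff 0.1420, p = 0.0083 (2 of 12 species temp-larger)
```

Reading: the pooled ln-slope is statistically indistinguishable from zero
(the sexes respond near-proportionally to temperature; with only 12 species
the point estimate wanders), SDTD does not significantly moderate it, and
diet induces larger sex differences than temperature in 10 of the 12
species (mean paired difference +0.142 in |standardized ln-slope|,
sign-flip p = 0.0083) — the qualitative pattern the generator's defaults
encode. A single dataset:

```r
d <- primary_dataset("d1", "s1", "Pieris_rapae", "Lepidoptera",
  records = data.frame(treatment_value = c(15, 20, 25, 30),
                       male_mean = c(40, 30, 22, 17), male_se = c(1, .8, .6, .5),
                       female_mean = c(44, 33, 24, 18), female_se = c(1, .9, .7, .5)))
rma_ln_slope(d)  # $ln_slope -0.0414, $r_mf 0.9997: females slightly more plastic
sdtd(d)          # 0.0874: females develop ~9% longer on average
bootstrap_slope_sd(d, boot_config(n_reps = 1000, seed = 1))$boot_sd  # 0.0558
```

Input CSV schema (see `default_dialect()` to remap): one row per
(dataset, treatment) with columns `dataset_id, study_id, species,
order_name, trait {total|larval}, factor {temperature|diet},
treatment_value, male_mean_dt, male_se, female_mean_dt, female_se`. Trees
are Newick (`read_tree()`); species absent from the tree can be mapped to
congeneric tips via a mapping CSV (`resolve_species()`).

A command-line front end with `simulate`, `effects` and `run-all`
subcommands lives in `inst/scripts/sexplast-cli.R`.

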