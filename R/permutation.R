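#' @title Permutation-based inference
#' @name permutation
#' @description
#' Because the bootstrap-derived weights make the null distribution of the
#' meta-analytic z statistic non-Gaussian, significance is assessed against
#' permutation reference distributions: (i) for the pooled mean, male and
#' female values (means with their SEs) are swapped with probability 1/2
#' independently within each treatment of each dataset — the ln-slope is
#' exactly antisymmetric under a full swap; (ii) for the SDTD moderator, the
#' dataset-level SDTD values are shuffled across effect sizes; (iii) the
#' paired temperature-versus-diet comparison uses within-species sign flips
#' of the difference in absolute standardized ln-slopes.
NULL

#' Permutation configuration
#'
#' @param n_perms Number of permutation replicates (default 10000).
#' @param seed Integer seed recorded in outputs.
#' @param two_sided Two-sided p (default TRUE).
#' @param recompute_var Recompute bootstrap variances in each overall-test
#'   replicate (`TRUE`, the literal reading of permuting "together with
#'   corresponding standard error values") or reuse the observed ones
#'   (`FALSE`, the fast null; valid because the bootstrap SD is sex-swap
#'   invariant in distribution).
#' @param boot_cfg [boot_config()] used when `recompute_var = TRUE`.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_perms = 10000L, seed = 1L, two_sided = TRUE,
                        recompute_var = TRUE, boot_cfg = boot_config()) {
  stopifnot(n_perms >= 99L)
  structure(list(n_perms = as.integer(n_perms), seed = as.integer(seed),
                 two_sided = isTRUE(two_sided),
                 recompute_var = isTRUE(recompute_var), boot_cfg = boot_cfg),
            class = "perm_config")
}

#' Randomly swap the sexes within each treatment of a dataset
#'
#' Independently per treatment, with probability 1/2 the male and female
#' means (and their SEs) trade places; everything else is untouched.
#'
#' @param ds A [primary_dataset].
#' @param swap Optional logical vector of length k forcing the swap pattern
#'   (for enumeration); default: random fair coin per treatment.
#' @return The permuted `primary_dataset`.
#' @export
sex_permute_dataset <- function(ds, swap = NULL) {
  k <- ds$k
  if (is.null(swap)) swap <- stats::runif(k) < 0.5
  stopifnot(length(swap) == k)
  r <- ds$records
  mm <- r$male_mean; ms <- r$male_se
  r$male_mean[swap] <- r$female_mean[swap]
  r$male_se[swap] <- r$female_se[swap]
  r$female_mean[swap] <- mm[swap]
  r$female_se[swap] <- ms[swap]
  ds$records <- r
  ds
}

# two-sided (or one-sided) permutation p with the +1 correction
perm_p <- function(z_obs, z_null, two_sided = TRUE) {
  z_null <- z_null[is.finite(z_null)]
  if (two_sided) {
    (1 + sum(abs(z_null) >= abs(z_obs) - 1e-12)) / (1 + length(z_null))
  } else {
    (1 + sum(z_null >= z_obs - 1e-12)) / (1 + length(z_null))
  }
}

#' Permutation test of the pooled mean ln-slope
#'
#' Each replicate sex-permutes every dataset, recomputes the ln-slopes (and,
#' unless `cfg$recompute_var` is off, the bootstrap variances), refits the
#' no-moderator model and records the z statistic.
#'
#' @param datasets List of quantitative [primary_dataset] objects.
#' @param corr [phylo_correlation()] or `NULL`.
#' @param cfg A [perm_config()].
#' @param effects Optional precomputed effect table (with `boot_sd`) for
#'   these datasets; computed if missing.
#' @param max_fail_frac Abort if more than this fraction of replicate fits
#'   fail (default 0.01).
#' @return List with `z_obs`, `p_perm`, `null_z`, the observed `fit`, and
#'   `n_failed`.
#' @export
permutation_test_overall <- function(datasets, corr = NULL, cfg = perm_config(),
                                     effects = NULL, max_fail_frac = 0.01) {
  set.seed(cfg$seed)
  if (is.null(effects)) {
    effects <- compute_effects(datasets)$effects
    effects <- attach_uncertainty(effects, datasets, cfg$boot_cfg)$effects
  }
  fit <- fit_meta(effects, corr)
  # observed statistic through the exact same optimizer map as the null
  # replicates, so the permutation comparison is like-with-like
  z_obs <- refit_meta(fit, fit$model$y)
  ord <- match(effects$dataset_id, vapply(datasets, `[[`, "", "dataset_id"))
  null_z <- rep(NA_real_, cfg$n_perms)
  n_failed <- 0L
  for (b in seq_len(cfg$n_perms)) {
    y <- numeric(nrow(effects))
    v_new <- effects$boot_sd
    bad <- FALSE
    for (i in seq_len(nrow(effects))) {
      d <- sex_permute_dataset(datasets[[ord[i]]])
      sl <- tryCatch(rma_ln_slope(d), sexplast_undefined_slope = function(e) e)
      if (inherits(sl, "condition")) { bad <- TRUE; break }
      y[i] <- sl$ln_slope
      if (cfg$recompute_var) {
        bs <- tryCatch(bootstrap_slope_sd(d, cfg$boot_cfg, use_seed = FALSE),
                       error = function(e) NULL)
        if (is.null(bs)) { bad <- TRUE; break }
        v_new[i] <- bs$boot_sd
      }
    }
    if (bad) { n_failed <- n_failed + 1L; next }
    f <- fit
    f$model$v <- v_new^2
    z <- tryCatch(refit_meta(f, y), error = function(e) NULL)
    if (is.null(z)) { n_failed <- n_failed + 1L; next }
    null_z[b] <- z
  }
  if (n_failed > max_fail_frac * cfg$n_perms)
    stop("permutation test unstable: ", n_failed, " of ", cfg$n_perms,
         " replicate fits failed")
  p <- perm_p(z_obs, null_z, cfg$two_sided)
  fit$p_perm <- p
  list(z_obs = z_obs, p_perm = p, null_z = null_z[!is.na(null_z)],
       fit = fit, n_failed = n_failed, seed = cfg$seed)
}

#' Permutation test of the SDTD moderator
#'
#' The observed statistic is the z of the moderator coefficient; null
#' replicates shuffle the dataset-level SDTD values across effect sizes,
#' keeping ln-slopes, variances and grouping fixed.
#'
#' @param effects Effect table with `boot_sd` and the moderator column.
#' @param corr [phylo_correlation()] or `NULL`.
#' @param cfg A [perm_config()].
#' @param moderator Moderator column name (default `"sdtd"`).
#' @param max_fail_frac As in [permutation_test_overall()].
#' @return List with `z_obs`, `beta_hat`, `p_perm`, `null_z`, `fit`.
#' @export
permutation_test_moderator <- function(effects, corr = NULL, cfg = perm_config(),
                                       moderator = "sdtd",
                                       max_fail_frac = 0.01) {
  set.seed(cfg$seed)
  mod <- effects[[moderator]]
  if (is.null(mod)) stop("moderator column '", moderator, "' not found")
  if (stats::sd(mod) == 0)
    stop("moderator '", moderator, "' is constant; permutation test refused")
  fit <- fit_meta(effects, corr, moderator = moderator)
  # same optimizer map for observed and permuted designs (like-with-like)
  z_obs <- refit_meta(fit, fit$model$y, X = fit$model$X)
  null_z <- rep(NA_real_, cfg$n_perms)
  n_failed <- 0L
  X <- fit$model$X
  for (b in seq_len(cfg$n_perms)) {
    Xb <- X
    Xb[, 2L] <- sample(mod)
    z <- tryCatch(refit_meta(fit, fit$model$y, X = Xb), error = function(e) NULL)
    if (is.null(z)) { n_failed <- n_failed + 1L; next }
    null_z[b] <- z
  }
  if (n_failed > max_fail_frac * cfg$n_perms)
    stop("moderator permutation unstable: ", n_failed, " of ", cfg$n_perms,
         " replicate fits failed")
  p <- perm_p(z_obs, null_z, cfg$two_sided)
  fit$p_perm <- p
  list(z_obs = z_obs, beta_hat = fit$beta_hat, p_perm = p,
       null_z = null_z[!is.na(null_z)], fit = fit, n_failed = n_failed,
       seed = cfg$seed)
}

#' Standardized absolute ln-slopes paired by species
#'
#' For species with both a temperature and a diet effect on the same
#' development-time trait, builds the paired records entering
#' [paired_temp_diet_test()]. `std_rule = "none"` uses the raw absolute
#' ln-slope; `"gradient_scaled"` multiplies by `ln(gradient_length)` — the
#' cumulative log male/female divergence across the observed gradient —
#' which compensates for thermal gradients being much longer than diet
#' gradients.
#'
#' @param effects Effect table containing both factors.
#' @param std_rule `"none"` (default) or `"gradient_scaled"`.
#' @return Data frame: species, trait, abs_std_slope_temp,
#'   abs_std_slope_diet, std_rule; one row per (species, trait) pair with a
#'   notice for trait mismatches. When a species contributes several
#'   datasets per factor+trait their absolute standardized slopes are
#'   averaged first.
#' @export
standardize_slopes <- function(effects, std_rule = c("none", "gradient_scaled")) {
  std_rule <- match.arg(std_rule)
  val <- abs(effects$ln_slope)
  if (std_rule == "gradient_scaled") val <- val * log(effects$gradient_length)
  eff <- cbind(effects[, c("species", "trait", "factor")], std = val)
  agg <- stats::aggregate(std ~ species + trait + factor, data = eff, FUN = mean)
  wide <- merge(agg[agg$factor == "temperature", c("species", "trait", "std")],
                agg[agg$factor == "diet", c("species", "trait", "std")],
                by = c("species", "trait"),
                suffixes = c("_temp", "_diet"))
  if (!nrow(wide)) stop("no species with both temperature and diet data on the same trait")
  data.frame(species = wide$species, trait = wide$trait,
             abs_std_slope_temp = wide$std_temp,
             abs_std_slope_diet = wide$std_diet,
             std_rule = std_rule, stringsAsFactors = FALSE)
}

#' Paired sign-flip test: temperature- versus diet-induced sex differences
#'
#' Statistic T = mean over species of (|standardized diet ln-slope| -
#' |standardized temperature ln-slope|); the null distribution randomly
#' flips the sign of each species' difference (a within-species label swap).
#' T > 0 means diet typically induces the larger sex difference.
#'
#' @param pairs Data frame from [standardize_slopes()].
#' @param cfg A [perm_config()].
#' @param exclude Character vector of species excluded as outliers (logged;
#'   results should be reported with and without).
#' @param exact Enumerate all 2^n sign patterns instead of sampling
#'   (feasible for n <= 20; default automatic for n <= 12).
#' @return List with `mean_diff`, `p_perm`, `n_pairs`,
#'   `n_temp_larger` (species whose temperature response shows the larger
#'   sex difference), `table`, `excluded`.
#' @export
paired_temp_diet_test <- function(pairs, cfg = perm_config(), exclude = character(),
                                  exact = NULL) {
  keep <- !(pairs$species %in% exclude)
  excluded <- pairs$species[!keep]
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 2L) stop("fewer than 2 species pairs after exclusions")
  d <- pairs$abs_std_slope_diet - pairs$abs_std_slope_temp
  t_obs <- mean(d)
  if (is.null(exact)) exact <- n <= 12L
  if (exact) {
    # full enumeration of the 2^n sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- as.vector(signs %*% d) / n
    p <- if (cfg$two_sided) mean(abs(t_null) >= abs(t_obs) - 1e-12)
         else mean(t_null >= t_obs - 1e-12)
  } else {
    set.seed(cfg$seed)
    t_null <- replicate(cfg$n_perms,
                        mean(d * sample(c(-1, 1), n, replace = TRUE)))
    p <- perm_p(t_obs, t_null, cfg$two_sided)
  }
  tab <- cbind(pairs, diff = d, larger_factor = ifelse(d > 0, "diet",
                                                       ifelse(d < 0, "temperature", "tie")))
  list(mean_diff = t_obs, p_perm = p, n_pairs = n,
       n_temp_larger = sum(d < 0), table = tab, excluded = excluded,
       exact = exact)
}
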