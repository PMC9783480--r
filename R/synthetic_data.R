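#' @title Synthetic corpora with the structure of the literature data
#' @name synthetic_data
#' @description
#' Generates phylogenies and treatment-level development-time corpora with
#' the statistical features the analysis assumes: development time falls
#' monotonically with rearing temperature in both sexes, male and female
#' responses are near-proportional on the log scale, species-level true
#' ln-slopes carry phylogenetic signal plus study- and observation-level
#' heterogeneity, reported means come with relative standard errors, and
#' diet-factor datasets have shorter gradients and wider slope dispersion.
#' Every corpus ships its generating parameters so recovery tests can read
#' the truth.
NULL

#' Simulation configuration
#'
#' Defaults state the corpus the generator emulates: 2-11 treatments per
#' dataset averaging 4; thermal gradients spanning a ~3.27-fold change in
#' development time versus ~1.28-fold for diet; SDTD centred slightly above
#' zero so roughly 69% of datasets are female-longer; small relative SEs
#' (3%) yielding male-female log correlations >= 0.98 in ~95% of datasets.
#'
#' @param n_species Number of species.
#' @param datasets_per_species Sampler for the number of datasets a species
#'   contributes (function of n, returning integers >= 1).
#' @param k_sampler Sampler for the treatment count; default `2 + Binom(9,
#'   2/9)` giving support 2-11 with mean 4.
#' @param mu_true Grand mean ln-slope (default 0).
#' @param beta_true SDTD moderator effect (default 0).
#' @param sigma2_phylo,sigma2_study,sigma2_obs Variance components of the
#'   true ln-slopes.
#' @param sdtd_mean,sdtd_sd SDTD distribution (normal; default mean 0.05,
#'   sd 0.10).
#' @param temp_range Rearing temperature range, degrees C.
#' @param dt_ref Female development time (days) at the midpoint temperature.
#' @param log_gradient Total log fold-change of development time across the
#'   gradient (default `log(3.27)` for temperature).
#' @param diet_log_gradient As above for diet datasets (default `log(1.28)`).
#' @param se_rel Relative standard error of each treatment mean (default 0.03).
#' @param noise_rel Relative SD of the realized mean around the thermal
#'   curve (default = `se_rel`, i.e. means scatter by about one SE).
#' @param diet_slope_sd_mult Extra ln-slope dispersion multiplier for diet
#'   datasets (default 3).
#' @param trait `"total"` or `"larval"`.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 50L,
                       datasets_per_species = function(n) rep(1L, n),
                       k_sampler = function(n) 2L + stats::rbinom(n, 9L, 2 / 9),
                       mu_true = 0, beta_true = 0,
                       sigma2_phylo = 0.0015, sigma2_study = 0.0015,
                       sigma2_obs = 0.002,
                       sdtd_mean = 0.05, sdtd_sd = 0.10,
                       temp_range = c(12, 32), dt_ref = 30,
                       log_gradient = log(3.27),
                       diet_log_gradient = log(1.28),
                       se_rel = 0.03, noise_rel = se_rel,
                       diet_slope_sd_mult = 3,
                       trait = "total", seed = 1L) {
  stopifnot(n_species >= 2L, sigma2_phylo >= 0, sigma2_study >= 0,
            sigma2_obs >= 0, temp_range[2] > temp_range[1])
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Ultrametric Yule tree rescaled to unit depth, tips `sp_1 ... sp_n`.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Optional seed.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("sp_", seq_len(n_species))
  attr(tree, "has_branch_lengths") <- TRUE
  tree
}

#' Simulate species/dataset-level true ln-slopes
#'
#' Species effects are multivariate normal with covariance
#' `sigma2_phylo * A` (Brownian motion on the tree); each dataset adds a
#' study effect, an observation effect and the moderator contribution
#' `beta_true * SDTD`.
#'
#' @param tree Phylogeny covering the species.
#' @param cfg A [sim_config()]. The caller controls the RNG state.
#' @return Data frame with one row per dataset: dataset_id, study_id,
#'   species, true_ln_slope, true_sdtd, factor.
#' @export
simulate_true_slopes <- function(tree, cfg) {
  A <- phylo_correlation(tree)$matrix
  n_sp <- cfg$n_species
  u <- drop(crossprod(chol(A + diag(1e-10, n_sp)),
                      stats::rnorm(n_sp, 0, sqrt(cfg$sigma2_phylo))))
  names(u) <- colnames(A)
  n_ds <- cfg$datasets_per_species(n_sp)
  rows <- list()
  ds_i <- 0L
  for (i in seq_len(n_sp)) {
    sp <- tree$tip.label[i]
    # studies contribute up to two datasets each (mirrors multi-experiment
    # papers); shared study effects keep sigma2_study identifiable
    s_study <- stats::rnorm(ceiling(n_ds[i] / 2), 0, sqrt(cfg$sigma2_study))
    for (j in seq_len(n_ds[i])) {
      ds_i <- ds_i + 1L
      s <- s_study[ceiling(j / 2)]
      o <- stats::rnorm(1, 0, sqrt(cfg$sigma2_obs))
      sdtd_true <- stats::rnorm(1, cfg$sdtd_mean, cfg$sdtd_sd)
      rows[[ds_i]] <- data.frame(
        dataset_id = sprintf("ds_%04d", ds_i),
        study_id = sprintf("study_%s_%d", sp, ceiling(j / 2)),
        species = sp,
        true_ln_slope = cfg$mu_true + cfg$beta_true * sdtd_true +
          u[sp] + s + o,
        true_sdtd = sdtd_true,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate one treatment-level primary dataset
#'
#' The female log development time follows a declining log-linear thermal
#' curve; the male curve is the female curve times the true slope (on the
#' log scale) plus a dimorphism offset realizing the requested SDTD at the
#' gradient midpoint. Observation noise perturbs each realized mean by a
#' relative SD of `noise_rel`; the reported SE is `se_rel * mean`.
#'
#' @param true_ln_slope True log RMA slope.
#' @param true_sdtd Target SDTD (signed; positive = female longer).
#' @param cfg A [sim_config()].
#' @param dataset_id,study_id,species,order_name Identifiers.
#' @param diet_mode Diet dataset: shorter gradient, unordered labels.
#' @param k Number of treatments (default drawn from `cfg$k_sampler`).
#' @return A [primary_dataset].
#' @export
simulate_primary_dataset <- function(true_ln_slope, true_sdtd, cfg,
                                     dataset_id, study_id, species,
                                     order_name = "SimOrder",
                                     diet_mode = FALSE, k = NULL) {
  if (is.null(k)) k <- cfg$k_sampler(1L)
  k <- max(2L, k)
  lg <- if (diet_mode) cfg$diet_log_gradient else cfg$log_gradient
  tt <- seq(cfg$temp_range[1], cfg$temp_range[2], length.out = k)
  b <- lg / diff(cfg$temp_range)              # log-days lost per degree C
  t_mid <- mean(cfg$temp_range)
  lf <- log(cfg$dt_ref) - b * (tt - t_mid)    # female curve, decreasing in T
  slope <- exp(true_ln_slope)
  # male = slope * centred female curve + dimorphism offset at midpoint
  off <- if (true_sdtd >= 0) -log1p(true_sdtd) else log1p(-true_sdtd)
  lm_ <- log(cfg$dt_ref) + off + slope * (lf - log(cfg$dt_ref))
  lf <- lf + stats::rnorm(k, 0, cfg$noise_rel)
  lm_ <- lm_ + stats::rnorm(k, 0, cfg$noise_rel)
  f <- exp(lf); m <- exp(lm_)
  primary_dataset(
    dataset_id = dataset_id, study_id = study_id, species = species,
    order_name = order_name, trait = cfg$trait,
    factor = if (diet_mode) "diet" else "temperature",
    records = data.frame(
      treatment_value = if (diet_mode) seq_len(k) else tt,
      male_mean = m, male_se = cfg$se_rel * m,
      female_mean = f, female_se = cfg$se_rel * f))
}

#' Simulate a full corpus
#'
#' @param cfg A [sim_config()].
#' @param paired_diet Also generate one diet dataset per species (for the
#'   paired temperature-diet comparison); diet true ln-slopes get
#'   `diet_slope_sd_mult` times the dispersion.
#' @param n_orders Number of insect-order labels to spread over the species
#'   (contiguous blocks of the tip order, keeping orders clade-like).
#' @return List with `datasets` (named list of [primary_dataset]), `tree`,
#'   and `truth` (the generating parameters and per-dataset true values).
#' @export
simulate_corpus <- function(cfg, paired_diet = FALSE, n_orders = 1L) {
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species)
  truth <- simulate_true_slopes(tree, cfg)
  orders <- paste0("SimOrder", rep(seq_len(n_orders),
                                   length.out = cfg$n_species))
  names(orders) <- tree$tip.label
  datasets <- list()
  for (i in seq_len(nrow(truth))) {
    d <- simulate_primary_dataset(
      truth$true_ln_slope[i], truth$true_sdtd[i], cfg,
      dataset_id = truth$dataset_id[i], study_id = truth$study_id[i],
      species = truth$species[i], order_name = orders[truth$species[i]])
    datasets[[d$dataset_id]] <- d
  }
  if (paired_diet) {
    truth$true_diet_ln_slope <- NA_real_
    for (i in seq_len(nrow(truth))) {
      diet_slope <- cfg$mu_true +
        stats::rnorm(1, 0, cfg$diet_slope_sd_mult *
                       sqrt(cfg$sigma2_phylo + cfg$sigma2_study + cfg$sigma2_obs))
      id <- sub("^ds_", "dsdiet_", truth$dataset_id[i])
      d <- simulate_primary_dataset(
        diet_slope, truth$true_sdtd[i], cfg,
        dataset_id = id, study_id = paste0(truth$study_id[i], "_diet"),
        species = truth$species[i], order_name = orders[truth$species[i]],
        diet_mode = TRUE)
      datasets[[id]] <- d
      truth$true_diet_ln_slope[i] <- diet_slope
    }
  }
  list(datasets = datasets, tree = tree,
       truth = list(config = cfg, per_dataset = truth))
}

#' Simulate an effect-level corpus
#'
#' Shortcut for fit-level recovery tests: generates true ln-slopes on a
#' fresh tree and adds sampling noise with known variances directly, giving
#' an effect table ready for [fit_meta()] without treatment-level
#' simulation. The `boot_sd` column holds the true sampling SD.
#'
#' @param cfg A [sim_config()].
#' @param sampling_sd_range Range of per-effect sampling SDs, drawn
#'   log-uniformly (default 0.02-0.05).
#' @return List with `effects`, `corr` (the [phylo_correlation()]), `tree`
#'   and `truth`.
#' @export
simulate_effect_corpus <- function(cfg, sampling_sd_range = c(0.02, 0.05)) {
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species)
  truth <- simulate_true_slopes(tree, cfg)
  n <- nrow(truth)
  sd_i <- exp(stats::runif(n, log(sampling_sd_range[1]),
                           log(sampling_sd_range[2])))
  effects <- data.frame(
    dataset_id = truth$dataset_id, study_id = truth$study_id,
    species = truth$species, order_name = "SimOrder", trait = cfg$trait,
    factor = "temperature", k = 4L, has_se = TRUE,
    ln_slope = truth$true_ln_slope + stats::rnorm(n, 0, sd_i),
    r_mf = NA_real_, sdtd = truth$true_sdtd, gradient_length = 3.27,
    boot_sd = sd_i, weight = sd_i^-2, stringsAsFactors = FALSE)
  list(effects = effects, corr = phylo_correlation(tree), tree = tree,
       truth = list(config = cfg, per_dataset = truth))
}

#' Write a simulated corpus in the ingest CSV schema
#'
#' @param corpus Result of [simulate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`primary.csv`, `tree.nwk`,
#'   `truth.json`).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(corpus$datasets, function(d) {
    data.frame(dataset_id = d$dataset_id, study_id = d$study_id,
               species = d$species, order_name = d$order_name,
               trait = d$trait, factor = d$factor,
               treatment_value = d$records$treatment_value,
               male_mean_dt = d$records$male_mean, male_se = d$records$male_se,
               female_mean_dt = d$records$female_mean,
               female_se = d$records$female_se, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  p1 <- file.path(dir, "primary.csv")
  utils::write.csv(rows, p1, row.names = FALSE)
  p2 <- file.path(dir, "tree.nwk")
  ape::write.tree(corpus$tree, p2)
  p3 <- file.path(dir, "truth.json")
  truth <- corpus$truth
  truth$config <- truth$config[!vapply(truth$config, is.function, TRUE)]
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(primary = p1, tree = p2, truth = p3))
}
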