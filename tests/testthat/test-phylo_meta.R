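test_that("phylogenetic correlations: star, cherry, Grafen default, pruning", {
  p <- tempfile(fileext = ".nwk")
  writeLines("(A,B,C,D);", p)
  star <- read_tree(p)
  corr <- phylo_correlation(star)
  expect_equal(unname(corr$matrix), diag(4), tolerance = 1e-12)

  writeLines("((A:1,B:1):1,C:2);", p)
  tr <- read_tree(p)
  corr <- phylo_correlation(tr)
  expect_equal(corr$matrix["A", "B"], 0.5)
  expect_equal(corr$matrix["A", "C"], 0)
  expect_equal(diag(corr$matrix), c(A = 1, B = 1, C = 1))

  # topology-only input gets Grafen heights; pruning drops a tip
  writeLines("((A,B),(C,D));", p)
  tr <- read_tree(p)
  corr <- phylo_correlation(tr, tips = c("A", "B", "C"))
  expect_equal(corr$species, c("A", "B", "C"))
  expect_true(all(corr$matrix >= 0 & corr$matrix <= 1))
  expect_error(phylo_correlation(tr, tips = c("A", "Z")), "Z")
})

test_that("correlation matrix matches the path-enumeration oracle on a random tree", {
  set.seed(31)
  tr <- simulate_tree(20)
  corr <- phylo_correlation(tr)
  M <- oracle_phylo_corr(tr)
  expect_equal(corr$matrix[tr$tip.label, tr$tip.label], M, tolerance = 1e-10)
  ev <- eigen(corr$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("degenerate closed forms are exact", {
  # all y equal, variances forced to zero: mu = c exactly
  eff <- data.frame(dataset_id = letters[1:4], study_id = letters[1:4],
                    species = letters[1:4], ln_slope = rep(0.07, 4),
                    boot_sd = rep(0.03, 4), sdtd = c(0, 0.1, 0.2, 0.3))
  f <- fit_meta(eff, sigma2 = c(0, 0, 0))
  expect_equal(f$mu_hat, 0.07, tolerance = 1e-10)
  expect_equal(c(f$sigma2_phylo, f$sigma2_study, f$sigma2_obs), c(0, 0, 0))

  # two effects: inverse-variance weighted mean
  eff2 <- eff[1:2, ]; eff2$ln_slope <- c(0.1, -0.05); eff2$boot_sd <- c(0.02, 0.04)
  f2 <- fit_meta(eff2, sigma2 = c(0, 0, 0))
  w <- eff2$boot_sd^-2
  expect_equal(f2$mu_hat, sum(w * eff2$ln_slope) / sum(w), tolerance = 1e-10)
  expect_equal(f2$se_mu, sqrt(1 / sum(w)), tolerance = 1e-10)
})

test_that("REML agrees with an independent dense evaluation and beats a local grid", {
  set.seed(77)
  cfg <- sim_config(n_species = 5, datasets_per_species = function(n) rep(3L, n),
                    seed = 77)
  ec <- simulate_effect_corpus(cfg)
  f <- fit_meta(ec$effects, ec$corr)
  expect_true(f$converged)
  m <- f$model
  # same restricted likelihood by independent linear algebra
  ll_indep <- oracle_reml_ll(c(f$sigma2_phylo, f$sigma2_study, f$sigma2_obs),
                             m$y, m$X, m$Ap, m$As, m$v)
  expect_equal(f$loglik_reml, ll_indep, tolerance = 1e-6)
  # optimum at least as good as a coarse grid around plausible values
  grid <- exp(seq(log(1e-6), log(0.05), length.out = 25))
  best <- oracle_grid_best(m$y, m$X, m$Ap, m$As, m$v, grid, grid, grid)
  expect_gte(f$loglik_reml, best - 1e-6)
})

test_that("identity correlation reduces to the non-phylogenetic fit; shift equivariance", {
  set.seed(12)
  cfg <- sim_config(n_species = 6, datasets_per_species = function(n) rep(2L, n),
                    seed = 12)
  ec <- simulate_effect_corpus(cfg)
  sp <- unique(ec$effects$species)
  ident <- structure(list(species = sp,
                          matrix = diag(length(sp)) |>
                            (\(m) {dimnames(m) <- list(sp, sp); m})()),
                     class = "phylo_corr")
  f_id <- fit_meta(ec$effects, ident)
  f_null <- fit_meta(ec$effects, NULL)
  expect_equal(f_id$mu_hat, f_null$mu_hat, tolerance = 1e-6)
  expect_equal(f_id$loglik_reml, f_null$loglik_reml, tolerance = 1e-6)

  shifted <- ec$effects; shifted$ln_slope <- shifted$ln_slope + 0.5
  f0 <- fit_meta(ec$effects, ec$corr)
  f1 <- fit_meta(shifted, ec$corr)
  expect_equal(f1$mu_hat - f0$mu_hat, 0.5, tolerance = 1e-6)
  expect_equal(f1$sigma2_obs, f0$sigma2_obs, tolerance = 1e-6)
  expect_equal(f1$sigma2_study, f0$sigma2_study, tolerance = 1e-6)
})

test_that("moderator fit refuses singular designs and reports the tested coefficient", {
  set.seed(13)
  cfg <- sim_config(n_species = 6, datasets_per_species = function(n) rep(2L, n),
                    beta_true = 0.5, seed = 13)
  ec <- simulate_effect_corpus(cfg)
  f <- fit_meta(ec$effects, ec$corr, moderator = "sdtd")
  expect_false(is.na(f$beta_hat))
  expect_equal(f$z_stat, f$beta_hat / f$se_beta)
  bad <- ec$effects; bad$sdtd <- 0.2
  expect_error(fit_meta(bad, ec$corr, moderator = "sdtd"), "singular")
})

test_that("variance partition returns shares summing to one", {
  fake <- structure(list(sigma2_phylo = 0.01, sigma2_study = 0.02,
                         sigma2_obs = 0.07, converged = TRUE), class = "meta_fit")
  expect_equal(variance_partition(fake),
               c(phylo = 0.10, study = 0.20, obs = 0.70))
  fake$sigma2_phylo <- 0
  expect_equal(unname(variance_partition(fake)["phylo"]), 0)
  zero <- structure(list(sigma2_phylo = 0, sigma2_study = 0, sigma2_obs = 0,
                         converged = TRUE), class = "meta_fit")
  expect_true(all(is.na(variance_partition(zero))))
})

test_that("subgroup fits prune the tree per order and Holm-adjust table-wide", {
  set.seed(14)
  cfg <- sim_config(n_species = 9, datasets_per_species = function(n) rep(2L, n),
                    seed = 14)
  ec <- simulate_effect_corpus(cfg)
  ec$effects$order_name <- rep(paste0("Ord", 1:3), each = 6)
  sub <- subgroup_fits(ec$effects, ec$corr)
  expect_equal(nrow(sub$table), 4)   # 3 orders + all
  grp <- sub$table[sub$table$group != "all", ]
  expect_equal(grp$p_adjusted, oracle_holm(grp$p))
  expect_equal(sub$table$n[sub$table$group == "all"], 18)

  # single-group corpus: identical to the plain pooled fit
  ec$effects$order_name <- "Only"
  sub1 <- subgroup_fits(ec$effects, ec$corr)
  f_all <- fit_meta(ec$effects, ec$corr)
  expect_equal(sub1$table$mean_effect[1], f_all$mu_hat, tolerance = 1e-8)

  # frozen hand-computed Holm fixture
  expect_equal(oracle_holm(c(0.42, 0.72, 0.68, 0.51, 0.11, 0.66, 0.06)),
               c(1, 1, 1, 1, 0.66, 1, 0.42))
  expect_equal(stats::p.adjust(c(0.42, 0.72, 0.68, 0.51, 0.11, 0.66, 0.06), "holm"),
               c(1, 1, 1, 1, 0.66, 1, 0.42))
})
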