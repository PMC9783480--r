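test_that("pure-birth trees are ultrametric, unit depth, fully bifurcating", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  tr <- simulate_tree(50, seed = 2)
  expect_equal(tr$Nnode, 49)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 1, tolerance = 1e-9)
})

test_that("true slopes: zero variance collapses to mu; noiseless beta is exact", {
  cfg <- sim_config(n_species = 8, mu_true = 0.02, beta_true = 0,
                    sigma2_phylo = 0, sigma2_study = 0, sigma2_obs = 0, seed = 3)
  set.seed(3)
  tr <- simulate_tree(8)
  truth <- simulate_true_slopes(tr, cfg)
  expect_equal(truth$true_ln_slope, rep(0.02, 8), tolerance = 1e-12)

  cfg$beta_true <- 0.165
  truth2 <- simulate_true_slopes(tr, cfg)
  b <- coef(lm(true_ln_slope ~ true_sdtd, data = truth2))[2]
  expect_equal(unname(b), 0.165, tolerance = 1e-10)
})

test_that("species effects realize the phylogenetic covariance", {
  cfg <- sim_config(n_species = 6, sigma2_phylo = 0.04, sigma2_study = 0,
                    sigma2_obs = 0, sdtd_sd = 0, sdtd_mean = 0, seed = 4)
  set.seed(4)
  tr <- simulate_tree(6)
  A <- phylo_correlation(tr)$matrix
  U <- replicate(800, simulate_true_slopes(tr, cfg)$true_ln_slope)
  emp <- cov(t(U))
  # entrywise MC tolerance ~ 4 * sigma2 * sqrt(2/n_rep)
  expect_lt(max(abs(emp - 0.04 * A)), 4 * 0.04 * sqrt(2 / 800) + 0.004)
})

test_that("noiseless datasets recover the true slope exactly; curves decline", {
  cfg <- sim_config(n_species = 4, noise_rel = 0, seed = 5)
  set.seed(5)
  d0 <- simulate_primary_dataset(0, 0, cfg, "d0", "s", "sp", k = 5)
  sl <- rma_ln_slope(d0)
  expect_equal(sl$ln_slope, 0, tolerance = 1e-12)
  expect_equal(sl$r_mf, 1, tolerance = 1e-12)
  d1 <- simulate_primary_dataset(0.1, 0.05, cfg, "d1", "s", "sp", k = 6)
  expect_equal(rma_ln_slope(d1)$ln_slope, 0.1, tolerance = 1e-12)
  # monotone decline with temperature in both sexes
  expect_true(all(diff(d1$records$female_mean) < 0))
  expect_true(all(diff(d1$records$male_mean) < 0))
  # SDTD realized with the requested sign and size at slope 1
  expect_equal(sdtd(d0), 0, tolerance = 1e-12)
  d2 <- simulate_primary_dataset(0, 0.2, cfg, "d2", "s", "sp", k = 4)
  expect_equal(sdtd(d2), 0.2, tolerance = 1e-10)
  d3 <- simulate_primary_dataset(0, -0.2, cfg, "d3", "s", "sp", k = 4)
  expect_equal(sdtd(d3), -0.2, tolerance = 1e-10)
})

test_that("thermal and diet gradients hit the configured fold-changes", {
  cfg <- sim_config(n_species = 4, noise_rel = 0, seed = 6)
  set.seed(6)
  th <- simulate_primary_dataset(0, 0, cfg, "t", "s", "sp", k = 4)
  expect_equal(gradient_length(th), 3.27, tolerance = 1e-10)
  di <- simulate_primary_dataset(0, 0, cfg, "d", "s", "sp", diet_mode = TRUE, k = 4)
  expect_equal(gradient_length(di), 1.28, tolerance = 1e-10)
  expect_equal(di$factor, "diet")
})

test_that("treatment-count sampler has support 2-11 with mean about 4", {
  cfg <- sim_config(n_species = 4, seed = 7)
  set.seed(7)
  k <- cfg$k_sampler(20000)
  expect_true(all(k >= 2 & k <= 11))
  expect_equal(mean(k), 4, tolerance = 0.05)
})

test_that("corpora are seed-reproducible, serialize truth, and round-trip ingest", {
  cfg <- sim_config(n_species = 6, seed = 8)
  c1 <- simulate_corpus(cfg, paired_diet = TRUE, n_orders = 2)
  c2 <- simulate_corpus(cfg, paired_diet = TRUE, n_orders = 2)
  expect_identical(c1$datasets, c2$datasets)
  expect_equal(length(c1$datasets), 12)   # 6 thermal + 6 diet
  expect_true(all(c("true_ln_slope", "true_diet_ln_slope") %in%
                    names(c1$truth$per_dataset)))

  dir <- tempfile()
  paths <- write_corpus(c1, dir)
  res <- read_primary_table(paths["primary"])
  expect_length(res$datasets, 12)
  expect_equal(nrow(res$rejects), 0)
  back <- res$datasets[[c1$datasets[[1]]$dataset_id]]
  expect_equal(back$records$male_mean, c1$datasets[[1]]$records$male_mean,
               tolerance = 1e-12)
  tr <- read_tree(paths["tree"])
  expect_setequal(tr$tip.label, c1$tree$tip.label)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$config$mu_true, 0)
})

test_that("default noise yields the near-proportional log responses of real corpora", {
  cfg <- sim_config(n_species = 40,
                    datasets_per_species = function(n) rep(2L, n),
                    k_sampler = function(n) rep(5L, n), seed = 9)
  corpus <- simulate_corpus(cfg)
  eff <- compute_effects(corpus$datasets)$effects
  frac <- mean(eff$r_mf >= 0.98, na.rm = TRUE)
  expect_gte(frac, 0.85)   # calibrated to emulate roughly 95% observed
})
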