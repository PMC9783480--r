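test_that("sex permutation: forced swaps negate the slope, none is identity", {
  set.seed(41)
  d <- random_ds(4)
  sl <- rma_ln_slope(d)$ln_slope
  all_swap <- sex_permute_dataset(d, swap = rep(TRUE, 4))
  expect_identical(rma_ln_slope(all_swap)$ln_slope, -sl)
  none <- sex_permute_dataset(d, swap = rep(FALSE, 4))
  expect_identical(none$records, d$records)
})

test_that("random swap patterns are uniform over the 2^k possibilities", {
  set.seed(42)
  d <- make_ds(c(44, 33, 24), c(40, 30, 22),
               female_se = c(1, 1, 1), male_se = c(1, 1, 1))
  draws <- replicate(8000, {
    p <- sex_permute_dataset(d)
    sum(2^(0:2) * (p$records$male_mean != d$records$male_mean))
  })
  counts <- table(factor(draws, levels = 0:7))
  expect_length(counts, 8)
  chi2 <- sum((counts - 1000)^2 / 1000)
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("degenerate corpus (male = female everywhere) gives z 0 and p 1", {
  ds <- lapply(1:5, function(i) {
    f <- c(44, 33, 24) * (1 + 0.1 * i)
    make_ds(f, f, female_se = 0.02 * f, male_se = 0.02 * f,
            id = paste0("d", i), study = paste0("s", i),
            species = paste0("sp", i))
  })
  names(ds) <- paste0("d", 1:5)
  cfg <- perm_config(n_perms = 99, seed = 3, recompute_var = FALSE,
                     boot_cfg = boot_config(n_reps = 100, seed = 3))
  res <- permutation_test_overall(ds, corr = NULL, cfg = cfg)
  expect_equal(res$z_obs, 0, tolerance = 1e-6)
  expect_equal(res$p_perm, 1)
  expect_true(all(abs(res$null_z) < 1e-6))
})

test_that("permutation p respects the +1 floor and is seeded-deterministic", {
  set.seed(5)
  cfg_sim <- sim_config(n_species = 5, datasets_per_species = function(n) rep(2L, n),
                        mu_true = 0.3, sigma2_phylo = 0, sigma2_study = 0,
                        sigma2_obs = 1e-4, seed = 5)
  corpus <- simulate_corpus(cfg_sim)
  cfg <- perm_config(n_perms = 199, seed = 9, recompute_var = FALSE,
                     boot_cfg = boot_config(n_reps = 150, seed = 2))
  r1 <- permutation_test_overall(corpus$datasets, NULL, cfg)
  r2 <- permutation_test_overall(corpus$datasets, NULL, cfg)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$null_z, r2$null_z)
  expect_gte(r1$p_perm, 1 / 200)
  expect_lte(r1$p_perm, 1)
  # strong true effect: p at or near the attainable floor
  expect_lte(r1$p_perm, 0.05)
  # null distribution symmetric around zero in expectation
  expect_lt(abs(mean(r1$null_z)), 4 * sd(r1$null_z) / sqrt(length(r1$null_z)))
})

test_that("moderator permutation recovers a strong SDTD effect and refuses constants", {
  set.seed(6)
  cfg_sim <- sim_config(n_species = 20, datasets_per_species = function(n) rep(2L, n),
                        beta_true = 1.2, sigma2_phylo = 1e-5,
                        sigma2_study = 1e-5, sigma2_obs = 1e-5, seed = 6)
  ec <- simulate_effect_corpus(cfg_sim)
  res <- permutation_test_moderator(ec$effects, ec$corr,
                                    perm_config(n_perms = 199, seed = 4))
  expect_equal(res$beta_hat, 1.2, tolerance = 0.15)
  expect_lte(res$p_perm, 0.05)
  bad <- ec$effects; bad$sdtd <- 0.1
  expect_error(permutation_test_moderator(bad, ec$corr), "constant")
})

test_that("overall test is exact under its own null (sex-exchangeable corpora)", {
  # sharp null: no dimorphism, no true-slope heterogeneity; within-treatment
  # sex swaps are then a true symmetry and the size must be nominal. (Under
  # correlated slope heterogeneity with mu = 0 the swap null understates the
  # corpus-mean variance and the test over-rejects; that robustness failure
  # is measured and documented by the acceptance suite.)
  p <- vapply(1:60, function(r) {
    cfg <- sim_config(n_species = 6, datasets_per_species = function(n) rep(3L, n),
                      mu_true = 0, sigma2_phylo = 0, sigma2_study = 0,
                      sigma2_obs = 0, sdtd_mean = 0, sdtd_sd = 0,
                      seed = 200000L + r)
    corpus <- simulate_corpus(cfg)
    pcfg <- perm_config(n_perms = 99L, seed = 300000L + r, recompute_var = FALSE,
                        boot_cfg = boot_config(n_reps = 150L, seed = 400000L + r))
    permutation_test_overall(corpus$datasets, phylo_correlation(corpus$tree),
                             pcfg)$p_perm
  }, numeric(1))
  expect_lte(sum(p <= 0.05), qbinom(0.995, 60, 0.05))
})

test_that("standardization rules: zero slope stays zero, gradient scaling multiplies", {
  eff <- data.frame(species = rep(c("A", "B"), each = 2),
                    trait = "total",
                    factor = rep(c("temperature", "diet"), 2),
                    ln_slope = c(0, 0.05, 0.1, -0.3),
                    gradient_length = c(3.27, 1.3, exp(2), 1.3))
  p0 <- standardize_slopes(eff, "none")
  expect_equal(p0$abs_std_slope_temp[p0$species == "A"], 0)
  expect_equal(p0$abs_std_slope_diet[p0$species == "B"], 0.3)
  pg <- standardize_slopes(eff, "gradient_scaled")
  expect_equal(pg$abs_std_slope_temp[pg$species == "B"], 0.1 * 2)
  # trait mismatch: no pair
  eff2 <- eff; eff2$trait <- c("total", "larval", "total", "larval")
  expect_error(standardize_slopes(eff2), "no species")
})

test_that("paired sign-flip test: ties give p 1; MC matches exact enumeration", {
  pairs <- data.frame(species = letters[1:5], trait = "total",
                      abs_std_slope_temp = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      abs_std_slope_diet = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      std_rule = "none")
  res <- paired_temp_diet_test(pairs, perm_config(n_perms = 99, seed = 1))
  expect_equal(res$mean_diff, 0)
  expect_equal(res$p_perm, 1)

  set.seed(50)
  pairs10 <- data.frame(species = letters[1:10], trait = "total",
                        abs_std_slope_temp = runif(10, 0, 0.3),
                        abs_std_slope_diet = runif(10, 0, 0.6),
                        std_rule = "none")
  ex <- paired_temp_diet_test(pairs10, exact = TRUE)
  mc <- paired_temp_diet_test(pairs10, perm_config(n_perms = 4000, seed = 2),
                              exact = FALSE)
  tol <- 3 * sqrt(ex$p_perm * (1 - ex$p_perm) / 4000) + 1 / 4000
  expect_lt(abs(mc$p_perm - ex$p_perm), tol + 1e-12)

  # exclusions are honoured and logged
  res_ex <- paired_temp_diet_test(pairs10, exclude = "a", exact = TRUE)
  expect_equal(res_ex$n_pairs, 9)
  expect_equal(res_ex$excluded, "a")
  expect_error(paired_temp_diet_test(pairs10[1, ], exact = TRUE), "fewer than 2")
})
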