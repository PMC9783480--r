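#' @title End-to-end analysis pipeline
#' @name pipeline
NULL

#' Run the full meta-analytic pipeline
#'
#' Ingest (or simulate) -> effect sizes -> bootstrap weights -> per-trait
#' pooled and SDTD-moderated fits with permutation p-values -> per-order
#' subgroup table -> diagnostics -> optional paired temperature-diet test,
#' with a reproducibility manifest. Total and larval development time are
#' analyzed as separate corpora throughout.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{simulate}{a [sim_config()] (self-contained mode), or}
#'     \item{primary,tree,mapping}{file paths for CSV/Newick/mapping inputs}
#'     \item{seed}{master seed; per-stage seeds derive from it}
#'     \item{boot}{arguments for [boot_config()]}
#'     \item{perms}{arguments for [perm_config()] (`n_perms` etc.)}
#'     \item{paired}{`TRUE` to run the paired temperature-diet test}
#'     \item{exclude_species}{outlier species excluded from the paired test}
#'     \item{std_rule}{standardization rule for the paired test}
#'     \item{out_dir}{optional directory for CSV/JSON reports}
#'   }
#' @return A `report_bundle` list: effects table, per-trait fits and
#'   permutation tests, subgroup tables, diagnostics, paired test, manifest.
#' @export
run_pipeline <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("sexplast")),
                   stages = list())
  t0 <- Sys.time()

  # -- ingest or simulate -----------------------------------------------------
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    cfg$seed <- seed
    corpus <- simulate_corpus(cfg, paired_diet = isTRUE(config$paired),
                              n_orders = if (is.null(config$n_orders)) 1L
                                         else config$n_orders)
    datasets <- corpus$datasets; tree <- corpus$tree
    manifest$stages$ingest <- list(mode = "simulate",
                                   n_datasets = length(datasets))
  } else {
    ing <- read_primary_table(config$primary,
                              dialect = if (is.null(config$dialect))
                                default_dialect() else config$dialect)
    tree <- read_tree(config$tree)
    mapping <- if (!is.null(config$mapping))
      utils::read.csv(config$mapping, stringsAsFactors = FALSE) else NULL
    res <- resolve_species(ing$datasets, tree, mapping,
                           strict = !isFALSE(config$strict))
    datasets <- res$datasets
    manifest$stages$ingest <- list(
      mode = "files", n_rows = ing$n_rows, n_rejected_rows = nrow(ing$rejects),
      n_datasets = length(datasets), unmapped = res$unmapped,
      primary_sha = unname(tools::md5sum(config$primary)))
  }

  incl <- apply_inclusion_rules(datasets)
  manifest$stages$inclusion <- list(
    quantitative = length(incl$included), qualitative = length(incl$qualitative),
    excluded = nrow(incl$excluded))

  # -- effect sizes and weights ----------------------------------------------
  all_ds <- c(incl$included, incl$qualitative)
  eff_all <- compute_effects(all_ds)
  boot_args <- if (is.null(config$boot)) list() else config$boot
  boot_args$seed <- seed + 1L
  bcfg <- do.call(boot_config, boot_args)
  quant_ids <- names(incl$included)
  eff <- attach_uncertainty(eff_all$effects, all_ds, bcfg)
  effects <- eff$effects
  manifest$stages$effects <- list(
    n_effects = nrow(effects), n_flagged = nrow(eff_all$flagged),
    boot = bcfg[c("n_reps", "width_rule", "seed")])

  diagnostics <- corpus_diagnostics(effects)

  # -- per-trait fits and permutation tests ----------------------------------
  perm_args <- if (is.null(config$perms)) list() else config$perms
  perm_args$boot_cfg <- bcfg
  fits <- list()
  for (trait in unique(effects$trait)) {
    e <- effects[effects$trait == trait & !is.na(effects$boot_sd) &
                   effects$factor == "temperature", , drop = FALSE]
    if (nrow(e) < 2L) next
    corr <- phylo_correlation(tree, unique(e$species))
    pa <- perm_args; pa$seed <- seed + 100L + match(trait, c("total", "larval"))
    pcfg <- do.call(perm_config, pa)
    overall <- permutation_test_overall(datasets[e$dataset_id], corr,
                                        cfg = pcfg, effects = e)
    moderated <- if (stats::sd(e$sdtd) > 0)
      permutation_test_moderator(e, corr, cfg = pcfg) else NULL
    sub <- subgroup_fits(e, corr)
    fits[[trait]] <- list(overall = overall, moderated = moderated,
                          subgroups = sub,
                          variance_shares = variance_partition(overall$fit))
  }

  # -- paired temperature vs diet --------------------------------------------
  paired <- NULL
  if (any(effects$factor == "diet")) {
    std_rule <- if (is.null(config$std_rule)) "none" else config$std_rule
    pairs <- standardize_slopes(effects, std_rule)
    pa <- perm_args; pa$seed <- seed + 200L
    paired <- paired_temp_diet_test(
      pairs, cfg = do.call(perm_config, pa),
      exclude = if (is.null(config$exclude_species)) character()
                else config$exclude_species)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  bundle <- structure(list(effects = effects, diagnostics = diagnostics,
                           fits = fits, paired = paired,
                           inclusion = incl["excluded"],
                           qc = eff$qc, flagged = eff_all$flagged,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_effect_table(bundle$effects, file.path(dir, "effects.csv"))
  summarize_fit <- function(tr) {
    f <- tr$overall$fit
    out <- list(mu_hat = f$mu_hat, se_mu = f$se_mu, z = f$z_stat,
                p_perm = f$p_perm, sigma2_phylo = f$sigma2_phylo,
                sigma2_study = f$sigma2_study, sigma2_obs = f$sigma2_obs,
                phylo_var_share = f$phylo_var_share, n = f$n_effects)
    if (!is.null(tr$moderated))
      out$moderator <- list(beta_hat = tr$moderated$beta_hat,
                            p_perm = tr$moderated$p_perm)
    out$subgroups <- tr$subgroups$table
    out
  }
  report <- list(fits = lapply(bundle$fits, summarize_fit),
                 diagnostics = bundle$diagnostics[c("r_mf", "sdtd_signs", "gradient")],
                 manifest = bundle$manifest)
  if (!is.null(bundle$paired))
    report$paired <- bundle$paired[c("mean_diff", "p_perm", "n_pairs",
                                     "n_temp_larger", "excluded")]
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  for (trait in names(bundle$fits))
    utils::write.csv(bundle$fits[[trait]]$subgroups$table,
                     file.path(dir, paste0("subgroups_", trait, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d effects (%d flagged)\n",
              nrow(x$effects), nrow(x$flagged)))
  for (trait in names(x$fits)) {
    f <- x$fits[[trait]]$overall$fit
    cat(sprintf("  %s DT: pooled ln-slope %.4f, permutation p = %.3g, phylo share %.0f%%\n",
                trait, f$mu_hat, f$p_perm, 100 * f$phylo_var_share))
    m <- x$fits[[trait]]$moderated
    if (!is.null(m))
      cat(sprintf("    SDTD moderator: %.4f, permutation p = %.3g\n",
                  m$beta_hat, m$p_perm))
  }
  if (!is.null(x$paired))
    cat(sprintf("  paired temp vs diet: mean diff %.4f, p = %.3g (%d of %d species temp-larger)\n",
                x$paired$mean_diff, x$paired$p_perm, x$paired$n_temp_larger,
                x$paired$n_pairs))
  invisible(x)
}
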