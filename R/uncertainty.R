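#' @title Bootstrap sampling variances and meta-analytic weights
#' @name uncertainty
#' @description
#' The sampling variance of each ln-slope is estimated by a parametric
#' bootstrap on the reported treatment means: every (sex, treatment) mean is
#' replaced by a draw from a uniform distribution centred on it whose width
#' is set by the reported standard error, the ln-slope is recomputed, and the
#' standard deviation over replicates is the variability estimate. Its
#' squared inverse is the meta-analytic weight.
NULL

#' Bootstrap configuration
#'
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param width_rule `"sd_matched"` (default): uniform on
#'   `[m - sqrt(3)*SE, m + sqrt(3)*SE]`, so the draw's SD equals the reported
#'   SE; `"half_width_se"`: uniform on `[m - SE, m + SE]`.
#' @param seed Integer seed recorded in all outputs.
#' @param degenerate_floor Minimum boot SD (default 1e-8), preventing
#'   infinite weights when all SEs are (near) zero.
#' @param max_reject_frac Abort when more than this fraction of replicates
#'   yields an undefined slope (default 0.5).
#' @return A `boot_config` list.
#' @export
boot_config <- function(n_reps = 1000L, width_rule = c("sd_matched", "half_width_se"),
                        seed = 1L, degenerate_floor = 1e-8,
                        max_reject_frac = 0.5) {
  width_rule <- match.arg(width_rule)
  stopifnot(n_reps >= 2L, degenerate_floor >= 0)
  structure(list(n_reps = as.integer(n_reps), width_rule = width_rule,
                 seed = as.integer(seed), degenerate_floor = degenerate_floor,
                 max_reject_frac = max_reject_frac),
            class = "boot_config")
}

# half-width of the uniform draw for a vector of SEs
uniform_half_width <- function(se, width_rule) {
  switch(width_rule, sd_matched = sqrt(3) * se, half_width_se = se,
         stop("unknown width_rule: ", width_rule))
}

#' Bootstrap SD and weight of a dataset's ln-slope
#'
#' Replicates with an undefined slope (sign flip or zero spread under the
#' perturbation) are redrawn so exactly `n_reps` values contribute; the
#' redraw count is returned for QC. All-zero SEs make every replicate
#' reproduce the observed slope, giving boot SD 0, floored to
#' `degenerate_floor`.
#'
#' @param ds A [primary_dataset] with `has_se = TRUE`.
#' @param cfg A [boot_config()]. The caller controls the RNG state; set
#'   `use_seed = TRUE` to seed from `cfg$seed` locally.
#' @param use_seed Seed the RNG from `cfg$seed` before drawing.
#' @return List with `boot_sd`, `weight` (= boot_sd^-2), `n_rejected`,
#'   `seed`, `width_rule`.
#' @export
bootstrap_slope_sd <- function(ds, cfg = boot_config(), use_seed = TRUE) {
  if (!ds$has_se)
    stop("dataset '", ds$dataset_id,
         "' lacks standard errors (qualitative-only); bootstrap refused")
  if (use_seed) set.seed(cfg$seed)
  f <- ds$records$female_mean; m <- ds$records$male_mean
  hf <- uniform_half_width(ds$records$female_se, cfg$width_rule)
  hm <- uniform_half_width(ds$records$male_se, cfg$width_rule)
  k <- length(f)
  B <- cfg$n_reps
  slopes <- numeric(B)
  filled <- 0L; rejected <- 0L
  max_reject <- ceiling(cfg$max_reject_frac * B) + B
  while (filled < B) {
    todo <- B - filled
    # vectorised block of draws: k x todo matrices per sex
    fm <- f + hf * matrix(stats::runif(k * todo, -1, 1), k, todo)
    mm <- m + hm * matrix(stats::runif(k * todo, -1, 1), k, todo)
    ok <- colSums(fm <= 0 | mm <= 0) == 0L
    lx <- log(fm); ly <- log(mm)
    cx <- lx - matrix(colMeans(lx), k, todo, byrow = TRUE)
    cy <- ly - matrix(colMeans(ly), k, todo, byrow = TRUE)
    sxx <- colSums(cx * cx); syy <- colSums(cy * cy); sxy <- colSums(cx * cy)
    ok <- ok & sxx > 0 & syy > 0 & sxy > 0
    nok <- sum(ok)
    if (nok) {
      slopes[filled + seq_len(nok)] <- 0.5 * (log(syy[ok]) - log(sxx[ok]))
      filled <- filled + nok
    }
    rejected <- rejected + (todo - nok)
    if (rejected > max_reject)
      stop("bootstrap unstable for dataset '", ds$dataset_id,
           "': more than ", 100 * cfg$max_reject_frac, "% of replicates undefined")
  }
  if (rejected > cfg$max_reject_frac * B)
    stop("bootstrap unstable for dataset '", ds$dataset_id,
         "': more than ", 100 * cfg$max_reject_frac, "% of replicates undefined")
  boot_sd <- stats::sd(slopes)
  boot_sd <- max(boot_sd, cfg$degenerate_floor)
  list(boot_sd = boot_sd, weight = boot_sd^-2, n_rejected = rejected,
       seed = cfg$seed, width_rule = cfg$width_rule)
}

#' Attach bootstrap SDs and weights to an effect-size table
#'
#' Quantitative datasets get `boot_sd` and `weight` filled; qualitative-only
#' datasets are left missing. Each dataset's bootstrap is seeded
#' deterministically from `cfg$seed` and the dataset's position so reruns
#' with the same configuration are bit-identical.
#'
#' @param effects Effect-size data frame from [compute_effects()].
#' @param datasets The list of [primary_dataset] objects it came from.
#' @param cfg A [boot_config()].
#' @return List with the completed `effects` table and a `qc` data frame
#'   (per-dataset rejected-replicate counts).
#' @export
attach_uncertainty <- function(effects, datasets, cfg = boot_config()) {
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  qc <- list()
  for (i in seq_len(nrow(effects))) {
    id <- effects$dataset_id[i]
    j <- match(id, ids)
    if (is.na(j)) stop("effect row '", id, "' has no matching dataset")
    d <- datasets[[j]]
    if (!d$has_se) next
    sub_cfg <- cfg
    sub_cfg$seed <- (cfg$seed + 104729L * i) %% .Machine$integer.max
    res <- bootstrap_slope_sd(d, sub_cfg, use_seed = TRUE)
    effects$boot_sd[i] <- res$boot_sd
    effects$weight[i] <- res$weight
    qc[[id]] <- data.frame(dataset_id = id, n_rejected = res$n_rejected,
                           seed = sub_cfg$seed, stringsAsFactors = FALSE)
  }
  list(effects = effects,
       qc = if (length(qc)) do.call(rbind, qc) else
         data.frame(dataset_id = character(), n_rejected = integer(),
                    seed = integer()))
}
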