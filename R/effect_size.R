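#' @title Dataset-level effect sizes: ln-RMA slope, SDTD, diagnostics
#' @name effect_size
#' @description
#' The effect size for each primary dataset is the natural log of the reduced
#' major axis (RMA) regression slope of ln(male development time) on
#' ln(female development time) across treatments. An ln-slope of 0 means the
#' two sexes respond proportionally; ln-slope < 0 means females are the
#' thermally more sensitive sex, > 0 males. Accompanying diagnostics are the
#' sexual development time dimorphism (SDTD, Lovich-Gibbons style signed
#' ratio), the male-female Pearson correlation on the log scale, and the
#' gradient length (fold-change between the largest and smallest mean in the
#' dataset).
NULL

#' ln-RMA slope of male on female log development time
#'
#' The RMA slope is sign(cor(x, y)) * SD(y)/SD(x) with x = ln(female mean),
#' y = ln(male mean); for k = 2 it degenerates to the exact two-point ratio
#' |dy|/|dx| signed by the product of the differences. The SD ratio is
#' denominator-invariant, so population or sample SDs give the same slope.
#'
#' @param ds A [primary_dataset].
#' @return List with `ln_slope` (log of the RMA slope) and `r_mf` (Pearson
#'   correlation of the log means; `NA` for k < 3).
#' @details A sex that is invariant across treatments (zero spread) leaves
#'   the slope undefined, as does a negative male-female correlation (the
#'   slope's log does not exist); both raise an error with class
#'   `sexplast_undefined_slope` so callers can flag the dataset.
#' @export
rma_ln_slope <- function(ds) {
  x <- log(ds$records$female_mean)
  y <- log(ds$records$male_mean)
  rma_ln_slope_xy(x, y)
}

# internal: slope from prepared log vectors (hot path for the bootstrap)
rma_ln_slope_xy <- function(x, y) {
  k <- length(x)
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx * dx); syy <- sum(dy * dy); sxy <- sum(dx * dy)
  if (sxx <= 0 || syy <= 0)
    stop(structure(class = c("sexplast_undefined_slope", "error", "condition"),
                   list(message = "RMA slope undefined: one sex invariant across treatments",
                        call = sys.call(-1))))
  if (sxy < 0)
    stop(structure(class = c("sexplast_undefined_slope", "error", "condition"),
                   list(message = "ln-slope undefined for negative RMA slope (male and female responses oppose)",
                        call = sys.call(-1))))
  ln_slope <- 0.5 * (log(syy) - log(sxx))
  r_mf <- if (k >= 3) sxy / sqrt(sxx * syy) else NA_real_
  list(ln_slope = ln_slope, r_mf = r_mf)
}

#' Sexual development time dimorphism (SDTD)
#'
#' Per treatment, (longer sex's development time / shorter sex's) - 1, signed
#' positive when the female is the longer-developing sex and negative when
#' the male is; an exact tie contributes 0. The dataset value is the
#' arithmetic mean over treatments.
#'
#' @param ds A [primary_dataset].
#' @return Numeric scalar.
#' @export
sdtd <- function(ds) {
  f <- ds$records$female_mean; m <- ds$records$male_mean
  per <- ifelse(f > m, f / m - 1, ifelse(m > f, -(m / f - 1), 0))
  mean(per)
}

#' Gradient length of a primary dataset
#'
#' Fold-difference between the largest and smallest development-time mean.
#' By default both sexes' means are pooled before taking max/min; the
#' per-sex variant averages the two sexes' fold-changes.
#'
#' @param ds A [primary_dataset].
#' @param per_sex Pool the sexes (`FALSE`, default) or average per-sex ratios.
#' @return Numeric scalar, always >= 1.
#' @export
gradient_length <- function(ds, per_sex = FALSE) {
  f <- ds$records$female_mean; m <- ds$records$male_mean
  if (per_sex) {
    mean(c(max(f) / min(f), max(m) / min(m)))
  } else {
    v <- c(f, m)
    max(v) / min(v)
  }
}

#' Compute the effect-size table for a corpus
#'
#' Runs [rma_ln_slope()], [sdtd()] and [gradient_length()] over every
#' dataset. Datasets whose ln-slope is undefined (invariant sex or negative
#' male-female correlation) are excluded with a logged reason rather than
#' propagated as NaN.
#'
#' @param datasets List of [primary_dataset] objects.
#' @return List with `effects` (data frame: dataset_id, study_id, species,
#'   order_name, trait, factor, k, has_se, ln_slope, r_mf, sdtd,
#'   gradient_length, boot_sd, weight) and `flagged` (data frame of excluded
#'   dataset ids with reasons).
#' @export
compute_effects <- function(datasets) {
  rows <- list(); flag_id <- character(); flag_reason <- character()
  for (d in datasets) {
    sl <- tryCatch(rma_ln_slope(d), sexplast_undefined_slope = function(e) e)
    if (inherits(sl, "condition")) {
      flag_id <- c(flag_id, d$dataset_id)
      flag_reason <- c(flag_reason, conditionMessage(sl))
      next
    }
    rows[[d$dataset_id]] <- data.frame(
      dataset_id = d$dataset_id, study_id = d$study_id, species = d$species,
      order_name = d$order_name, trait = d$trait, factor = d$factor,
      k = d$k, has_se = d$has_se,
      ln_slope = sl$ln_slope, r_mf = sl$r_mf, sdtd = sdtd(d),
      gradient_length = gradient_length(d),
      boot_sd = NA_real_, weight = NA_real_,
      stringsAsFactors = FALSE)
  }
  effects <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dataset_id = character(), study_id = character(),
               species = character(), order_name = character(),
               trait = character(), factor = character(), k = integer(),
               has_se = logical(), ln_slope = numeric(), r_mf = numeric(),
               sdtd = numeric(), gradient_length = numeric(),
               boot_sd = numeric(), weight = numeric())
  rownames(effects) <- NULL
  list(effects = effects,
       flagged = data.frame(dataset_id = flag_id, reason = flag_reason,
                            stringsAsFactors = FALSE))
}

#' Corpus-level descriptive diagnostics
#'
#' Summaries mirroring the qualitative checks reported for the literature
#' corpus: how many datasets have near-perfect male-female log correlations,
#' the direction of development-time dimorphism by trait, mean gradient
#' lengths by factor, and ln-slope histogram counts by factor.
#'
#' @param effects Effect-size data frame from [compute_effects()].
#' @param r_threshold Correlation threshold (default 0.98) applied to
#'   datasets with k >= 3.
#' @param breaks Histogram break points for ln-slope.
#' @return List of summary tables.
#' @export
corpus_diagnostics <- function(effects, r_threshold = 0.98,
                               breaks = seq(-1.025, 1.025, by = 0.05)) {
  k3 <- effects[!is.na(effects$r_mf), , drop = FALSE]
  r_summary <- data.frame(
    n_k3 = nrow(k3),
    n_high_r = sum(k3$r_mf >= r_threshold),
    threshold = r_threshold)
  sign_counts <- do.call(rbind, lapply(split(effects, effects$trait), function(e)
    data.frame(trait = e$trait[1L], n = nrow(e),
               female_longer = sum(e$sdtd > 0), male_longer = sum(e$sdtd < 0),
               tied = sum(e$sdtd == 0))))
  rownames(sign_counts) <- NULL
  grad <- do.call(rbind, lapply(split(effects, effects$factor), function(e)
    data.frame(factor = e$factor[1L], n = nrow(e),
               mean_gradient_length = mean(e$gradient_length))))
  rownames(grad) <- NULL
  hist_by_factor <- lapply(split(effects, effects$factor), function(e) {
    s <- pmin(pmax(e$ln_slope, min(breaks)), max(breaks))
    h <- graphics::hist(s, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  list(r_mf = r_summary, sdtd_signs = sign_counts, gradient = grad,
       ln_slope_hist = hist_by_factor)
}
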