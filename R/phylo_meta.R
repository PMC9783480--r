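#' @title Phylogenetic multilevel meta-analysis by REML
#' @name phylo_meta
#' @description
#' Effect sizes (dataset ln-slopes) are pooled with the model
#' \deqn{y_i = \mu + \beta\,SDTD_i + u_{species(i)} + s_{study(i)} + o_i + e_i}
#' where the species effects u are multivariate normal with covariance
#' sigma2_phylo * A (A the Brownian-motion correlation matrix from the
#' phylogeny), s are iid study effects, o iid observation effects (residual
#' heterogeneity), and e_i has known sampling variance v_i from the
#' bootstrap. Variance components are estimated by REML on the log-variance
#' scale; fixed effects by GLS at the REML solution.
NULL

#' Phylogenetic correlation matrix from a tree
#'
#' Under Brownian motion on an ultrametric tree the expected correlation
#' between two tips is their shared root-to-ancestor path length divided by
#' total tree depth. Topology-only trees (e.g. Open Tree exports) get branch
#' lengths assigned first: Grafen height scaling (default) yields an
#' ultrametric tree; `"equal"` sets every branch to 1.
#'
#' @param tree A `phylo` object.
#' @param tips Tip subset to keep (default: all).
#' @param branch_rule `"keep"` (use existing branch lengths; error if
#'   absent), `"grafen"`, or `"equal"`. Default: keep when present, else
#'   Grafen.
#' @return Object of class `phylo_corr`: list with `species` and the
#'   symmetric unit-diagonal `matrix`, eigen-clipped to positive
#'   semidefinite.
#' @export
phylo_correlation <- function(tree, tips = tree$tip.label,
                              branch_rule = c("auto", "keep", "grafen", "equal")) {
  branch_rule <- match.arg(branch_rule)
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips))
    stop("tips not in tree: ", paste(missing_tips, collapse = ", "))
  if (length(tips) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, tips)
  has_bl <- !is.null(tree$edge.length)
  if (branch_rule == "auto") branch_rule <- if (has_bl) "keep" else "grafen"
  if (branch_rule == "keep" && !has_bl)
    stop("tree has no branch lengths; use branch_rule 'grafen' or 'equal'")
  if (branch_rule == "grafen") {
    tree$edge.length <- NULL
    tree <- ape::compute.brlen(tree, method = "Grafen", power = 1)
  } else if (branch_rule == "equal") {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  A <- ape::vcv(tree, corr = TRUE)
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("phylogenetic correlation matrix not positive semidefinite")
  if (min(ev$values) < 0) {   # clip numerical negatives
    vals <- pmax(ev$values, 0)
    A <- ev$vectors %*% (vals * t(ev$vectors))
    dimnames(A) <- list(tree$tip.label, tree$tip.label)
    A <- stats::cov2cor(A)
  }
  A <- A[tips, tips, drop = FALSE]
  structure(list(species = tips, matrix = A), class = "phylo_corr")
}

#' @export
print.phylo_corr <- function(x, ...) {
  cat(sprintf("<phylo_corr> %d species, mean off-diagonal correlation %.3f\n",
              length(x$species),
              mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

# ---- REML engine ------------------------------------------------------------

# Restricted log-likelihood (up to an additive constant) for
# V = s2[1]*Ap + s2[2]*As + s2[3]*I + diag(v). Returns list(ll, beta, se, ...)
# or ll only when value_only.
reml_eval <- function(s2, y, X, Ap, As, v, value_only = TRUE) {
  n <- length(y)
  V <- s2[1] * Ap + s2[2] * As + diag(s2[3] + v, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(if (value_only) -1e10 else NULL)
  ldetV <- 2 * sum(log(diag(R)))
  U <- backsolve(R, X, transpose = TRUE)
  uy <- backsolve(R, y, transpose = TRUE)
  XtVX <- crossprod(U)
  XtVy <- crossprod(U, uy)
  cf <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cf)) return(if (value_only) -1e10 else NULL)
  beta <- backsolve(cf, backsolve(cf, XtVy, transpose = TRUE))
  quad <- sum(uy^2) - sum((backsolve(cf, XtVy, transpose = TRUE))^2)
  ll <- -0.5 * (ldetV + 2 * sum(log(diag(cf))) + quad)
  if (value_only) return(ll)
  vcov_beta <- chol2inv(cf)
  list(ll = ll, beta = drop(beta), se = sqrt(diag(vcov_beta)),
       vcov_beta = vcov_beta)
}

# Negative restricted log-likelihood and its gradient on the log-variance
# scale. Gradient: d ll / d s2_j = -0.5 * (tr(P G_j) - (Py)' G_j (Py)) with
# P = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv and G = (Ap, As, I); chain rule
# multiplies by s2_j for the log scale.
reml_obj_grad <- function(p, y, X, Ap, As, v) {
  s2 <- exp(p)
  n <- length(y)
  V <- s2[1] * Ap + s2[2] * As + diag(s2[3] + v, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(objective = 1e10, gradient = rep(0, 3)))
  Vinv <- chol2inv(R)
  ldetV <- 2 * sum(log(diag(R)))
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  cf <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cf)) return(list(objective = 1e10, gradient = rep(0, 3)))
  P <- Vinv - VX %*% chol2inv(cf) %*% t(VX)
  Py <- P %*% y
  ll <- -0.5 * (ldetV + 2 * sum(log(diag(cf))) + sum(y * Py))
  g <- -0.5 * c(sum(P * Ap) - crossprod(Py, Ap %*% Py),
                sum(P * As) - crossprod(Py, As %*% Py),
                sum(diag(P)) - sum(Py^2))
  list(objective = -ll, gradient = -g * s2)
}

# Optimize the REML criterion over log variances. starts: matrix of log-s2
# rows. Returns sigma2, loglik, convergence flag.
reml_optimize <- function(y, X, Ap, As, v, starts, reltol = 1e-10) {
  cache <- new.env(parent = emptyenv())
  both <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- reml_obj_grad(p, y, X, Ap, As, v)
      cache$key <- key
    }
    cache$val
  }
  best <- NULL
  conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[i, ], function(p) both(p)$objective,
                    gradient = function(p) both(p)$gradient,
                    lower = rep(-35, 3), upper = rep(8, 3),
                    control = list(rel.tol = reltol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best) || best$objective >= 1e10) return(NULL)
  s2 <- exp(best$par)
  s2[s2 < 1e-12] <- 0   # boundary estimates snap to zero
  list(sigma2 = s2, loglik = -best$objective, converged = conv)
}

# dispersed starting values on the log-variance scale
reml_starts <- function(y, v, n_extra = 4L) {
  tau2 <- max(stats::var(y) - mean(v), 0.05 * stats::var(y), 1e-6)
  base <- log(rep(tau2 / 3, 3))
  extra <- rbind(base + c(2, -2, 0), base + c(-2, 2, 0),
                 base + c(-2, -2, 2), base - 4)
  rbind(base, extra[seq_len(min(n_extra, nrow(extra))), , drop = FALSE])
}

#' Fit the multilevel phylogenetic meta-analytic model
#'
#' @param effects Effect-size data frame with columns `ln_slope`, `boot_sd`,
#'   `species`, `study_id` (and the moderator column if requested). Rows
#'   without `boot_sd` are refused: qualitative-only datasets never enter
#'   the weighted model.
#' @param corr A [phylo_correlation()] result covering all species, or
#'   `NULL` for a non-phylogenetic fit (A = identity).
#' @param moderator Optional column name (e.g. `"sdtd"`) entering as a fixed
#'   covariate; the reported `z_stat` then tests its coefficient, otherwise
#'   the pooled mean.
#' @param species_col Column holding the tip-resolved species names
#'   (default `"species"`).
#' @param sigma2 Optional fixed variance components
#'   `c(phylo, study, obs)`; skips REML (used for degenerate closed-form
#'   checks).
#' @param n_starts Number of dispersed REML starts (default 5).
#' @param reltol REML convergence tolerance.
#' @return Object of class `meta_fit`: estimates, SEs, variance components,
#'   z statistic with its normal-approximation p (diagnostic only — primary
#'   inference is by permutation, see [permutation_test_overall()]),
#'   phylogenetic variance share, REML log-likelihood, convergence flag.
#' @export
fit_meta <- function(effects, corr = NULL, moderator = NULL,
                     species_col = "species", sigma2 = NULL,
                     n_starts = 5L, reltol = 1e-10) {
  if (any(is.na(effects$boot_sd)))
    stop("all effects entering the weighted model need boot_sd; drop qualitative-only rows first")
  n <- nrow(effects)
  if (n < 2L) stop("need at least 2 effects")
  y <- effects$ln_slope
  v <- effects$boot_sd^2
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(moderator)) {
    mod <- effects[[moderator]]
    if (is.null(mod)) stop("moderator column '", moderator, "' not found")
    if (stats::sd(mod) == 0)
      stop("singular design: moderator '", moderator, "' is constant")
    X <- cbind(X, matrix(mod, ncol = 1, dimnames = list(NULL, moderator)))
  }
  sp <- as.character(effects[[species_col]])
  if (is.null(corr)) {
    A <- diag(length(unique(sp)))
    dimnames(A) <- list(unique(sp), unique(sp))
  } else {
    missing_sp <- setdiff(sp, corr$species)
    if (length(missing_sp))
      stop("species not in correlation matrix: ",
           paste(unique(missing_sp), collapse = ", "))
    A <- corr$matrix
  }
  Zs <- outer(sp, colnames(A), "==") * 1
  Ap <- Zs %*% A %*% t(Zs)
  st <- as.character(effects$study_id)
  Zt <- outer(st, unique(st), "==") * 1
  As <- tcrossprod(Zt)

  if (!is.null(sigma2)) {
    stopifnot(length(sigma2) == 3, all(sigma2 >= 0))
    opt <- list(sigma2 = sigma2, loglik = reml_eval(sigma2, y, X, Ap, As, v),
                converged = TRUE)
  } else {
    starts <- reml_starts(y, v, n_extra = n_starts - 1L)
    opt <- reml_optimize(y, X, Ap, As, v, starts, reltol = reltol)
    if (is.null(opt))
      return(structure(list(converged = FALSE, n_effects = n), class = "meta_fit"))
  }
  s2 <- opt$sigma2
  fe <- reml_eval(s2, y, X, Ap, As, v, value_only = FALSE)
  tested <- ncol(X)   # moderator when present, else intercept
  z <- fe$beta[tested] / fe$se[tested]
  tot <- sum(s2)
  structure(list(
    mu_hat = fe$beta[1L],
    beta_hat = if (ncol(X) > 1) fe$beta[2L] else NA_real_,
    se_mu = fe$se[1L],
    se_beta = if (ncol(X) > 1) fe$se[2L] else NA_real_,
    sigma2_phylo = s2[1L], sigma2_study = s2[2L], sigma2_obs = s2[3L],
    z_stat = z,
    p_normal = 2 * stats::pnorm(-abs(z)),
    p_perm = NA_real_,
    phylo_var_share = if (tot > 0) s2[1L] / tot else NA_real_,
    n_effects = n, converged = opt$converged, loglik_reml = opt$loglik,
    moderator = moderator,
    model = list(y = y, X = X, Ap = Ap, As = As, v = v,
                 log_s2_opt = log(pmax(s2, 1e-12)))),
    class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("<meta_fit> NOT CONVERGED\n")
  cat(sprintf("<meta_fit> %d effects; pooled mean %.4f (SE %.4f)\n",
              x$n_effects, x$mu_hat, x$se_mu))
  if (!is.na(x$beta_hat))
    cat(sprintf("  moderator %s: %.4f (SE %.4f)\n", x$moderator, x$beta_hat,
                x$se_beta))
  cat(sprintf("  z = %.3f, normal p = %.4g%s\n", x$z_stat, x$p_normal,
              if (!is.na(x$p_perm)) sprintf(", permutation p = %.4g", x$p_perm) else ""))
  cat(sprintf("  sigma2: phylo %.5f, study %.5f, obs %.5f (phylo share %s)\n",
              x$sigma2_phylo, x$sigma2_study, x$sigma2_obs,
              if (is.na(x$phylo_var_share)) "undefined" else
                sprintf("%.1f%%", 100 * x$phylo_var_share)))
  invisible(x)
}

# Fast refit for permutation replicates: same random-effect design, new y
# and/or X. Starting values derive from (y, v) only — never from the
# observed fit — so the statistic is the *same* function of (y, X) for the
# observed and every permuted assignment; a data-dependent warm start would
# break the permutation symmetry and bias the test.
refit_meta <- function(fit, y, X = NULL, n_starts = 2L, reltol = 1e-8) {
  m <- fit$model
  if (is.null(X)) X <- m$X
  starts <- reml_starts(y, m$v, n_extra = n_starts - 1L)
  opt <- reml_optimize(y, X, m$Ap, m$As, m$v, starts, reltol = reltol)
  if (is.null(opt)) return(NULL)
  fe <- reml_eval(opt$sigma2, y, X, m$Ap, m$As, m$v, value_only = FALSE)
  tested <- ncol(X)
  fe$beta[tested] / fe$se[tested]
}

# Profiled ML log-likelihood machinery for likelihood-ratio intervals on the
# pooled mean. With mu fixed the model has no free fixed effect, so the
# comparison must be on the ML (not REML) scale on both sides.
ml_obj_grad <- function(p, r, Ap, As, v) {
  s2 <- exp(p)
  n <- length(r)
  V <- s2[1] * Ap + s2[2] * As + diag(s2[3] + v, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(objective = 1e10, gradient = rep(0, 3)))
  Vinv <- chol2inv(R)
  Vr <- Vinv %*% r
  ll <- -0.5 * (2 * sum(log(diag(R))) + sum(r * Vr))
  g <- -0.5 * c(sum(Vinv * Ap) - crossprod(Vr, Ap %*% Vr),
                sum(Vinv * As) - crossprod(Vr, As %*% Vr),
                sum(diag(Vinv)) - sum(Vr^2))
  list(objective = -ll, gradient = -g * s2)
}

# maximized ML log-likelihood for fixed mu (mu = NULL profiles it by GLS
# inside the objective); returns list(ll, par)
ml_max_ll <- function(mu, y, Ap, As, v, starts, reltol = 1e-8) {
  cache <- new.env(parent = emptyenv())
  both <- function(p) {
    key <- paste(p, collapse = ",")
    if (!identical(cache$key, key)) {
      r <- if (is.null(mu)) {
        s2 <- exp(p)
        V <- s2[1] * Ap + s2[2] * As + diag(s2[3] + v, length(y))
        R <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(R)) y - mean(y) else {
          u1 <- backsolve(R, rep(1, length(y)), transpose = TRUE)
          uy <- backsolve(R, y, transpose = TRUE)
          y - sum(u1 * uy) / sum(u1^2)   # GLS-profiled mean (envelope thm)
        }
      } else y - mu
      cache$val <- ml_obj_grad(p, r, Ap, As, v)
      cache$key <- key
    }
    cache$val
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[i, ], function(p) both(p)$objective,
                    gradient = function(p) both(p)$gradient,
                    lower = rep(-35, 3), upper = rep(8, 3),
                    control = list(rel.tol = reltol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) return(list(ll = NA_real_, par = starts[1, ]))
  list(ll = -best$objective, par = best$par)
}

#' Profile-likelihood confidence interval for the pooled mean
#'
#' Inverts the ML likelihood-ratio test of `mu = mu0`, re-estimating all
#' variance components at each fixed `mu0`. Unlike the plug-in Wald
#' interval, this propagates variance-component uncertainty and attains
#' close-to-nominal coverage at realistic corpus sizes (see the methods
#' vignette).
#'
#' @param fit A converged `meta_fit` from the no-moderator model.
#' @param level Confidence level (default 0.95).
#' @param max_widen Bracket expansion limit, in Wald-SE units (default 10).
#' @return Numeric `c(lower, upper)`.
#' @export
profile_mu_ci <- function(fit, level = 0.95, max_widen = 10) {
  stopifnot(isTRUE(fit$converged), is.null(fit$moderator))
  m <- fit$model
  state <- new.env(parent = emptyenv())
  state$par <- reml_starts(m$y, m$v, n_extra = 0L)[1, ]
  opt0 <- ml_max_ll(NULL, m$y, m$Ap, m$As, m$v,
                    rbind(state$par, state$par + c(-2, -2, 2)))
  ll_hat <- opt0$ll
  state$par <- opt0$par
  crit <- stats::qchisq(level, 1) / 2
  dev <- function(mu0) {
    # warm start from the neighbouring mu0 solved last (profiles are
    # smooth), plus one dispersed start so a poor local optimum cannot
    # understate the profiled likelihood and pinch the interval
    o <- ml_max_ll(mu0, m$y, m$Ap, m$As, m$v,
                   rbind(state$par, state$par + c(-2, -2, 2)))
    if (!is.na(o$ll)) state$par <- o$par
    ll_hat - o$ll - crit
  }
  bound <- function(dir) {
    state$par <- opt0$par
    step <- dir * fit$se_mu
    lo <- fit$mu_hat; hi <- fit$mu_hat + 1.5 * step
    i <- 1L
    while (dev(hi) < 0 && i < max_widen) { lo <- hi; hi <- hi + step; i <- i + 1L }
    if (dev(hi) < 0) return(fit$mu_hat + dir * max_widen * fit$se_mu)
    stats::uniroot(dev, sort(c(lo, hi)),
                   tol = 5e-3 * max(fit$se_mu, 1e-8))$root
  }
  c(bound(-1), bound(1))
}

#' Per-order subgroup fits (Table-1 analogue)
#'
#' Fits the no-moderator model within each insect order (with the
#' correlation matrix pruned to the order's species) plus the all-species
#' pool, and applies a table-wide multiplicity adjustment to the subgroup
#' p-values.
#'
#' @param effects Effect-size data frame (quantitative rows).
#' @param corr [phylo_correlation()] over all species, or `NULL`.
#' @param group_col Grouping column, default `"order_name"`.
#' @param adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @param min_n Minimum effects per group (default 2); smaller groups are
#'   skipped with a notice.
#' @param p_source `"normal"` (default) or `"permutation"`; the latter runs
#'   [permutation_test_overall()] within each group and needs `datasets`.
#' @param datasets,perm_cfg Required when `p_source = "permutation"`.
#' @return List with `table` (group, n, mean effect, SE, z, p, p_adjusted)
#'   and `fits` (the per-group `meta_fit` objects). The all-species row is
#'   not included in the multiplicity correction.
#' @export
subgroup_fits <- function(effects, corr = NULL, group_col = "order_name",
                          adjust = "holm", min_n = 2L,
                          p_source = c("normal", "permutation"),
                          datasets = NULL, perm_cfg = NULL) {
  p_source <- match.arg(p_source)
  groups <- split(effects, effects[[group_col]])
  skipped <- names(groups)[vapply(groups, nrow, 1L) < min_n]
  if (length(skipped))
    message("skipping groups with fewer than ", min_n, " effects: ",
            paste(skipped, collapse = ", "))
  groups <- groups[vapply(groups, nrow, 1L) >= min_n]
  fits <- list(); rows <- list()
  for (g in names(groups)) {
    e <- groups[[g]]
    gcorr <- if (is.null(corr)) NULL else
      phylo_corr_subset(corr, unique(e$species))
    f <- fit_meta(e, gcorr)
    p <- f$p_normal
    if (p_source == "permutation") {
      if (is.null(datasets)) stop("permutation p needs the primary datasets")
      pt <- permutation_test_overall(
        datasets[e$dataset_id], gcorr, effects = e,
        cfg = if (is.null(perm_cfg)) perm_config() else perm_cfg)
      p <- pt$p_perm
      f$p_perm <- p
    }
    fits[[g]] <- f
    rows[[g]] <- data.frame(group = g, n = f$n_effects, mean_effect = f$mu_hat,
                            se = f$se_mu, z = f$z_stat, p = p,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adjusted <- stats::p.adjust(tab$p, method = adjust)
  all_fit <- fit_meta(effects, corr)
  tab <- rbind(tab, data.frame(group = "all", n = all_fit$n_effects,
                               mean_effect = all_fit$mu_hat, se = all_fit$se_mu,
                               z = all_fit$z_stat, p = all_fit$p_normal,
                               p_adjusted = NA_real_))
  list(table = tab, fits = fits, all = all_fit, skipped = skipped)
}

# subset a phylo_corr to a species set (order matters only via names)
phylo_corr_subset <- function(corr, species) {
  missing_sp <- setdiff(species, corr$species)
  if (length(missing_sp))
    stop("species not in correlation matrix: ", paste(missing_sp, collapse = ", "))
  structure(list(species = species,
                 matrix = corr$matrix[species, species, drop = FALSE]),
            class = "phylo_corr")
}

#' Variance partition of a converged fit
#'
#' Shares of the phylogenetic, study and observation variance components in
#' their sum. Known sampling variances v_i are excluded from the
#' denominator.
#'
#' @param fit A converged `meta_fit`.
#' @return Named numeric shares summing to 1, or all-`NA` when every
#'   component is zero.
#' @export
variance_partition <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  s2 <- c(phylo = fit$sigma2_phylo, study = fit$sigma2_study,
          obs = fit$sigma2_obs)
  tot <- sum(s2)
  if (tot <= 0) return(c(phylo = NA_real_, study = NA_real_, obs = NA_real_))
  s2 / tot
}
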