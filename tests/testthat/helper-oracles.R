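# Fixture builders and independent oracles. Oracles deliberately avoid the
# package's code paths: slopes by explicit two-pass SDs, phylogenetic
# correlations by path enumeration over the edge list, REML by grid search
# with an eigendecomposition shortcut, bootstrap variance by a large
# vectorised Monte Carlo and by delta-method propagation.

make_ds <- function(female, male, female_se = NULL, male_se = NULL,
                    treatment = seq_along(female), id = "ds1", study = "s1",
                    species = "Aedes_albopictus", order_name = "Diptera",
                    trait = "total", factor = "temperature") {
  if (is.null(female_se)) female_se <- rep(NA_real_, length(female))
  if (is.null(male_se)) male_se <- rep(NA_real_, length(male))
  primary_dataset(id, study, species, order_name, trait, factor,
                  records = data.frame(treatment_value = treatment,
                                       male_mean = male, male_se = male_se,
                                       female_mean = female, female_se = female_se))
}

# random dataset with positively correlated log-linear sex responses
random_ds <- function(k = NULL, id = "r1") {
  if (is.null(k)) k <- sample(2:11, 1)
  repeat {
    x <- sort(stats::rnorm(k, mean = 3, sd = 0.5))
    slope <- stats::runif(1, 0.5, 2)
    y <- stats::rnorm(1, 0, 1) + slope * x + stats::rnorm(k, 0, 0.05)
    f <- exp(x); m <- exp(y)
    dx <- x - mean(x); dy <- y - mean(y)
    if (sum(dx^2) > 1e-8 && sum(dy^2) > 1e-8 && sum(dx * dy) > 1e-8) break
  }
  make_ds(f, m, female_se = 0.02 * f, male_se = 0.02 * m, id = id)
}

# two-pass SD-ratio oracle for the ln-RMA slope
oracle_ln_slope <- function(ds) {
  x <- log(ds$records$female_mean); y <- log(ds$records$male_mean)
  k <- length(x)
  sdx <- sqrt(sum((x - mean(x))^2) / (k - 1))
  sdy <- sqrt(sum((y - mean(y))^2) / (k - 1))
  log(sdy / sdx)
}

# Brownian correlation by explicit root-to-MRCA path enumeration
oracle_phylo_corr <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(max(tree$edge)); elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- node
    while (node != root) { node <- parent[node]; p <- c(p, node) }
    rev(p)   # root first
  }
  depth <- function(node) { s <- 0; for (nd in path_to_root(node)[-1]) s <- s + elen[nd]; s }
  total <- max(vapply(seq_len(ntip), depth, 1))
  M <- diag(ntip)
  for (i in seq_len(ntip - 1)) for (j in (i + 1):ntip) {
    pi_ <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi_, pj)
    mrca <- shared[length(shared)]   # deepest shared node (paths are root-first)
    M[i, j] <- M[j, i] <- depth(mrca) / total
  }
  dimnames(M) <- list(tree$tip.label, tree$tip.label)
  M
}

# REML restricted log-likelihood (same dropped constants as the package) by
# independent dense linear algebra, for grid evaluation
oracle_reml_ll <- function(s2, y, X, Ap, As, v) {
  V <- s2[1] * Ap + s2[2] * As + diag(s2[3] + v, length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

# grid-search oracle: best restricted ll over an n3-cubed grid, using
# eigen(M) with M = s2p*Ap + s2s*As + diag(v) so the sigma2_obs axis is a
# cheap rank-update (V = M + s2o*I shares M's eigenvectors)
oracle_grid_best <- function(y, X, Ap, As, v, grid_p, grid_s, grid_o) {
  stopifnot(ncol(X) == 1)
  best <- -Inf
  n <- length(y)
  for (sp in grid_p) for (ss in grid_s) {
    M <- sp * Ap + ss * As + diag(v, n)
    e <- eigen(M, symmetric = TRUE)
    ty <- drop(crossprod(e$vectors, y))
    tx <- drop(crossprod(e$vectors, X))
    for (so in grid_o) {
      d <- e$values + so
      if (any(d <= 0)) next
      xvx <- sum(tx^2 / d)
      beta <- sum(tx * ty / d) / xvx
      quad <- sum((ty - beta * tx)^2 / d)
      ll <- -0.5 * (sum(log(d)) + log(xvx) + quad)
      if (ll > best) best <- ll
    }
  }
  best
}

# large-B Monte Carlo oracle for the bootstrap SD, same draw rule,
# vectorised and independent of bootstrap_slope_sd
oracle_boot_sd <- function(ds, B = 2e5, width_rule = "sd_matched") {
  f <- ds$records$female_mean; m <- ds$records$male_mean
  wmul <- if (width_rule == "sd_matched") sqrt(3) else 1
  hf <- wmul * ds$records$female_se; hm <- wmul * ds$records$male_se
  k <- length(f)
  fm <- f + hf * matrix(stats::runif(k * B, -1, 1), k, B)
  mm <- m + hm * matrix(stats::runif(k * B, -1, 1), k, B)
  lx <- log(fm); ly <- log(mm)
  cx <- lx - matrix(colMeans(lx), k, B, byrow = TRUE)
  cy <- ly - matrix(colMeans(ly), k, B, byrow = TRUE)
  sxx <- colSums(cx^2); syy <- colSums(cy^2); sxy <- colSums(cx * cy)
  ok <- sxx > 0 & syy > 0 & sxy > 0
  stats::sd(0.5 * (log(syy[ok]) - log(sxx[ok])))
}

# first-order (delta-method) SD of the ln-slope under mean perturbations
# whose SD equals the reported SE
oracle_delta_sd <- function(ds) {
  f <- ds$records$female_mean; m <- ds$records$male_mean
  base <- c(f, m)
  g <- function(z) {
    k <- length(z) / 2
    x <- log(z[1:k]); y <- log(z[(k + 1):(2 * k)])
    0.5 * (log(sum((y - mean(y))^2)) - log(sum((x - mean(x))^2)))
  }
  eps <- 1e-6
  grad <- vapply(seq_along(base), function(i) {
    zp <- base; zp[i] <- zp[i] + eps
    zm <- base; zm[i] <- zm[i] - eps
    (g(zp) - g(zm)) / (2 * eps)
  }, 1)
  se <- c(ds$records$female_se, ds$records$male_se)
  sqrt(sum(grad^2 * se^2))
}

# hand-computed Holm adjustment (independent of stats::p.adjust)
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)
  out <- numeric(n); out[o] <- adj
  out
}
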