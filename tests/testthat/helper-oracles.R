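# Independent oracle implementations used across the suite. These stay
# deliberately naive (loops, dense matrices, grids) so they share no code
# path with the package internals they check.

# Activity: explicit loop over consecutive sample pairs.
naive_activity <- function(t, x, y, step_s = 0.2, gap_factor = 3) {
  total_d <- 0; total_t <- 0
  for (i in 2:length(t)) {
    dt <- t[i] - t[i - 1]
    if (dt <= gap_factor * step_s) {
      total_d <- total_d + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
      total_t <- total_t + dt
    }
  }
  total_d / total_t
}

# Feeding time: explicit per-sample enumeration, minutes.
naive_feeding <- function(x, y, zone, step_s = 0.2) {
  n_in <- 0
  for (i in seq_along(x)) {
    if (x[i] >= zone$x_min && x[i] <= zone$x_min + zone$width_cm &&
        y[i] >= zone$y_min && y[i] <= zone$y_min + zone$height_cm)
      n_in <- n_in + 1
  }
  n_in * step_s / 60
}

# Restricted profile log-likelihood via dense matrices (no Woodbury), with
# sigma^2 profiled out; same constant convention as the package reports.
dense_reml_loglik <- function(y, X, g, lambda) {
  n <- length(y); p <- ncol(X)
  Z <- stats::model.matrix(~ 0 + factor(g))
  V0 <- lambda * tcrossprod(Z) + diag(n)
  V0i <- solve(V0)
  XtViX <- t(X) %*% V0i %*% X
  beta <- solve(XtViX, t(X) %*% V0i %*% y)
  r <- y - X %*% beta
  RSS <- as.numeric(t(r) %*% V0i %*% r)
  df <- n - p
  s2 <- RSS / df
  ld <- as.numeric(determinant(V0)$modulus)
  ldX <- as.numeric(determinant(XtViX)$modulus)
  -0.5 * (ld + ldX + df * (log(2 * pi * s2) + 1))
}

# Brute-force grid maximization of the dense restricted likelihood over
# lambda (coarse scan then one refinement).
grid_reml_oracle <- function(y, X, g) {
  lams <- c(0, exp(seq(-18, 12, length.out = 241)))
  ll <- vapply(lams, function(l) dense_reml_loglik(y, X, g, l), numeric(1))
  i <- which.max(ll)
  lo <- if (i > 1) lams[i - 1] else 0
  hi <- if (i < length(lams)) lams[i + 1] else lams[i] * 2
  fine <- seq(lo, hi, length.out = 400)
  llf <- vapply(fine, function(l) dense_reml_loglik(y, X, g, l), numeric(1))
  j <- which.max(llf)
  list(lambda = fine[j], loglik = llf[j])
}

# Balanced one-way ANOVA method-of-moments variance components.
anova_components <- function(y, g) {
  g <- factor(g)
  m <- length(y) / nlevels(g)
  gm <- tapply(y, g, mean)
  msb <- m * sum((gm - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - nlevels(g))
  list(V_ID = (msb - msw) / m, V_res = msw)
}

# Coarse-to-fine grid search of the von Bertalanffy RSS surface.
vb_grid_oracle <- function(age, len, k = 21, passes = 3) {
  rss_of <- function(L, K, t0) sum((len - L * (1 - exp(-K * (age - t0))))^2)
  rL <- c(max(len) * 1.0001, 3 * max(len))
  rK <- c(1e-3, 0.2)
  rt <- c(min(age) - 80, min(age))
  best <- list(rss = Inf)
  for (pass in seq_len(passes)) {
    Ls <- seq(rL[1], rL[2], length.out = k)
    Ks <- exp(seq(log(rK[1]), log(rK[2]), length.out = k))
    ts <- seq(rt[1], rt[2], length.out = k)
    for (L in Ls) for (K in Ks) for (t0 in ts) {
      r <- rss_of(L, K, t0)
      if (r < best$rss) best <- list(rss = r, Linf = L, K = K, t0 = t0)
    }
    sL <- diff(rL) / (k - 1); sK <- diff(log(rK)) / (k - 1); st <- diff(rt) / (k - 1)
    rL <- c(max(best$Linf - 2 * sL, max(len) * 1.0001), best$Linf + 2 * sL)
    rK <- exp(c(log(best$K) - 2 * sK, log(best$K) + 2 * sK))
    rt <- c(best$t0 - 2 * st, best$t0 + 2 * st)
  }
  best
}

# Small random grouped dataset for REML oracle checks.
random_lmm_dataset <- function(n_groups = 5, m = 4, p_x = 1, V_ID = 0.5, V_res = 1) {
  g <- rep(seq_len(n_groups), each = m)
  n <- length(g)
  d <- data.frame(g = sprintf("g%02d", g))
  b <- rnorm(n_groups, 0, sqrt(V_ID))
  d$x <- rnorm(n)
  d$y <- 1 + 0.5 * d$x + b[g] + rnorm(n, 0, sqrt(V_res))
  d
}

# A jittered random-walk track with t on a fixed grid.
random_track <- function(n = 100, step_s = 0.2) {
  data.frame(t_s = (seq_len(n) - 1) * step_s,
             x_cm = cumsum(rnorm(n, 0, 0.3)),
             y_cm = cumsum(rnorm(n, 0, 0.3)))
}
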