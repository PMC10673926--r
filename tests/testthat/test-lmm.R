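test_that("balanced one-way designs reproduce ANOVA variance components", {
  set.seed(42)
  d <- data.frame(g = rep(letters[1:4], each = 5))
  d$y <- rep(c(10, 12, 9, 11), each = 5) + rnorm(20)
  fit <- fit_lmm(y ~ 1 + (1 | g), d)
  mom <- anova_components(d$y, d$g)
  expect_equal(fit$V_ID, mom$V_ID, tolerance = 1e-6)
  expect_equal(fit$V_res, mom$V_res, tolerance = 1e-6)
  expect_equal(unname(fit$beta[1]), mean(d$y), tolerance = 1e-8)
})

test_that("profiled REML optimum matches a dense grid oracle on small data", {
  set.seed(17)
  for (i in 1:6) {
    d <- random_lmm_dataset(n_groups = sample(4:7, 1), m = sample(3:5, 1),
                            V_ID = runif(1, 0, 1.5), V_res = runif(1, 0.3, 2))
    fit <- fit_lmm(y ~ x + (1 | g), d)
    X <- stats::model.matrix(~ x, d)
    oracle <- grid_reml_oracle(d$y, X, d$g)
    expect_equal(fit$loglik, oracle$loglik,
                 tolerance = 1e-6 * abs(oracle$loglik))
    expect_gte(fit$loglik, oracle$loglik - 1e-8)
  }
})

test_that("estimates agree with an independent REML implementation (lme4)", {
  set.seed(3)
  d <- random_lmm_dataset(n_groups = 15, m = 6, V_ID = 0.8, V_res = 1.5)
  d <- d[-sample(nrow(d), 13), ]   # make it unbalanced
  fit <- fit_lmm(y ~ x + (1 | g), d)
  lf <- lme4::lmer(y ~ x + (1 | g), d, REML = TRUE)
  expect_equal(fit$V_ID, unname(unlist(lme4::VarCorr(lf))), tolerance = 1e-5)
  expect_equal(fit$V_res, sigma(lf)^2, tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(coef(summary(lf))[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("boundary cases behave: shuffled labels give V_ID ~ 0, constant groups give R ~ 1", {
  set.seed(8)
  d <- data.frame(g = rep(sprintf("g%02d", 1:30), each = 8))
  d$y <- rnorm(240)                      # no group structure at all
  d$g <- sample(d$g)
  fit0 <- fit_lmm(y ~ 1 + (1 | g), d)
  expect_lt(fit0$V_ID, 0.1)        # within sampling error of zero
  expect_lt(repeatability(fit0), 0.1)

  d2 <- data.frame(g = rep(letters[1:5], each = 4),
                   y = rep(c(1, 3, 5, 7, 9), each = 4))
  fit1 <- fit_lmm(y ~ 1 + (1 | g), d2)
  expect_gt(repeatability(fit1), 0.999)
})

test_that("repeatability identities and error paths hold", {
  set.seed(21)
  d <- random_lmm_dataset(n_groups = 10, m = 5, V_ID = 1, V_res = 1)
  fit <- fit_lmm(y ~ 1 + (1 | g), d)
  expect_equal(repeatability(fit), fit$V_ID / (fit$V_ID + fit$V_res))
  expect_true(repeatability(fit) >= 0 && repeatability(fit) <= 1)

  degenerate <- fit
  degenerate$V_ID <- 0; degenerate$V_res <- 0
  expect_error(repeatability(degenerate), "undefined")

  ols <- fit_lmm(y ~ x, d)
  expect_error(repeatability(ols), "random grouping")
})

test_that("repeatability recovers the generating variance ratio", {
  set.seed(5)
  d <- data.frame(g = rep(sprintf("g%03d", 1:200), each = 20))
  d$y <- rep(rnorm(200, 0, 1), each = 20) + rnorm(4000, 0, sqrt(3))
  fit <- fit_lmm(y ~ 1 + (1 | g), d)
  expect_equal(repeatability(fit), 0.25, tolerance = 0.035)
})

test_that("rank-deficient designs fail with the collinear term named", {
  set.seed(2)
  d <- random_lmm_dataset(n_groups = 6, m = 4)
  d$x2 <- d$x
  expect_error(fit_lmm(y ~ x + x2 + (1 | g), d), "collinear.*x2")
})

test_that("likelihood-ratio p-values separate strong effects from noise", {
  set.seed(33)
  d <- data.frame(g = rep(sprintf("g%02d", 1:20), each = 6))
  d$x <- rnorm(120)
  d$z <- rnorm(120)
  d$y <- 5 * d$x + rep(rnorm(20, 0, 0.5), each = 6) + rnorm(120, 0, 0.5)
  fit <- fit_lmm(y ~ x + z + (1 | g), d)
  pv <- fixed_effect_pvalues(fit)
  expect_lt(pv$p[pv$term == "x"], 1e-6)
  expect_gt(pv$p[pv$term == "z"], 0.01)

  # null predictors give approximately uniform p-values
  set.seed(54)
  ps <- replicate(150, {
    d <- data.frame(g = rep(sprintf("g%02d", 1:15), each = 4))
    d$x <- rnorm(60)
    d$y <- rep(rnorm(15, 0, 0.7), each = 4) + rnorm(60)
    pv <- fixed_effect_pvalues(fit_lmm(y ~ x + (1 | g), d))
    pv$p[1]
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("marginality is respected: interactions tested before main effects", {
  set.seed(12)
  d <- data.frame(g = rep(sprintf("g%02d", 1:12), each = 6))
  d$x <- rnorm(72); d$w <- rnorm(72)
  d$y <- d$x + rep(rnorm(12), each = 6) + rnorm(72)
  fit <- fit_lmm(y ~ x * w + (1 | g), d)
  pv <- fixed_effect_pvalues(fit)
  expect_false(pv$removable[pv$term == "x"])
  expect_false(pv$removable[pv$term == "w"])
  expect_true(pv$removable[pv$term == "x:w"])
})

test_that("stepwise-backward keeps true and protected terms, drops noise", {
  set.seed(61)
  d <- data.frame(g = rep(sprintf("g%02d", 1:25), each = 6))
  n <- nrow(d)
  d$x_true <- rnorm(n); d$n1 <- rnorm(n); d$n2 <- rnorm(n); d$n3 <- rnorm(n)
  d$y <- 2 * d$x_true + rep(rnorm(25, 0, 0.6), each = 6) + rnorm(n)

  sw <- stepwise_backward(y ~ x_true + n1 + n2 + n3 + (1 | g), d)
  kept <- attr(sw$fit$terms, "term.labels")
  expect_true("x_true" %in% kept)
  expect_false(any(c("n1", "n2", "n3") %in% kept))

  # pure noise with no protection reduces to the intercept-only model
  d$y0 <- rep(rnorm(25, 0, 0.6), each = 6) + rnorm(n)
  sw0 <- stepwise_backward(y0 ~ n1 + n2 + n3 + (1 | g), d)
  expect_length(attr(sw0$fit$terms, "term.labels"), 0)

  # a protected noise term survives selection
  swp <- stepwise_backward(y0 ~ n1 + n2 + (1 | g), d, protected = "n1")
  expect_true("n1" %in% attr(swp$fit$terms, "term.labels"))

  # fully significant models come back unchanged
  d$y2 <- 2 * d$x_true + 2 * d$n1 + rep(rnorm(25, 0, 0.4), each = 6) + rnorm(n, 0, 0.4)
  sw2 <- stepwise_backward(y2 ~ x_true + n1 + (1 | g), d)
  expect_setequal(attr(sw2$fit$terms, "term.labels"), c("x_true", "n1"))
})

test_that("partial R2 matches its closed forms in plain regression", {
  set.seed(9)
  d <- data.frame(x = rnorm(10))
  d$y <- 1 + 0.8 * d$x + rnorm(10, 0, 0.7)
  fit <- fit_lmm(y ~ x, d)
  tstat <- fit$beta[["x"]] / fit$se[[2]]
  df_res <- 10 - 2
  expect_equal(partial_r2(fit, "x"), tstat^2 / (tstat^2 + df_res),
               tolerance = 1e-10)
  # with a single predictor this is the squared Pearson correlation
  expect_equal(partial_r2(fit, "x"), cor(d$x, d$y)^2, tolerance = 1e-10)

  d$z <- rnorm(10) * 1e-8  # essentially zero-coefficient term
  fit2 <- fit_lmm(y ~ x + z, d)
  expect_lt(partial_r2(fit2, "z"), 0.35)
  expect_error(partial_r2(fit2, "missing_term"), "not in the model")
})

test_that("Nakagawa R2 identities hold", {
  set.seed(44)
  d <- random_lmm_dataset(n_groups = 20, m = 6, V_ID = 1, V_res = 1)
  fit0 <- fit_lmm(y ~ 1 + (1 | g), d)
  r2 <- r2_nakagawa(fit0)
  expect_equal(unname(r2["marginal"]), 0)
  expect_equal(unname(r2["conditional"]), repeatability(fit0))

  d$gs <- sample(d$g)   # destroyed grouping: V_ID ~ 0
  fit1 <- fit_lmm(y ~ x + (1 | gs), d)
  r2b <- r2_nakagawa(fit1)
  expect_equal(unname(r2b["marginal"]), unname(r2b["conditional"]),
               tolerance = 0.02)
})

test_that("simulation CIs are reproducible, ordered, and labelled", {
  set.seed(10)
  d <- random_lmm_dataset(n_groups = 15, m = 8, V_ID = 0.8, V_res = 1)
  fit <- fit_lmm(y ~ 1 + (1 | g), d)
  a <- simulate_ci(fit, n_sim = 50, seed = 123)
  b <- simulate_ci(fit, n_sim = 50, seed = 123)
  expect_identical(a$ci_low, b$ci_low)
  expect_identical(a$ci_high, b$ci_high)
  expect_lte(a$ci_low, a$ci_high)
  expect_identical(a$kind, "raw")
  # the point estimate sits inside the interval, up to simulation noise
  expect_gte(a$R, a$ci_low - 0.05)
  expect_lte(a$R, a$ci_high + 0.05)

  fit_adj <- fit_lmm(y ~ x + (1 | g), d)
  expect_identical(simulate_ci(fit_adj, n_sim = 20, seed = 1)$kind, "adjusted")
})

test_that("repeatability on a log-transformed response stays in [0, 1]", {
  set.seed(71)
  d <- data.frame(g = rep(sprintf("g%02d", 1:20), each = 10))
  d$act <- exp(rep(rnorm(20), each = 10) + rnorm(200))
  fit <- fit_lmm(log(act) ~ 1 + (1 | g), d)
  R <- repeatability(fit)
  expect_true(R >= 0 && R <= 1)
  est <- simulate_ci(fit, n_sim = 40, seed = 2)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
})
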