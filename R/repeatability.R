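#' Repeatability (intraclass correlation) of a fitted mixed model
#'
#' The fraction of phenotypic variance attributable to consistent
#' among-individual differences: `R = V_ID / (V_ID + V_res)`. From an
#' intercept-only model this is the raw repeatability; with fixed-effect
#' covariates it is the adjusted repeatability.
#'
#' @param fit An [fit_lmm()] result with a grouping factor.
#' @return `R` in `[0, 1]`.
#' @export
repeatability <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) stop("model did not converge", call. = FALSE)
  if (is.null(fit$group))
    stop("repeatability requires a model with a random grouping factor", call. = FALSE)
  tot <- fit$V_ID + fit$V_res
  if (tot <= 0) stop("undefined repeatability: V_ID = V_res = 0", call. = FALSE)
  fit$V_ID / tot
}

#' Simulation-based confidence interval for repeatability
#'
#' Parametric model simulation: `n_sim` response vectors are drawn from the
#' fitted model (fixed effects + group effects `N(0, V_ID)` + residuals
#' `N(0, V_res)`), each is refitted to the same design, and the 2.5/97.5
#' percentile bounds (type-7 quantiles) of the simulated repeatability
#' distribution form the interval. Consistent among-individual differences
#' are called significant when the interval excludes zero.
#'
#' @param fit An [fit_lmm()] result with a grouping factor.
#' @param n_sim Number of model simulations (default 1000).
#' @param seed Optional integer seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `repeatability_estimate`: `R`, `ci_low`,
#'   `ci_high`, `kind` ("raw" for an intercept-only model, else "adjusted"),
#'   `n_sim`, `seed`, `significant`, and the vector of simulated values.
#' @export
simulate_ci <- function(fit, n_sim = 1000, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) stop("model did not converge", call. = FALSE)
  if (is.null(fit$group))
    stop("simulate_ci requires a model with a random grouping factor", call. = FALSE)
  if (n_sim < 2L) stop("n_sim must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  mu <- as.numeric(fit$X %*% fit$beta)
  gi <- as.integer(fit$g)
  G <- nlevels(fit$g)
  n <- length(mu)
  sd_id <- sqrt(fit$V_ID)
  sd_res <- sqrt(fit$V_res)

  sims <- vapply(seq_len(n_sim), function(j) {
    ystar <- mu + stats::rnorm(G, 0, sd_id)[gi] + stats::rnorm(n, 0, sd_res)
    pf <- tryCatch(refit_lmm_y(fit, ystar), error = function(e) NULL)
    if (is.null(pf) || !isTRUE(pf$converged)) return(NA_real_)
    pf$V_ID / (pf$V_ID + pf$V_res)
  }, numeric(1))

  fail <- mean(is.na(sims))
  if (fail > 0.2)
    stop(sprintf("CI unreliable: %.0f%% of model refits failed", 100 * fail),
         call. = FALSE)

  alpha <- (1 - level) / 2
  ci <- stats::quantile(sims, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE, type = 7)
  is_raw <- ncol(fit$X) == 1L && colnames(fit$X)[1L] == "(Intercept)"
  structure(list(
    R = repeatability(fit), ci_low = ci[1L], ci_high = ci[2L],
    kind = if (is_raw) "raw" else "adjusted",
    n_sim = n_sim, seed = seed, level = level,
    significant = ci[1L] > 0, sims = sims
  ), class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("%s repeatability R = %.3f, %g%% CI [%.3f, %.3f] (%d simulations)%s\n",
              x$kind, x$R, 100 * x$level, x$ci_low, x$ci_high, x$n_sim,
              if (x$significant) " *" else ""))
  invisible(x)
}
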