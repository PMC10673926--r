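#' Von Bertalanffy length at age
#'
#' `L(t) = Linf * (1 - exp(-K * (t - t0)))`: `Linf` is the asymptotic
#' standard length, `K` the growth coefficient (per day), `t0` the
#' theoretical age at zero length. Values for `t < t0` are negative and
#' returned as-is; prediction consumers clamp at zero (see
#' [predicted_size_at()]).
#'
#' @param t Age in days (vectorized).
#' @param Linf,K,t0 Growth parameters, or pass a `vb_params` list as `Linf`.
#' @return Length in cm.
#' @export
#' @examples
#' vb_length(c(0, 100, 1e5), Linf = 5, K = 0.02, t0 = 0)
vb_length <- function(t, Linf, K = NULL, t0 = NULL) {
  if (is.list(Linf)) {
    p <- Linf; Linf <- p$Linf; K <- p$K; t0 <- p$t0
  }
  Linf * (1 - exp(-K * (t - t0)))
}

#' Fit an individual von Bertalanffy growth curve
#'
#' Nonlinear least squares over `(Linf, K, t0)` by Levenberg-Marquardt
#' (through [minpack.lm::nlsLM()]). Starting values follow the classical
#' linearization: `Linf0 = 1.05 * max(length)`, then `K0` and `t00` from the
#' regression of `log(1 - L / Linf0)` on age. Three deterministically
#' perturbed restarts guard against local minima; the best-RSS solution is
#' returned. A fit is flagged
#' unconverged when all starts fail, when the series carries no growth signal
#' (constant lengths), or when the solution sits on a boundary (`K` at its
#' lower bound or `Linf` far beyond the data).
#'
#' @param records Data.frame with columns `age_days` and `length_cm` (and
#'   optionally `individual_id`) for one individual; at least 4 records at 4
#'   distinct ages.
#' @param individual_id Optional id stored in the result (defaults to the
#'   records' id column, if present).
#' @return An object of class `growth_fit`: `individual_id`, `params`
#'   (list `Linf, K, t0`), `rss`, `n_points`, `converged`.
#' @export
fit_vb <- function(records, individual_id = NULL) {
  if (!all(c("age_days", "length_cm") %in% names(records)))
    stop("records must have columns age_days and length_cm", call. = FALSE)
  records <- records[stats::complete.cases(records[c("age_days", "length_cm")]), ]
  if (is.null(individual_id))
    individual_id <- if ("individual_id" %in% names(records))
      as.character(records$individual_id[1L]) else NA_character_
  age <- records$age_days
  len <- records$length_cm
  if (length(age) < 4L || length(unique(age)) < 4L)
    stop("insufficient data: need >= 4 records at >= 4 distinct ages", call. = FALSE)
  if (any(len <= 0)) stop("lengths must be positive", call. = FALSE)

  out <- structure(list(individual_id = individual_id,
                        params = list(Linf = NA_real_, K = NA_real_, t0 = NA_real_),
                        rss = NA_real_, n_points = length(age), converged = FALSE),
                   class = "growth_fit")
  if (stats::sd(len) == 0) return(out)   # flat series: no growth signal

  Linf0 <- 1.05 * max(len)
  z <- log(pmax(1 - len / Linf0, 1e-8))
  init_lm <- stats::lm(z ~ age)
  K0 <- -unname(stats::coef(init_lm)[2L])
  if (!is.finite(K0) || K0 <= 0) K0 <- 0.01
  t00 <- unname(stats::coef(init_lm)[1L]) / K0
  if (!is.finite(t00)) t00 <- 0

  # deterministic perturbed restarts (keeps fits reproducible and the
  # ambient RNG untouched)
  starts <- list(c(Linf0, K0, t00),
                 c(Linf0 * 0.85, K0 * 1.6, t00 - 8),
                 c(Linf0 * 1.25, K0 * 0.6, t00 + 8),
                 c(Linf0 * 1.05, K0 * 2.2, t00 - 15))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        len ~ Linf * (1 - exp(-K * (age - t0))),
        start = list(Linf = s[1L], K = s[2L], t0 = s[3L]),
        lower = c(Linf = 1e-3, K = 1e-6, t0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) return(out)

  cf <- best$coef
  boundary <- cf[["K"]] <= 2e-6 || cf[["Linf"]] >= 5 * max(len)
  out$params <- list(Linf = unname(cf[["Linf"]]), K = unname(cf[["K"]]),
                     t0 = unname(cf[["t0"]]))
  out$rss <- best$rss
  out$converged <- !boundary
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: Linf = %.3f cm, K = %.5f /day, t0 = %.2f d (RSS %.4g, n = %d%s)\n",
              x$individual_id, x$params$Linf, x$params$K, x$params$t0,
              x$rss, x$n_points, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit growth curves for every individual in a size table
#'
#' @param sizes Data.frame `individual_id, age_days, length_cm`.
#' @return A list with `fits` (named list of [fit_vb()] results) and `table`
#'   (data.frame `individual_id, Linf, K, t0, rss, n_points, converged`).
#' @export
fit_vb_cohort <- function(sizes) {
  fits <- lapply(split(sizes, sizes$individual_id), fit_vb)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(individual_id = f$individual_id, Linf = f$params$Linf,
               K = f$params$K, t0 = f$params$t0, rss = f$rss,
               n_points = f$n_points, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Predicted standard length at a given age
#'
#' Evaluates the fitted growth curve; used for the size-at-parturition
#' covariates at each brood's parturition age. Negative predictions (ages
#' before `t0`) are clamped at zero with a warning.
#'
#' @param fit A converged [fit_vb()] result.
#' @param age Age in days (vectorized).
#' @return Predicted length(s) in cm.
#' @export
predicted_size_at <- function(fit, age) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged))
    stop("growth fit for ", fit$individual_id, " did not converge", call. = FALSE)
  L <- vb_length(age, fit$params)
  if (any(L < 0)) {
    warning("predicted length negative at some ages (before t0); clamped at 0")
    L <- pmax(L, 0)
  }
  L
}

#' Relationship between growth coefficient and asymptotic size
#'
#' Plain regression of `Linf` on `K` and mother identity (no random term):
#' larger fish approach their asymptote more slowly, so the `K` coefficient
#' is expected to be negative.
#'
#' @param growth_table Output table of [fit_vb_cohort()].
#' @param mother_ids Data.frame `individual_id, mother_id`.
#' @return A list with `fit` (the [fit_lmm()] OLS fit), `coef_K`,
#'   `r_squared`, and `pvalues`.
#' @export
k_linf_model <- function(growth_table, mother_ids) {
  d <- merge(growth_table[growth_table$converged, , drop = FALSE],
             mother_ids, by = "individual_id")
  if (nrow(d) < 5L)
    stop("need >= 5 converged growth fits", call. = FALSE)
  d$mother_id <- factor(d$mother_id)
  fit <- fit_lmm(Linf ~ K + mother_id, d)
  tss <- sum((d$Linf - mean(d$Linf))^2)
  list(fit = fit, coef_K = unname(fit$beta[["K"]]),
       r_squared = 1 - fit$RSS / tss,
       pvalues = fixed_effect_pvalues(fit))
}
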