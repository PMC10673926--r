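#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y = X beta + Z b + e`, `b ~ N(0, V_ID)`, `e ~ N(0, V_res)`, with a
#' single grouping factor, by profiling the variance ratio
#' `lambda = V_ID / V_res`: for fixed lambda the generalized-least-squares
#' solution is closed-form (via group-wise Woodbury algebra), leaving a
#' one-dimensional (restricted) profile log-likelihood in log(lambda) that is
#' scanned coarsely and then optimized. A profile maximized at the boundary
#' reports `V_ID = 0` exactly.
#'
#' The formula uses the grammar `response ~ term1 + term2 + term1:term2 +
#' (1 | group)`; the random-intercept part may instead be supplied through
#' `group`. With no grouping factor at all the model degenerates to ordinary
#' least squares (`V_ID = 0`), which is how plain linear models are handled
#' throughout the package.
#'
#' @param formula Model formula, e.g. `log(activity_cm_s) ~ length_cm *
#'   age_class + (1 | individual_id)`.
#' @param data A data.frame; rows with missing values in any referenced
#'   column are dropped (complete-case analysis).
#' @param group Name of the grouping column, if not given in the formula.
#' @param reml Use REML (default) or maximum likelihood.
#' @return An object of class `lmm_fit` with elements `beta`, `se`, `vcov`,
#'   `V_ID`, `V_res`, `lambda`, `loglik`, `n_obs`, `n_groups`, `converged`,
#'   and the design internals used by downstream inference.
#' @seealso [repeatability()], [simulate_ci()], [fixed_effect_pvalues()],
#'   [stepwise_backward()], [r2_nakagawa()], [partial_r2()]
#' @export
#' @examples
#' d <- data.frame(id = rep(letters[1:6], each = 4),
#'                 y = rep(rnorm(6), each = 4) + rnorm(24, sd = 0.5))
#' fit <- fit_lmm(y ~ 1 + (1 | id), d)
#' repeatability(fit)
fit_lmm <- function(formula, data, group = NULL, reml = TRUE) {
  pf <- parse_lmm_formula(formula)
  if (is.null(group)) group <- pf$group
  fixed <- pf$fixed

  vars <- unique(c(all.vars(fixed), group))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]

  g <- NULL
  if (!is.null(group)) {
    g <- factor(dat[[group]])
    if (nlevels(g) < 2L)
      stop("grouping factor '", group, "' needs >= 2 levels", call. = FALSE)
    ord <- order(g)
    dat <- dat[ord, , drop = FALSE]
    g <- g[ord]
  }

  mf <- stats::model.frame(fixed, dat)
  trm <- attr(mf, "terms")
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(trm, mf)
  p <- ncol(X)
  if (nrow(X) < p + 2L)
    stop("insufficient data: ", nrow(X), " complete rows for ", p, " parameters",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient fixed-effects design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  prof <- lmm_profile(y, X, g, reml = reml)

  structure(c(prof, list(
    fixed = fixed, group = group, terms = trm, assign = attr(X, "assign"),
    X = X, y = y, g = g, data = dat, reml = reml,
    n_obs = length(y), n_groups = if (is.null(g)) NA_integer_ else nlevels(g),
    call = match.call()
  )), class = "lmm_fit")
}

# Split "resp ~ fixed + (1 | g)" into the fixed-effects formula and the
# grouping-variable name. Only a single random intercept is supported.
parse_lmm_formula <- function(formula) {
  txt <- paste(deparse(formula), collapse = " ")
  m <- regmatches(txt, gregexpr("\\(\\s*1\\s*\\|\\s*[^)]+\\)", txt))[[1L]]
  if (length(m) > 1L)
    stop("only one random-intercept term (1 | group) is supported", call. = FALSE)
  group <- NULL
  if (length(m) == 1L) {
    group <- trimws(sub("\\)", "", sub(".*\\|", "", m)))
    txt <- gsub("\\+?\\s*\\(\\s*1\\s*\\|\\s*[^)]+\\)", "", txt)
    txt <- sub("~\\s*\\+", "~", txt)
    txt <- sub("~\\s*$", "~ 1", trimws(txt))
  }
  list(fixed = stats::as.formula(txt, env = environment(formula)), group = group)
}

# Core profiled (RE)ML engine on a prepared design. `g` must be sorted.
# Returns variance components, GLS fixed effects and the log-likelihood.
lmm_profile <- function(y, X, g = NULL, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  df <- if (reml) n - p else n

  if (is.null(g)) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    RSS <- sum((y - X %*% beta)^2)
    sigma2 <- RSS / df
    R <- qr.R(qrX)
    ldX <- 2 * sum(log(abs(diag(R))))
    loglik <- if (reml) -0.5 * (df * (log(2 * pi * sigma2) + 1) + ldX)
              else      -0.5 * (n * (log(2 * pi * sigma2) + 1))
    XtXinv <- chol2inv(chol(crossprod(X)))
    return(list(beta = stats::setNames(as.numeric(beta), colnames(X)),
                se = sqrt(diag(XtXinv) * sigma2),
                vcov = XtXinv * sigma2,
                V_ID = 0, V_res = sigma2, lambda = 0,
                loglik = loglik, RSS = RSS, converged = TRUE))
  }

  ni <- as.numeric(table(g))
  Sx <- rowsum(X, g, reorder = TRUE)
  sy <- as.numeric(rowsum(y, g, reorder = TRUE))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  eval_lambda <- function(lam) {
    w <- lam / (1 + lam * ni)
    XtVX <- XtX - crossprod(Sx, Sx * w)
    XtVy <- Xty - crossprod(Sx, sy * w)
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
    RSS <- max(yty - sum(w * sy^2) - sum(beta * XtVy), 1e-300)
    ld <- sum(log1p(lam * ni))
    ldX <- 2 * sum(log(diag(ch)))
    crit <- if (reml) ld + ldX + df * log(RSS) else ld + n * log(RSS)
    list(crit = crit, beta = beta, RSS = RSS, ch = ch, ld = ld, ldX = ldX)
  }

  loglams <- seq(-18, 12, length.out = 31)
  crits <- vapply(loglams, function(ll) eval_lambda(exp(ll))$crit, numeric(1))
  i0 <- which.min(crits)
  lo <- loglams[max(i0 - 1L, 1L)]
  hi <- loglams[min(i0 + 1L, length(loglams))]
  opt <- stats::optimize(function(ll) eval_lambda(exp(ll))$crit,
                         interval = c(lo, hi), tol = 1e-10)
  at0 <- eval_lambda(0)
  if (at0$crit <= opt$objective + 1e-9 || opt$minimum <= loglams[1L] + 1e-6) {
    lam <- 0
    sol <- at0
  } else {
    lam <- exp(opt$minimum)
    sol <- eval_lambda(lam)
  }

  sigma2 <- sol$RSS / df
  loglik <- if (reml)
    -0.5 * (sol$ld + sol$ldX + df * (log(2 * pi * sigma2) + 1))
  else
    -0.5 * (sol$ld + n * (log(2 * pi * sigma2) + 1))
  XtVXinv <- chol2inv(sol$ch)

  list(beta = stats::setNames(as.numeric(sol$beta), colnames(X)),
       se = sqrt(diag(XtVXinv) * sigma2),
       vcov = XtVXinv * sigma2,
       V_ID = lam * sigma2, V_res = sigma2, lambda = lam,
       loglik = loglik, RSS = sol$RSS,
       converged = is.finite(loglik))
}

# Refit the stored design to a new response (used by the simulation CI).
refit_lmm_y <- function(fit, y) {
  lmm_profile(y, fit$X, fit$g, reml = fit$reml)
}

#' @export
print.lmm_fit <- function(x, ...) {
  kind <- if (is.null(x$group)) "linear model (OLS)" else
    sprintf("random-intercept LMM (%s), group = %s",
            if (x$reml) "REML" else "ML", x$group)
  cat("<lmm_fit> ", kind, "\n", sep = "")
  cat(sprintf("  n = %d obs%s; logLik = %.3f\n", x$n_obs,
              if (is.na(x$n_groups)) "" else sprintf(", %d groups", x$n_groups),
              x$loglik))
  cat(sprintf("  V_ID = %.6g, V_res = %.6g\n", x$V_ID, x$V_res))
  coefs <- cbind(estimate = x$beta, se = x$se)
  print(round(coefs, 4))
  invisible(x)
}
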