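#' Per-term likelihood-ratio p-values for the fixed effects
#'
#' Each fixed-effect term is tested by a likelihood-ratio test between
#' maximum-likelihood fits of the model with and without that term, on the
#' complete-case rows of the full model. Terms contained in a higher-order
#' interaction still present in the model are flagged as non-removable
#' (marginality); their p-values are reported but [stepwise_backward()] never
#' removes them while the interaction remains.
#'
#' @param fit An [fit_lmm()] result (REML or ML; refits are always ML).
#' @return A data.frame `term, df, chisq, p, removable`.
#' @export
fixed_effect_pvalues <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  labels <- attr(fit$terms, "term.labels")
  if (!length(labels))
    return(data.frame(term = character(0), df = integer(0), chisq = numeric(0),
                      p = numeric(0), removable = logical(0)))

  full_ml <- if (fit$reml)
    fit_lmm(fit$fixed, fit$data, group = fit$group, reml = FALSE) else fit
  p_full <- length(full_ml$beta)

  fac <- attr(fit$terms, "factors")
  ord <- attr(fit$terms, "order")
  contained <- vapply(seq_along(labels), function(i) {
    any(vapply(seq_along(labels), function(j) {
      j != i && ord[j] > ord[i] && all(fac[, i] == 0 | fac[, j] > 0)
    }, logical(1)))
  }, logical(1))

  rows <- lapply(seq_along(labels), function(i) {
    red <- stats::update(fit$fixed, paste(". ~ . -", labels[i]))
    red_ml <- tryCatch(fit_lmm(red, fit$data, group = fit$group, reml = FALSE),
                       error = function(e) NULL)
    if (is.null(red_ml) || !isTRUE(red_ml$converged))
      return(data.frame(term = labels[i], df = NA_integer_, chisq = NA_real_,
                        p = NA_real_, removable = !contained[i]))
    dfi <- p_full - length(red_ml$beta)
    ch <- max(2 * (full_ml$loglik - red_ml$loglik), 0)
    data.frame(term = labels[i], df = dfi, chisq = ch,
               p = stats::pchisq(ch, dfi, lower.tail = FALSE),
               removable = !contained[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise-backward selection of fixed effects
#'
#' Starting from the full model, iteratively removes the removable,
#' non-protected term with the largest likelihood-ratio p-value at or above
#' `alpha`, until every remaining candidate has `p < alpha`. Removal respects
#' marginality (an interaction is tested before its marginal terms, which are
#' never removed while it remains). Ties are broken by larger p, then by term
#' order. Complete cases are fixed once from the full model so all nested
#' comparisons use the same rows.
#'
#' @param formula Full model formula (may contain `(1 | group)`).
#' @param data Data.frame.
#' @param group Grouping-variable name (if not in the formula).
#' @param alpha Removal threshold (default 0.05).
#' @param protected Character vector of variable names that must stay in the
#'   model (e.g. mother identity, size at parturition); any term involving a
#'   protected variable is kept.
#' @return A list of class `stepwise_fit`: `formula` (final), `fit` (REML fit
#'   of the final model), `pvalues` (final-term tests), `steps` (removal log),
#'   `n_obs`.
#' @export
stepwise_backward <- function(formula, data, group = NULL, alpha = 0.05,
                              protected = character()) {
  pf <- parse_lmm_formula(formula)
  if (is.null(group)) group <- pf$group
  vars <- unique(c(all.vars(pf$fixed), group))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- data[stats::complete.cases(data[vars]), , drop = FALSE]

  cur <- pf$fixed
  steps <- data.frame(term = character(0), p = numeric(0))
  repeat {
    fit_ml <- fit_lmm(cur, dat, group = group, reml = FALSE)
    pv <- fixed_effect_pvalues(fit_ml)
    if (!nrow(pv)) break
    prot <- vapply(pv$term, function(tm) {
      any(all.vars(stats::reformulate(tm)) %in% protected)
    }, logical(1))
    cand <- which(pv$removable & !prot & !is.na(pv$p) & pv$p >= alpha)
    if (!length(cand)) break
    drop_i <- cand[which.max(pv$p[cand])]
    steps <- rbind(steps, data.frame(term = pv$term[drop_i], p = pv$p[drop_i]))
    cur <- stats::update(cur, paste(". ~ . -", pv$term[drop_i]))
  }

  final <- fit_lmm(cur, dat, group = group, reml = TRUE)
  structure(list(formula = cur, fit = final,
                 pvalues = fixed_effect_pvalues(final),
                 steps = steps, n_obs = final$n_obs, group = group,
                 alpha = alpha, protected = protected),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> final model: ",
      paste(deparse(x$formula), collapse = " "), "\n", sep = "")
  if (nrow(x$steps))
    cat("  removed:", paste(sprintf("%s (p = %.3f)", x$steps$term, x$steps$p),
                            collapse = ", "), "\n")
  print(x$fit)
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R-squared: marginal
#' `var(X beta) / (var(X beta) + V_ID + V_res)` is the variance explained by
#' the fixed effects alone; conditional adds the among-individual variance to
#' the numerator.
#'
#' @param fit An [fit_lmm()] result.
#' @return Named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  varF <- if (ncol(fit$X) == 1L) 0 else stats::var(as.numeric(fit$X %*% fit$beta))
  tot <- varF + fit$V_ID + fit$V_res
  c(marginal = varF / tot, conditional = (varF + fit$V_ID) / tot)
}

#' Partial R-squared of one fixed-effect term
#'
#' For a model without a random term this is the classical semi-partial
#' `Delta RSS / RSS_reduced`, which for a single-df term equals
#' `t^2 / (t^2 + df_res)`. For a mixed model it is the drop in marginal
#' R-squared ([r2_nakagawa()]) when the term is removed, floored at zero.
#'
#' @param fit An [fit_lmm()] result.
#' @param term A term label present in the model (e.g. `"feeding_min"`).
#' @return Partial R-squared in `[0, 1]`.
#' @export
partial_r2 <- function(fit, term) {
  stopifnot(inherits(fit, "lmm_fit"))
  labels <- attr(fit$terms, "term.labels")
  if (!term %in% labels)
    stop("term '", term, "' is not in the model (terms: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  red_formula <- stats::update(fit$fixed, paste(". ~ . -", term))
  red <- fit_lmm(red_formula, fit$data, group = fit$group, reml = fit$reml)
  if (is.null(fit$group)) {
    dRSS <- max(red$RSS - fit$RSS, 0)
    dRSS / (dRSS + fit$RSS)
  } else {
    max(r2_nakagawa(fit)[["marginal"]] - r2_nakagawa(red)[["marginal"]], 0)
  }
}
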