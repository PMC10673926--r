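#' Build reproductive profiles from brood and offspring tables
#'
#' Joins per-brood counts with measured offspring lengths, derives the onset
#' of reproduction (age at first parturition), and fills each brood's
#' `female_size_at_parturition` from the individual's fitted growth curve.
#' Individuals present in the growth fits but without any brood are excluded
#' with a message (mirroring the exclusion of females without reproductive
#' data). Broods whose offspring were not measured keep `NA` mean length and
#' stay available for brood-size analyses.
#'
#' @param broods Data.frame `individual_id, mother_id, brood_id,
#'   age_at_parturition_days, brood_size` (a `measured` flag is optional).
#' @param offspring Data.frame `individual_id, brood_id, length_cm`.
#' @param growth_fits Named list of converged [fit_vb()] results (as from
#'   [fit_vb_cohort()]`$fits`), one per reproducing individual.
#' @return An object of class `repro_profiles`: `broods` (augmented per-brood
#'   table with `onset`, `mean_offspring_length`, `n_measured`,
#'   `female_size_at_parturition`), `summary` (one row per individual), and
#'   `n_excluded` (individuals with growth data but no broods).
#' @export
build_profiles <- function(broods, offspring, growth_fits) {
  need <- c("individual_id", "mother_id", "brood_id",
            "age_at_parturition_days", "brood_size")
  if (!all(need %in% names(broods)))
    stop("broods table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(broods$brood_size < 1))
    stop("brood_size must be >= 1", call. = FALSE)
  if (any(broods$age_at_parturition_days <= 0))
    stop("data error: brood at or before birth", call. = FALSE)

  broods <- broods[order(broods$individual_id, broods$age_at_parturition_days), ]
  dup <- unlist(tapply(broods$age_at_parturition_days, broods$individual_id,
                       function(a) duplicated(a)))
  if (any(dup))
    stop("data error: non-increasing parturition ages within an individual",
         call. = FALSE)

  agg <- stats::aggregate(length_cm ~ brood_id, data = offspring,
                          FUN = function(x) c(m = mean(x), n = length(x)))
  mo <- data.frame(brood_id = agg$brood_id,
                   mean_offspring_length = agg$length_cm[, "m"],
                   n_measured = as.integer(agg$length_cm[, "n"]),
                   stringsAsFactors = FALSE)
  broods <- merge(broods, mo, by = "brood_id", all.x = TRUE, sort = FALSE)
  broods$n_measured[is.na(broods$n_measured)] <- 0L
  if (any(broods$n_measured > broods$brood_size))
    stop("measured offspring exceed brood_size for some broods", call. = FALSE)

  ids <- unique(broods$individual_id)
  no_fit <- ids[!ids %in% names(growth_fits)]
  if (length(no_fit))
    stop("no growth fit for reproducing individuals: ",
         paste(no_fit, collapse = ", "), call. = FALSE)
  broods$female_size_at_parturition <- NA_real_
  for (id in ids) {
    sel <- broods$individual_id == id
    broods$female_size_at_parturition[sel] <-
      predicted_size_at(growth_fits[[id]], broods$age_at_parturition_days[sel])
  }

  onset <- tapply(broods$age_at_parturition_days, broods$individual_id, min)
  broods$onset <- as.numeric(onset[broods$individual_id])

  smry <- do.call(rbind, lapply(split(broods, broods$individual_id), function(b) {
    data.frame(individual_id = b$individual_id[1L],
               mother_id = b$mother_id[1L],
               onset = min(b$age_at_parturition_days),
               n_broods = nrow(b),
               mean_brood_size = mean(b$brood_size),
               mean_offspring_length = if (all(is.na(b$mean_offspring_length)))
                 NA_real_ else mean(b$mean_offspring_length, na.rm = TRUE),
               total_offspring = sum(b$brood_size),
               stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL

  n_excluded <- sum(!names(growth_fits) %in% ids)
  if (n_excluded > 0)
    message(n_excluded, " individual(s) with no broods excluded from reproductive profiles")

  broods <- broods[order(broods$individual_id, broods$age_at_parturition_days), ]
  rownames(broods) <- NULL
  structure(list(broods = broods, summary = smry, n_excluded = n_excluded),
            class = "repro_profiles")
}

#' @export
print.repro_profiles <- function(x, ...) {
  cat(sprintf("<repro_profiles> %d individuals, %d broods (%d with measured offspring)\n",
              nrow(x$summary), nrow(x$broods), sum(x$broods$n_measured > 0)))
  invisible(x)
}

#' Cumulative number of offspring produced by an individual
#'
#' Right-continuous step function: the summed sizes of all broods with
#' parturition age at or before `t`.
#'
#' @param profiles A [build_profiles()] result (or its per-brood table).
#' @param individual_id The individual.
#' @param t Ages in days (vectorized).
#' @return Integer counts, non-decreasing in `t`.
#' @export
cumulative_offspring <- function(profiles, individual_id, t) {
  b <- if (inherits(profiles, "repro_profiles")) profiles$broods else profiles
  b <- b[b$individual_id == individual_id, , drop = FALSE]
  vapply(t, function(tt) sum(b$brood_size[b$age_at_parturition_days <= tt]),
         numeric(1))
}

#' Trade-off-adjusted models for offspring size and brood size
#'
#' Two random-intercept mixed models on per-brood rows: (a) mean offspring
#' length on brood size, onset, female size at parturition, and mother
#' identity; (b) brood size on mean offspring length plus the same
#' covariates. Together they quantify the size-number trade-off while
#' controlling for onset, body size, and descent; their variance components
#' give the adjusted repeatabilities of both traits. Raw (intercept-only)
#' fits are returned alongside: the brood-size raw fit uses every brood, the
#' offspring-size models only broods with measured offspring.
#'
#' @param profiles A [build_profiles()] result with at least 2 broods for at
#'   least 2 individuals.
#' @return A list of class `tradeoff_models`: `offspring_model`,
#'   `brood_model` (adjusted REML fits), `offspring_raw`, `brood_raw`,
#'   `tradeoff_estimate` (brood-size coefficient in the offspring model, with
#'   its standard error, p-value, and partial R-squared), and the row counts
#'   `n_broods`, `n_measured`.
#' @export
tradeoff_models <- function(profiles) {
  stopifnot(inherits(profiles, "repro_profiles"))
  b <- profiles$broods
  b$mother_id <- factor(b$mother_id)
  multi <- table(b$individual_id)
  if (sum(multi >= 2) < 2)
    stop("need >= 2 broods for >= 2 individuals", call. = FALSE)
  meas <- b[!is.na(b$mean_offspring_length), , drop = FALSE]

  off_fit <- fit_lmm(mean_offspring_length ~ brood_size + onset +
                       female_size_at_parturition + mother_id + (1 | individual_id),
                     meas)
  brood_fit <- fit_lmm(brood_size ~ mean_offspring_length + onset +
                         female_size_at_parturition + mother_id + (1 | individual_id),
                       meas)
  off_raw <- fit_lmm(mean_offspring_length ~ 1 + (1 | individual_id), meas)
  brood_raw <- fit_lmm(brood_size ~ 1 + (1 | individual_id), b)

  pv <- fixed_effect_pvalues(off_fit)
  tradeoff <- list(
    estimate = unname(off_fit$beta[["brood_size"]]),
    se = unname(off_fit$se[[which(names(off_fit$beta) == "brood_size")]]),
    p = pv$p[pv$term == "brood_size"],
    partial_r2 = partial_r2(off_fit, "brood_size")
  )

  structure(list(offspring_model = off_fit, brood_model = brood_fit,
                 offspring_raw = off_raw, brood_raw = brood_raw,
                 tradeoff_estimate = tradeoff,
                 n_broods = nrow(b), n_measured = nrow(meas)),
            class = "tradeoff_models")
}

#' @export
print.tradeoff_models <- function(x, ...) {
  cat(sprintf("<tradeoff_models> %d broods (%d with measured offspring)\n",
              x$n_broods, x$n_measured))
  cat(sprintf("  size-number trade-off: %.4f cm/offspring (p = %.3g, partial R2 = %.3f)\n",
              x$tradeoff_estimate$estimate, x$tradeoff_estimate$p,
              x$tradeoff_estimate$partial_r2))
  invisible(x)
}
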