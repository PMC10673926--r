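# Pipeline stages: behavior repeatabilities -> growth -> reproduction ->
# linkage models, plus the run_all orchestrator producing a results bundle.

rep_row <- function(trait, est, fit) {
  data.frame(trait = trait, kind = est$kind, R = est$R,
             ci_low = est$ci_low, ci_high = est$ci_high,
             n_sim = est$n_sim, seed = if (is.null(est$seed)) NA_integer_ else est$seed,
             n_obs = fit$n_obs, n_groups = fit$n_groups,
             significant = est$significant, stringsAsFactors = FALSE)
}

#' Behavior stage: repeatabilities and the activity-feeding relationship
#'
#' Computes raw repeatability for (log-)activity and feeding time, adjusted
#' repeatability controlling for body size and age class (weeks 1-4 as a
#' 4-level factor) plus their interaction, and the mixed model of daily
#' activity on daily feeding time.
#'
#' @param behavior Data.frame `individual_id, day, activity_cm_s,
#'   feeding_min, length_cm` (`length_cm` is the predicted size at that day;
#'   required for the adjusted models).
#' @param n_sim Simulations for each repeatability CI.
#' @param seed Base seed; each CI uses a deterministic offset.
#' @param log_activity Log-transform activity before the repeatability models
#'   (the default; daily activity is right-skewed).
#' @return A list: `repeatability` (4-row table), `models` (the four fits),
#'   `activity_feeding` (fit, slope, p, marginal R-squared).
#' @export
run_behavior_stage <- function(behavior, n_sim = 1000, seed = 1L,
                               log_activity = TRUE) {
  need <- c("individual_id", "day", "activity_cm_s", "feeding_min", "length_cm")
  miss <- setdiff(need, names(behavior))
  if (length(miss))
    stop("behavior table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  behavior$age_class <- factor(ceiling(behavior$day / 7))
  act_resp <- if (log_activity) "log(activity_cm_s)" else "activity_cm_s"

  f_raw_act <- stats::as.formula(paste(act_resp, "~ 1 + (1 | individual_id)"))
  f_adj_act <- stats::as.formula(paste(
    act_resp, "~ length_cm * age_class + (1 | individual_id)"))
  raw_act <- fit_lmm(f_raw_act, behavior)
  adj_act <- fit_lmm(f_adj_act, behavior)
  raw_feed <- fit_lmm(feeding_min ~ 1 + (1 | individual_id), behavior)
  adj_feed <- fit_lmm(feeding_min ~ length_cm * age_class + (1 | individual_id),
                      behavior)

  ests <- list(
    rep_row("activity", simulate_ci(raw_act, n_sim, seed = seed + 1L), raw_act),
    rep_row("activity", simulate_ci(adj_act, n_sim, seed = seed + 2L), adj_act),
    rep_row("feeding", simulate_ci(raw_feed, n_sim, seed = seed + 3L), raw_feed),
    rep_row("feeding", simulate_ci(adj_feed, n_sim, seed = seed + 4L), adj_feed)
  )

  af <- fit_lmm(activity_cm_s ~ feeding_min + (1 | individual_id), behavior)
  af_p <- fixed_effect_pvalues(af)
  activity_feeding <- list(
    fit = af,
    slope = unname(af$beta[["feeding_min"]]),
    p = af_p$p[af_p$term == "feeding_min"],
    r2_marginal = r2_nakagawa(af)[["marginal"]]
  )

  list(repeatability = do.call(rbind, ests),
       models = list(raw_activity = raw_act, adjusted_activity = adj_act,
                     raw_feeding = raw_feed, adjusted_feeding = adj_feed),
       activity_feeding = activity_feeding)
}

#' Growth stage: individual growth curves and the K-Linf relationship
#'
#' @param sizes Data.frame `individual_id, age_days, length_cm`.
#' @param mother_ids Data.frame `individual_id, mother_id`.
#' @return A list: `fits`, `table` (per-individual parameters), `k_linf`
#'   (see [k_linf_model()]).
#' @export
run_growth_stage <- function(sizes, mother_ids) {
  gc <- fit_vb_cohort(sizes)
  n_bad <- sum(!gc$table$converged)
  if (n_bad > 0)
    message(n_bad, " growth fit(s) did not converge and are excluded downstream")
  list(fits = gc$fits, table = gc$table,
       k_linf = k_linf_model(gc$table, mother_ids))
}

#' Reproduction stage: profiles, trade-off models, and repeatabilities
#'
#' @param broods,offspring Brood and offspring tables (see
#'   [build_profiles()]).
#' @param growth_fits Named list of converged growth fits.
#' @param n_sim,seed As in [run_behavior_stage()].
#' @return A list: `profiles`, `tradeoff` (see [tradeoff_models()]), and a
#'   4-row `repeatability` table (raw/adjusted x brood size/offspring size).
#' @export
run_reproduction_stage <- function(broods, offspring, growth_fits,
                                   n_sim = 1000, seed = 1L) {
  profiles <- build_profiles(broods, offspring, growth_fits)
  tm <- tradeoff_models(profiles)
  ests <- list(
    rep_row("offspring_size", simulate_ci(tm$offspring_raw, n_sim, seed = seed + 5L),
            tm$offspring_raw),
    rep_row("offspring_size", simulate_ci(tm$offspring_model, n_sim, seed = seed + 6L),
            tm$offspring_model),
    rep_row("brood_size", simulate_ci(tm$brood_raw, n_sim, seed = seed + 7L),
            tm$brood_raw),
    rep_row("brood_size", simulate_ci(tm$brood_model, n_sim, seed = seed + 8L),
            tm$brood_model)
  )
  list(profiles = profiles, tradeoff = tm,
       repeatability = do.call(rbind, ests))
}

# One row per candidate term of a linkage model: retained after stepwise,
# with the full-model estimate and LRT p-value for reference.
linkage_rows <- function(model_name, sw, full_fit) {
  full_p <- fixed_effect_pvalues(full_fit)
  final_terms <- attr(sw$fit$terms, "term.labels")
  single <- table(names(full_fit$beta))  # not used; estimates mapped below
  est <- vapply(full_p$term, function(tm) {
    cols <- which(full_fit$assign == match(tm, attr(full_fit$terms, "term.labels")))
    if (length(cols) == 1L) unname(full_fit$beta[cols]) else NA_real_
  }, numeric(1))
  data.frame(model = model_name, term = full_p$term,
             estimate_full = est, p_full = full_p$p,
             retained = full_p$term %in% final_terms,
             stringsAsFactors = FALSE)
}

#' Linkage stage: behavior, growth, and reproduction models
#'
#' Fits the three families of association models, each reduced by
#' [stepwise_backward()] with mother identity (and the mandated covariates)
#' protected:
#' \itemize{
#'   \item direct models: brood size and offspring size (mixed, per-brood
#'     rows, controlling for female size at parturition) and onset (plain
#'     regression) on mean activity and mean feeding;
#'   \item growth models: `Linf` on activity + feeding, and `K` on activity +
#'     feeding with `Linf` as a protected covariate;
#'   \item growth-to-reproduction models: brood size, offspring size (mixed,
#'     with female age at parturition as covariate) and onset on `K` and
#'     `Linf`.
#' }
#' Individuals lacking any stage's data are dropped listwise with a message.
#'
#' @param behavior Behavior table (as in [run_behavior_stage()]).
#' @param growth_table Per-individual growth parameters
#'   ([fit_vb_cohort()]`$table`).
#' @param profiles A [build_profiles()] result.
#' @param alpha Stepwise removal threshold.
#' @return A list of class `linkage_results`: the eight `stepwise_fit`
#'   objects (named), and `table` summarizing every candidate term.
#' @export
run_linkage_stage <- function(behavior, growth_table, profiles, alpha = 0.05) {
  means <- stats::aggregate(
    cbind(mean_activity = activity_cm_s, mean_feeding = feeding_min) ~ individual_id,
    data = behavior, FUN = mean, na.rm = TRUE, na.action = stats::na.pass)

  ind <- merge(profiles$summary, growth_table[growth_table$converged,
                                              c("individual_id", "Linf", "K")],
               by = "individual_id")
  ind <- merge(ind, means, by = "individual_id")
  ok <- stats::complete.cases(ind[c("mean_activity", "mean_feeding", "Linf",
                                    "K", "onset")])
  if (any(!ok))
    message("dropped from linkage (incomplete data): ",
            paste(ind$individual_id[!ok], collapse = ", "))
  ind <- ind[ok, , drop = FALSE]
  ind$mother_id <- factor(ind$mother_id)

  bb <- merge(profiles$broods,
              ind[c("individual_id", "mean_activity", "mean_feeding", "Linf", "K")],
              by = "individual_id")
  bb$mother_id <- factor(bb$mother_id)
  bb$female_age <- bb$age_at_parturition_days

  sw <- function(f, d, prot) stepwise_backward(f, d, alpha = alpha, protected = prot)
  full <- function(f, d) fit_lmm(f, d)

  models <- list(
    direct_brood = list(
      f = brood_size ~ mean_activity + mean_feeding + female_size_at_parturition +
        mother_id + (1 | individual_id),
      d = bb, prot = c("mother_id", "female_size_at_parturition")),
    direct_offspring = list(
      f = mean_offspring_length ~ mean_activity + mean_feeding +
        female_size_at_parturition + mother_id + (1 | individual_id),
      d = bb, prot = c("mother_id", "female_size_at_parturition")),
    direct_onset = list(
      f = onset ~ mean_activity + mean_feeding + mother_id,
      d = ind, prot = "mother_id"),
    growth_linf = list(
      f = Linf ~ mean_activity + mean_feeding + mother_id,
      d = ind, prot = "mother_id"),
    growth_k = list(
      f = K ~ mean_activity + mean_feeding + Linf + mother_id,
      d = ind, prot = c("mother_id", "Linf")),
    repro_brood = list(
      f = brood_size ~ K + Linf + female_age + mother_id + (1 | individual_id),
      d = bb, prot = "mother_id"),
    repro_offspring = list(
      f = mean_offspring_length ~ K + Linf + female_age + mother_id +
        (1 | individual_id),
      d = bb, prot = "mother_id"),
    repro_onset = list(
      f = onset ~ K + Linf + mother_id,
      d = ind, prot = "mother_id")
  )

  fits <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    list(stepwise = sw(m$f, m$d, m$prot), full = full(m$f, m$d))
  })
  names(fits) <- names(models)

  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    linkage_rows(nm, fits[[nm]]$stepwise, fits[[nm]]$full)
  }))
  rownames(tab) <- NULL

  structure(list(fits = fits, table = tab, n_individuals = nrow(ind)),
            class = "linkage_results")
}

#' @export
print.linkage_results <- function(x, ...) {
  cat(sprintf("<linkage_results> %d individuals\n", x$n_individuals))
  print(x$table, digits = 4)
  invisible(x)
}

#' Run the full individuality analysis
#'
#' Orchestrates every stage on a (synthetic or real) study: growth curves are
#' fitted first, predicted sizes are attached to the behavior table, then the
#' behavior, reproduction, and linkage stages run. The returned bundle
#' carries an 8-row repeatability table (raw and adjusted for activity,
#' feeding, brood size, offspring size), the activity-feeding model, the
#' growth and K-Linf results, the trade-off models, the linkage tables, and
#' a provenance block (seed, config hash, package version). Identical seeds
#' give identical bundles.
#'
#' @param study A `sim_study` (from [simulate_study()]) or a list with the
#'   same `behavior`, `sizes`, `broods`, `offspring` tables; `broods` must
#'   carry `mother_id`.
#' @param n_sim Simulations per repeatability CI (default 1000).
#' @param alpha Stepwise threshold.
#' @param seed Base seed for all CI simulations.
#' @param log_activity Log-transform activity for its repeatability models.
#' @return An object of class `results_bundle`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_individuals = 12, seed = 3))
#' bundle <- run_all(study, n_sim = 50, seed = 3)
#' bundle$repeatability
#' }
run_all <- function(study, n_sim = 1000, alpha = 0.05, seed = 1L,
                    log_activity = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  mothers <- unique(study$broods[c("individual_id", "mother_id")])

  growth <- run_growth_stage(study$sizes, mothers)
  message(sprintf("[growth] %d fits (%d converged) in %.1fs",
                  nrow(growth$table), sum(growth$table$converged),
                  proc.time()[["elapsed"]] - t0))

  behavior <- study$behavior
  behavior$length_cm <- NA_real_
  for (id in names(growth$fits)) {
    f <- growth$fits[[id]]
    if (isTRUE(f$converged)) {
      sel <- behavior$individual_id == id
      behavior$length_cm[sel] <- predicted_size_at(f, behavior$day[sel])
    }
  }

  beh <- run_behavior_stage(behavior, n_sim = n_sim, seed = seed,
                            log_activity = log_activity)
  message(sprintf("[behavior] %d rows, 4 repeatabilities in %.1fs",
                  nrow(behavior), proc.time()[["elapsed"]] - t0))

  conv <- Filter(function(f) isTRUE(f$converged), growth$fits)
  repro <- run_reproduction_stage(study$broods, study$offspring, conv,
                                  n_sim = n_sim, seed = seed)
  message(sprintf("[reproduction] %d broods in %.1fs",
                  nrow(repro$profiles$broods), proc.time()[["elapsed"]] - t0))

  linkage <- run_linkage_stage(behavior, growth$table, repro$profiles,
                               alpha = alpha)
  message(sprintf("[linkage] %d individuals in %.1fs",
                  linkage$n_individuals, proc.time()[["elapsed"]] - t0))

  cfg <- if (!is.null(study$config)) study$config else NULL
  structure(list(
    repeatability = rbind(beh$repeatability, repro$repeatability),
    behavior = beh, growth = growth, reproduction = repro, linkage = linkage,
    provenance = list(seed = seed, n_sim = n_sim, alpha = alpha,
                      log_activity = log_activity,
                      config_hash = object_hash(cfg),
                      version = as.character(utils::packageVersion("indilife")))
  ), class = "results_bundle")
}

# md5 of a serialized object, for provenance (NULL-safe).
object_hash <- function(x) {
  if (is.null(x)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle> version ", x$provenance$version,
      ", seed ", x$provenance$seed, "\n", sep = "")
  cat("Repeatabilities:\n")
  print(x$repeatability[c("trait", "kind", "R", "ci_low", "ci_high", "significant")],
        digits = 3)
  cat(sprintf("Activity ~ feeding: slope %.3f (p = %.3g, marginal R2 = %.3f)\n",
              x$behavior$activity_feeding$slope, x$behavior$activity_feeding$p,
              x$behavior$activity_feeding$r2_marginal))
  cat(sprintf("K-Linf model: coef(K) = %.2f, R2 = %.3f\n",
              x$growth$k_linf$coef_K, x$growth$k_linf$r_squared))
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Writes `repeatability.csv`, `growth_fits.csv`, `linkage.csv`,
#' `profile_summary.csv`, and `bundle.json` (scalar results + provenance).
#'
#' @param bundle A [run_all()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(bundle$repeatability, file.path(dir, "repeatability.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$growth$table, file.path(dir, "growth_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$linkage$table, file.path(dir, "linkage.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$reproduction$profiles$summary,
                   file.path(dir, "profile_summary.csv"), row.names = FALSE)
  scalars <- list(
    activity_feeding_slope = bundle$behavior$activity_feeding$slope,
    k_linf_coef = bundle$growth$k_linf$coef_K,
    k_linf_r2 = bundle$growth$k_linf$r_squared,
    tradeoff_estimate = bundle$reproduction$tradeoff$tradeoff_estimate$estimate,
    provenance = bundle$provenance
  )
  jsonlite::write_json(scalars, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
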