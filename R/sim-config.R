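#' Simulation configuration for a synthetic clonal cohort
#'
#' Bundles every parameter of the synthetic-data generator: cohort layout
#' (individuals, behavior days, life-history horizon), trajectory recording
#' geometry (arena, feeding zone, time step, phase durations), the latent
#' among-/within-individual variance structure of the two behavioral traits,
#' von Bertalanffy growth parameters and their coupling to feeding, and the
#' reproductive process (onset, gestation, brood size, offspring size,
#' size-number trade-off).
#'
#' Defaults emulate a cohort of 34 clonal fish observed daily over their first
#' 28 days of life (8 h activity phase + 2 h feeding phase at 0.2 s
#' resolution), measured weekly for 280 days, and reproducing from roughly
#' day 170 at ~30-day gestation intervals, which yields about 4.5 broods per
#' female by day 280.
#'
#' @param n_individuals Number of focal individuals.
#' @param n_days_behavior Days of daily behavioral recording.
#' @param horizon_days Length of the life-history observation window (days).
#' @param step_s Trajectory sampling interval (seconds). Reducible for tests.
#' @param activity_phase_h,feeding_phase_h Durations (hours) of the daily
#'   activity and feeding recording phases.
#' @param arena_w_cm,arena_h_cm Arena width/height (cm). Not reported for the
#'   original tanks; defaults are a plausible 20 x 20 cm observation arena.
#' @param zone_w_cm,zone_h_cm Feeding-zone width/height (cm); the rectangle
#'   around the stationary food patch (5 x 13 cm).
#' @param mean_log_activity Population mean of log daily activity (log cm/s).
#' @param V_ID_act,V_res_act Among-/within-individual variance of log-activity.
#' @param mean_feeding_min Population mean daily feeding time (minutes).
#' @param V_ID_feed,V_res_feed Among-/within-individual variance of feeding
#'   time (min^2).
#' @param rho_act_feed Correlation between activity and feeding, applied both
#'   to the latent intercepts and to the daily residuals (negative: more
#'   active fish — and more active days — leave less time at the stationary
#'   food patch).
#' @param vb_Linf_base Baseline asymptotic standard length (cm) at zero mean
#'   feeding.
#' @param beta_feed_Linf Increase in asymptotic length (cm) per minute of mean
#'   daily feeding time: the feeding -> growth link.
#' @param sigma_Linf SD (cm) of the individual asymptotic-length residual.
#' @param vb_K_mean,vb_K_sd Mean and residual SD of the growth coefficient K
#'   (per day).
#' @param k_linf_slope Change in K per cm of asymptotic-length deviation
#'   (negative: larger fish approach their asymptote more slowly).
#' @param vb_t0_mean,vb_t0_sd Mean and SD of t0 (days), the theoretical age at
#'   zero length. Negative t0 gives a realistic positive length at birth.
#' @param sigma_length SD (cm) of the weekly length measurement error.
#' @param gestation_days Mean interval between successive broods (days).
#' @param gestation_jitter_sd SD (days) of inter-brood-interval jitter.
#' @param onset_base Mean age at first parturition (days).
#' @param onset_slope_Linf Increase in onset age (days) per cm of
#'   asymptotic-length deviation (larger fish start reproducing later).
#' @param onset_sd Residual SD of onset age (days).
#' @param brood_size_mean Mean brood size (offspring per brood).
#' @param V_ID_broodsize Among-individual variance of log brood-size
#'   productivity.
#' @param broodsize_size_slope Effect of female size at parturition (per cm,
#'   log scale) on brood size.
#' @param broodsize_disp_sd Brood-level log-normal over-dispersion SD of the
#'   Poisson brood-size rate.
#' @param offsize_base Mean newborn standard length (cm).
#' @param tradeoff_slope Change in mean offspring length (cm) per additional
#'   offspring in the brood (negative: size-number trade-off).
#' @param V_ID_offsize Among-individual variance (cm^2) of mean offspring
#'   length: individual productivity in offspring size.
#' @param offsize_size_slope Effect of female size at parturition on mean
#'   offspring length (cm per cm).
#' @param sigma_brood_offsize Brood-level SD (cm) of mean offspring length.
#' @param sigma_offspring Within-brood SD (cm) of individual offspring length.
#' @param n_mothers Number of (clonal) mothers of the focal cohort.
#' @param mother_sd_Linf,mother_sd_offsize SD of mother-identity effects on
#'   asymptotic length (cm) and offspring length (cm).
#' @param p_dropout_activity,p_dropout_feeding Per-recording probability that
#'   an activity/feeding recording is lost to technical issues (default off).
#' @param p_brood_unmeasured Probability that a brood is counted but its
#'   offspring are not measured.
#' @param base_speed_cm_s Baseline per-step swimming speed (cm/s) of the
#'   simulated correlated random walk.
#' @param heading_sd SD (radians) of the per-step turning angle.
#' @param feed_attraction Strength of the latent feeding effect on
#'   feeding-zone attraction (logit scale).
#' @param seed Integer master seed for [simulate_study()].
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_study()], [sim_config_scaled()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 8, seed = 42)
#' cfg$zone_w_cm
sim_config <- function(n_individuals = 34,
                       n_days_behavior = 28,
                       horizon_days = 280,
                       step_s = 0.2,
                       activity_phase_h = 8,
                       feeding_phase_h = 2,
                       arena_w_cm = 20,
                       arena_h_cm = 20,
                       zone_w_cm = 5,
                       zone_h_cm = 13,
                       mean_log_activity = 0.7,
                       V_ID_act = 0.6,
                       V_res_act = 1.0,
                       mean_feeding_min = 30,
                       V_ID_feed = 22,
                       V_res_feed = 100,
                       rho_act_feed = -0.5,
                       vb_Linf_base = 3.9,
                       beta_feed_Linf = 0.02,
                       sigma_Linf = 0.17,
                       vb_K_mean = 0.017,
                       vb_K_sd = 0.001,
                       k_linf_slope = -0.008,
                       vb_t0_mean = -14,
                       vb_t0_sd = 2,
                       sigma_length = 0.05,
                       gestation_days = 30,
                       gestation_jitter_sd = 2,
                       onset_base = 160,
                       onset_slope_Linf = 25,
                       onset_sd = 14,
                       brood_size_mean = 16,
                       V_ID_broodsize = 0.013,
                       broodsize_size_slope = 0.10,
                       broodsize_disp_sd = 0.12,
                       offsize_base = 0.95,
                       tradeoff_slope = -0.013,
                       V_ID_offsize = 2e-4,
                       offsize_size_slope = 0.15,
                       sigma_brood_offsize = 0.03,
                       sigma_offspring = 0.05,
                       n_mothers = 3,
                       mother_sd_Linf = 0.06,
                       mother_sd_offsize = 0.008,
                       p_dropout_activity = 0,
                       p_dropout_feeding = 0,
                       p_brood_unmeasured = 0.05,
                       base_speed_cm_s = 2,
                       heading_sd = 0.6,
                       feed_attraction = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config()].
#' @details `sim_config_scaled()` is a preset with coarser time steps and
#'   short recording phases so that a full cohort of trajectories simulates in
#'   seconds; the statistical structure (variance components, links) is
#'   unchanged.
#' @export
sim_config_scaled <- function(...) {
  args <- list(...)
  defaults <- list(step_s = 0.5, activity_phase_h = 0.05, feeding_phase_h = 0.05)
  for (nm in names(defaults)) if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(sim_config, args)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  pos <- c("n_individuals", "n_days_behavior", "horizon_days", "step_s",
           "activity_phase_h", "feeding_phase_h", "arena_w_cm", "arena_h_cm",
           "zone_w_cm", "zone_h_cm", "gestation_days", "brood_size_mean",
           "offsize_base", "n_mothers")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      fail(f, "must be a single positive finite number")
  }
  nonneg <- c("V_ID_act", "V_res_act", "V_ID_feed", "V_res_feed",
              "V_ID_broodsize", "V_ID_offsize", "sigma_Linf", "vb_K_sd",
              "vb_t0_sd", "sigma_length", "gestation_jitter_sd", "onset_sd",
              "broodsize_disp_sd", "sigma_brood_offsize", "sigma_offspring",
              "mother_sd_Linf", "mother_sd_offsize", "base_speed_cm_s",
              "heading_sd")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      fail(f, "must be a single non-negative finite number")
  }
  for (f in c("p_dropout_activity", "p_dropout_feeding", "p_brood_unmeasured")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      fail(f, "must be a probability in [0, 1]")
  }
  if (abs(cfg$rho_act_feed) > 1) fail("rho_act_feed", "must satisfy |rho| <= 1")
  if (cfg$zone_w_cm > cfg$arena_w_cm || cfg$zone_h_cm > cfg$arena_h_cm)
    fail("zone_w_cm", "feeding zone must fit inside the arena")
  if (cfg$vb_Linf_base + cfg$beta_feed_Linf * cfg$mean_feeding_min <= 0)
    fail("vb_Linf_base", "implied mean asymptotic length must be positive")
  if (cfg$horizon_days < 7) fail("horizon_days", "growth horizon must be >= 7 days")
  if (cfg$vb_K_mean <= 0) fail("vb_K_mean", "growth coefficient must be positive")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    fail("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d individuals, %d behavior days, %d-day horizon\n",
              x$n_individuals, x$n_days_behavior, x$horizon_days))
  cat(sprintf("  recording: %.3g s steps, %.3g h activity + %.3g h feeding, arena %g x %g cm\n",
              x$step_s, x$activity_phase_h, x$feeding_phase_h,
              x$arena_w_cm, x$arena_h_cm))
  cat(sprintf("  behavior variances: act %g/%g, feed %g/%g, rho = %g\n",
              x$V_ID_act, x$V_res_act, x$V_ID_feed, x$V_res_feed, x$rho_act_feed))
  cat(sprintf("  growth: Linf ~ %g + %g * feeding, K ~ %g (sd %g), t0 ~ %g\n",
              x$vb_Linf_base, x$beta_feed_Linf, x$vb_K_mean, x$vb_K_sd, x$vb_t0_mean))
  cat(sprintf("  reproduction: onset ~ %g d, gestation %g d, brood ~ %g, trade-off %g cm/offspring\n",
              x$onset_base, x$gestation_days, x$brood_size_mean, x$tradeoff_slope))
  invisible(x)
}
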