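#' Simulate one individual-day of trajectory data
#'
#' A correlated random walk confined to the arena, sampled at `step_s`:
#' heading follows a random walk with turning-angle SD `heading_sd`, step
#' length is `base_speed_cm_s * exp(u_act + e_act) * step_s` with a day-level
#' deviation `e_act`, and positions are reflected at the walls. The pair of
#' day-level deviations for activity and feeding shares the configured
#' `rho_act_feed` correlation. During the feeding phase the fish switches
#' between a roaming state and a foraging state; the stationary foraging
#' probability is `plogis(qlogis(mean_feeding / duration) + feed_attraction *
#' (u_feed + e_feed))`, so zone occupancy increases with the latent feeding
#' effect and `feed_attraction -> Inf` (with `u_feed > 0`) drives essentially
#' every feeding-phase sample into the zone. While foraging the fish swims
#' toward the zone center and then wanders inside the zone.
#'
#' @param ind One row of [simulate_cohort()] output.
#' @param day Recording day (1-based).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A data.frame `individual_id, day, phase, t_s, x_cm, y_cm`; phase is
#'   `"activity"` then `"feeding"`, `t_s` restarts at 0 in each phase.
#' @export
simulate_trajectory <- function(ind, day, config, seed = NULL) {
  validate_sim_config(config)
  if (day < 1 || day > config$n_days_behavior)
    stop(sprintf("day must be in [1, %d]", config$n_days_behavior), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  Sig <- matrix(c(config$V_res_act,
                  config$rho_act_feed * sqrt(config$V_res_act * config$V_res_feed),
                  config$rho_act_feed * sqrt(config$V_res_act * config$V_res_feed),
                  config$V_res_feed), 2L, 2L)
  e_day <- as.numeric(MASS::mvrnorm(1L, mu = c(0, 0), Sigma = Sig, tol = 1e-8))
  speed <- config$base_speed_cm_s * exp(ind$u_act[1L] + e_day[1L])
  zone <- default_zone(config)
  zc <- c(zone$x_min + zone$width_cm / 2, zone$y_min + zone$height_cm / 2)

  walk_phase <- function(n_steps, feeding) {
    x <- numeric(n_steps); y <- numeric(n_steps)
    pos <- c(stats::runif(1L, 0, config$arena_w_cm),
             stats::runif(1L, 0, config$arena_h_cm))
    theta <- stats::runif(1L, 0, 2 * pi)
    step_len <- speed * config$step_s

    foraging <- FALSE
    if (feeding) {
      dur_min <- config$feeding_phase_h * 60
      p_base <- min(max(config$mean_feeding_min / dur_min, 1e-3), 1 - 1e-3)
      p_for <- stats::plogis(stats::qlogis(p_base) +
                               config$feed_attraction * (ind$u_feed[1L] + e_day[2L]))
      tau <- 100                       # mean dwell, in steps
      r_leave <- 1 / tau
      r_enter <- min(p_for / ((1 - p_for) * tau), 1)
      foraging <- stats::runif(1L) < p_for
    }

    for (i in seq_len(n_steps)) {
      if (feeding) {
        if (foraging) {
          if (stats::runif(1L) < r_leave) foraging <- FALSE
        } else if (stats::runif(1L) < r_enter) foraging <- TRUE
      }
      if (feeding && foraging && step_len > 0) {
        d <- zc - pos
        dist <- sqrt(sum(d^2))
        if (dist > step_len) {          # approach the patch
          pos <- pos + d / dist * step_len
        } else {                        # wander inside the zone
          theta <- theta + stats::rnorm(1L, 0, config$heading_sd)
          cand <- pos + step_len * 0.3 * c(cos(theta), sin(theta))
          cand[1L] <- reflect_into(cand[1L], zone$x_min, zone$x_min + zone$width_cm)
          cand[2L] <- reflect_into(cand[2L], zone$y_min, zone$y_min + zone$height_cm)
          pos <- cand
        }
      } else if (step_len > 0) {
        theta <- theta + stats::rnorm(1L, 0, config$heading_sd)
        cand <- pos + step_len * c(cos(theta), sin(theta))
        cand[1L] <- reflect_into(cand[1L], 0, config$arena_w_cm)
        cand[2L] <- reflect_into(cand[2L], 0, config$arena_h_cm)
        pos <- cand
      }
      x[i] <- pos[1L]; y[i] <- pos[2L]
    }
    list(x = x, y = y)
  }

  n_act <- max(round(config$activity_phase_h * 3600 / config$step_s), 2L)
  n_feed <- max(round(config$feeding_phase_h * 3600 / config$step_s), 2L)
  act <- walk_phase(n_act, feeding = FALSE)
  feed <- walk_phase(n_feed, feeding = TRUE)

  data.frame(
    individual_id = ind$individual_id[1L],
    day = day,
    phase = rep(c("activity", "feeding"), c(n_act, n_feed)),
    t_s = c(seq_len(n_act) - 1, seq_len(n_feed) - 1) * config$step_s,
    x_cm = c(act$x, feed$x),
    y_cm = c(act$y, feed$y),
    stringsAsFactors = FALSE
  )
}

# Fold a coordinate back into [lo, hi] by reflection at the walls.
reflect_into <- function(p, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(lo)
  p <- (p - lo) %% (2 * w)
  p <- ifelse(p > w, 2 * w - p, p)
  p + lo
}

#' Simulate trajectories for a whole cohort
#'
#' Calls [simulate_trajectory()] for every individual-day; per-recording seeds
#' are derived deterministically from `seed` so the full set is reproducible.
#' With dropout configured, whole individual-days are removed per phase at the
#' configured rates.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config A [sim_config()]; use [sim_config_scaled()] to keep volumes
#'   test-sized.
#' @param seed Integer base seed.
#' @param days Days to simulate (default all behavior days).
#' @return A single long data.frame of trajectory rows.
#' @export
simulate_trajectories <- function(cohort, config, seed = 1L, days = NULL) {
  validate_sim_config(config)
  if (is.null(days)) days <- seq_len(config$n_days_behavior)
  out <- vector("list", nrow(cohort) * length(days))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (d in days) {
      k <- k + 1L
      s <- (as.integer(seed) + 7919L * i + 104729L * as.integer(d)) %% 2147483647L
      tr <- simulate_trajectory(cohort[i, , drop = FALSE], d, config, seed = s)
      if (config$p_dropout_activity > 0 && stats::runif(1L) < config$p_dropout_activity)
        tr <- tr[tr$phase != "activity", , drop = FALSE]
      if (config$p_dropout_feeding > 0 && stats::runif(1L) < config$p_dropout_feeding)
        tr <- tr[tr$phase != "feeding", , drop = FALSE]
      out[[k]] <- tr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
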