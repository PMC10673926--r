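#' Feeding-zone specification
#'
#' Axis-aligned rectangle around the stationary food patch. The default
#' dimensions are the 5 x 13 cm zone used for the feeding-time measure.
#'
#' @param x_min,y_min Lower-left corner (cm).
#' @param width_cm,height_cm Zone dimensions (cm), both positive.
#' @return An object of class `zone_spec`.
#' @export
#' @examples
#' zone_spec(7.5, 3.5)
zone_spec <- function(x_min, y_min, width_cm = 5, height_cm = 13) {
  if (!is.numeric(width_cm) || width_cm <= 0 || !is.numeric(height_cm) || height_cm <= 0)
    stop("zone width/height must be positive", call. = FALSE)
  structure(list(x_min = x_min, y_min = y_min,
                 width_cm = width_cm, height_cm = height_cm),
            class = "zone_spec")
}

#' @rdname zone_spec
#' @param config A [sim_config()]; returns the configured zone centered in the
#'   arena.
#' @export
default_zone <- function(config) {
  zone_spec((config$arena_w_cm - config$zone_w_cm) / 2,
            (config$arena_h_cm - config$zone_h_cm) / 2,
            config$zone_w_cm, config$zone_h_cm)
}

# Shared validation of one single-phase track. Returns the track sorted by
# time; errors on non-finite coordinates or non-monotone timestamps.
check_track <- function(traj) {
  need <- c("t_s", "x_cm", "y_cm")
  if (!all(need %in% names(traj)))
    stop("trajectory must have columns t_s, x_cm, y_cm", call. = FALSE)
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  if (any(!is.finite(traj$x_cm)) || any(!is.finite(traj$y_cm)) || any(!is.finite(traj$t_s)))
    stop("trajectory contains non-finite values", call. = FALSE)
  traj <- traj[order(traj$t_s), , drop = FALSE]
  if (anyDuplicated(traj$t_s))
    stop("non-monotone timestamps: duplicated t_s values", call. = FALSE)
  traj
}

#' Daily activity from an activity-phase track
#'
#' Activity is the average distance moved per second: the total path length
#' (sum of Euclidean distances between consecutive valid samples) divided by
#' the total valid elapsed time. Consecutive pairs separated by more than
#' `max_gap_factor * step_s` are treated as recording gaps and excluded from
#' both path length and elapsed time; nothing is interpolated.
#'
#' @param traj Data.frame with columns `t_s, x_cm, y_cm` (one phase of one
#'   individual-day).
#' @param step_s Nominal sampling interval in seconds.
#' @param max_gap_factor Pairs with elapsed time above `max_gap_factor *
#'   step_s` are excluded as gaps.
#' @return Activity in cm/s (a single non-negative number).
#' @export
#' @examples
#' tr <- data.frame(t_s = seq(0, 2, 0.2), x_cm = seq(0, 5, 0.5), y_cm = 0)
#' compute_activity(tr)  # 0.5 cm per 0.2 s step = 2.5 cm/s
compute_activity <- function(traj, step_s = 0.2, max_gap_factor = 3) {
  traj <- check_track(traj)
  if (nrow(traj) < 2L)
    stop("insufficient data: need >= 2 samples to compute activity", call. = FALSE)
  dt <- diff(traj$t_s)
  valid <- dt <= max_gap_factor * step_s
  if (!any(valid))
    stop("insufficient data: no valid consecutive sample pairs", call. = FALSE)
  dist <- sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2)
  sum(dist[valid]) / sum(dt[valid])
}

#' Daily feeding time from a feeding-phase track
#'
#' Each sample whose position lies inside the feeding zone (boundary
#' inclusive) contributes one sampling interval `step_s` of dwell time;
#' recording gaps contribute nothing. The sum is returned in minutes.
#'
#' @param traj Data.frame with columns `t_s, x_cm, y_cm`.
#' @param zone A [zone_spec()].
#' @param step_s Sampling interval in seconds (the per-sample dwell).
#' @return Time in the zone, in minutes.
#' @export
compute_feeding_time <- function(traj, zone, step_s = 0.2) {
  stopifnot(inherits(zone, "zone_spec"))
  traj <- check_track(traj)
  inside <- traj$x_cm >= zone$x_min & traj$x_cm <= zone$x_min + zone$width_cm &
    traj$y_cm >= zone$y_min & traj$y_cm <= zone$y_min + zone$height_cm
  sum(inside) * step_s / 60
}

#' Summarize one individual-day into the two behavioral measures
#'
#' Splits the rows of one individual-day by phase and computes activity
#' (activity phase) and feeding time (feeding phase). A missing phase yields a
#' missing metric; nothing is imputed.
#'
#' @param traj Trajectory rows for exactly one individual-day, with columns
#'   `individual_id, day, phase, t_s, x_cm, y_cm`.
#' @param zone A [zone_spec()].
#' @param step_s Sampling interval (seconds).
#' @param max_gap_factor See [compute_activity()].
#' @return One-row data.frame: `individual_id, day, activity_cm_s,
#'   feeding_min, activity_duration_min, feeding_duration_min`.
#' @export
summarize_day <- function(traj, zone, step_s = 0.2, max_gap_factor = 3) {
  if (length(unique(traj$individual_id)) != 1L || length(unique(traj$day)) != 1L)
    stop("summarize_day expects rows from exactly one individual-day", call. = FALSE)
  phases <- unique(traj$phase)
  if (!length(phases)) stop("no phase data present", call. = FALSE)
  if (!all(phases %in% c("activity", "feeding")))
    stop("phase must be 'activity' or 'feeding'", call. = FALSE)

  act <- NA_real_; act_dur <- NA_real_
  feed <- NA_real_; feed_dur <- NA_real_
  if ("activity" %in% phases) {
    a <- check_track(traj[traj$phase == "activity", , drop = FALSE])
    act <- compute_activity(a, step_s, max_gap_factor)
    dt <- diff(a$t_s)
    act_dur <- sum(dt[dt <= max_gap_factor * step_s]) / 60
  }
  if ("feeding" %in% phases) {
    f <- traj[traj$phase == "feeding", , drop = FALSE]
    feed <- compute_feeding_time(f, zone, step_s)
    feed_dur <- nrow(f) * step_s / 60
  }
  data.frame(individual_id = traj$individual_id[1L], day = traj$day[1L],
             activity_cm_s = act, feeding_min = feed,
             activity_duration_min = act_dur, feeding_duration_min = feed_dur,
             stringsAsFactors = FALSE)
}

#' Behavior table from a long table of trajectories
#'
#' Applies [summarize_day()] to every individual-day present. Duplicate
#' trajectory blocks for the same individual-day-phase (non-contiguous rows
#' with overlapping timestamps) surface as duplicated-timestamp errors.
#'
#' @param traj Long trajectory data.frame (`individual_id, day, phase, t_s,
#'   x_cm, y_cm`).
#' @param zone A [zone_spec()].
#' @param step_s Sampling interval (seconds).
#' @param max_gap_factor See [compute_activity()].
#' @return A `DailyBehavior` data.frame, one row per individual-day.
#' @export
behavior_from_trajectories <- function(traj, zone, step_s = 0.2, max_gap_factor = 3) {
  key <- interaction(traj$individual_id, traj$day, drop = TRUE)
  out <- lapply(split(traj, key), summarize_day,
                zone = zone, step_s = step_s, max_gap_factor = max_gap_factor)
  out <- do.call(rbind, out)
  out <- out[order(out$individual_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
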