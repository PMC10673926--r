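#' Draw the latent individuals of a synthetic clonal cohort
#'
#' Each individual carries four zero-mean latent effects: a log-activity
#' intercept `u_act`, a feeding-time intercept `u_feed` (jointly multivariate
#' normal with correlation `rho_act_feed`), and two independent reproductive
#' productivity effects `u_broodsize` (log scale) and `u_offsize` (cm). These
#' latent effects are the among-individual variance whose downstream estimate
#' is the repeatability. Mother identity is assigned in (near-)balanced
#' fashion across `n_mothers` clonal mothers, each with its own small effect
#' on asymptotic length and offspring length.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A data.frame with one row per individual: `individual_id`,
#'   `mother_id`, the four latent effects, and the mother effects
#'   `m_Linf`, `m_offsize`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 6), seed = 1)
#' cohort$u_act
simulate_cohort <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals

  Sigma <- matrix(c(config$V_ID_act,
                    config$rho_act_feed * sqrt(config$V_ID_act * config$V_ID_feed),
                    config$rho_act_feed * sqrt(config$V_ID_act * config$V_ID_feed),
                    config$V_ID_feed), 2L, 2L)
  u <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma, tol = 1e-8)
  u <- matrix(u, ncol = 2L)

  mothers <- sprintf("M%d", rep_len(seq_len(config$n_mothers), n))
  m_Linf <- stats::rnorm(config$n_mothers, 0, config$mother_sd_Linf)
  m_offsize <- stats::rnorm(config$n_mothers, 0, config$mother_sd_offsize)
  midx <- rep_len(seq_len(config$n_mothers), n)

  data.frame(
    individual_id = sprintf("F%02d", seq_len(n)),
    mother_id = mothers,
    u_act = u[, 1L],
    u_feed = u[, 2L],
    u_broodsize = stats::rnorm(n, 0, sqrt(config$V_ID_broodsize)),
    u_offsize = stats::rnorm(n, 0, sqrt(config$V_ID_offsize)),
    m_Linf = m_Linf[midx],
    m_offsize = m_offsize[midx],
    stringsAsFactors = FALSE
  )
}

#' Simulate the daily behavior table of a cohort
#'
#' Generates the per-individual, per-day behavioral measures directly from the
#' latent model: log daily activity = `mean_log_activity + u_act + e_act`,
#' daily feeding time = `mean_feeding_min + u_feed + e_feed` (truncated to the
#' feeding-phase duration), where the daily residuals `(e_act, e_feed)` are
#' bivariate normal with variances `(V_res_act, V_res_feed)` and correlation
#' `rho_act_feed` — the same coupling as the latent intercepts, so active days
#' are short-feeding days. This is the fast route to a behavior table with
#' exactly the configured variance components; [simulate_trajectories()]
#' provides the slower trajectory-level route through the same latent effects.
#'
#' Optional dropout removes whole recordings at the configured per-phase
#' rates, emulating recordings lost to technical issues.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The matching [sim_config()].
#' @param seed Optional integer seed.
#' @return A data.frame `individual_id, day, activity_cm_s, feeding_min` with
#'   `NA` for dropped recordings.
#' @export
simulate_behavior <- function(cohort, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  d <- config$n_days_behavior
  idx <- rep(seq_len(n), each = d)
  day <- rep(seq_len(d), times = n)

  Sig <- matrix(c(config$V_res_act,
                  config$rho_act_feed * sqrt(config$V_res_act * config$V_res_feed),
                  config$rho_act_feed * sqrt(config$V_res_act * config$V_res_feed),
                  config$V_res_feed), 2L, 2L)
  e <- matrix(MASS::mvrnorm(n * d, mu = c(0, 0), Sigma = Sig, tol = 1e-8), ncol = 2L)
  log_act <- config$mean_log_activity + cohort$u_act[idx] + e[, 1L]
  feed <- config$mean_feeding_min + cohort$u_feed[idx] + e[, 2L]
  feed <- pmin(pmax(feed, 0), config$feeding_phase_h * 60)

  act <- exp(log_act)
  if (config$p_dropout_activity > 0)
    act[stats::runif(n * d) < config$p_dropout_activity] <- NA_real_
  if (config$p_dropout_feeding > 0)
    feed[stats::runif(n * d) < config$p_dropout_feeding] <- NA_real_

  data.frame(
    individual_id = cohort$individual_id[idx],
    day = day,
    activity_cm_s = act,
    feeding_min = feed,
    stringsAsFactors = FALSE
  )
}

# True per-individual von Bertalanffy parameters implied by the latent cohort
# and its realized mean feeding time. Internal: shared by growth and
# reproduction simulators.
true_growth_params <- function(cohort, mean_feeding, config) {
  Linf <- config$vb_Linf_base + config$beta_feed_Linf * mean_feeding +
    cohort$m_Linf + stats::rnorm(nrow(cohort), 0, config$sigma_Linf)
  if (any(Linf <= 0))
    stop("simulated asymptotic length is non-positive; check vb_Linf_base/beta_feed_Linf",
         call. = FALSE)
  Linf_center <- config$vb_Linf_base + config$beta_feed_Linf * config$mean_feeding_min
  K <- config$vb_K_mean + config$k_linf_slope * (Linf - Linf_center) +
    stats::rnorm(nrow(cohort), 0, config$vb_K_sd)
  K <- pmax(K, 1e-4)
  t0 <- stats::rnorm(nrow(cohort), config$vb_t0_mean, config$vb_t0_sd)
  data.frame(individual_id = cohort$individual_id,
             true_Linf = Linf, true_K = K, true_t0 = t0,
             stringsAsFactors = FALSE)
}

#' Simulate weekly standard-length records for one individual
#'
#' Sizes follow the individual's von Bertalanffy curve
#' `L(t) = Linf (1 - exp(-K (t - t0)))` with additive measurement noise.
#' `Linf` is `vb_Linf_base + beta_feed_Linf * mean_feeding` plus mother and
#' individual deviations, so feeding behavior feeds forward into growth.
#'
#' @param ind One row of [simulate_cohort()] output.
#' @param mean_feeding The individual's mean daily feeding time (minutes).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A data.frame `individual_id, age_days, length_cm` with weekly ages
#'   `7, 14, ..., horizon_days`, lengths strictly positive.
#' @export
simulate_growth <- function(ind, mean_feeding, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  pars <- true_growth_params(ind, mean_feeding, config)
  ages <- seq(7, config$horizon_days, by = 7)
  len <- vb_length(ages, pars$true_Linf[1L], pars$true_K[1L], pars$true_t0[1L]) +
    stats::rnorm(length(ages), 0, config$sigma_length)
  len <- pmax(len, 0.05)
  data.frame(individual_id = ind$individual_id[1L], age_days = ages,
             length_cm = len, stringsAsFactors = FALSE)
}

# Internal: weekly sizes for a whole cohort given pre-drawn true parameters.
simulate_sizes_cohort <- function(pars, config) {
  ages <- seq(7, config$horizon_days, by = 7)
  out <- lapply(seq_len(nrow(pars)), function(i) {
    len <- vb_length(ages, pars$true_Linf[i], pars$true_K[i], pars$true_t0[i]) +
      stats::rnorm(length(ages), 0, config$sigma_length)
    data.frame(individual_id = pars$individual_id[i], age_days = ages,
               length_cm = pmax(len, 0.05), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate the reproductive profile of one individual
#'
#' Onset of reproduction (age at first parturition) increases with the
#' individual's asymptotic length (larger fish start reproducing later);
#' successive broods follow at ~`gestation_days` intervals until the horizon.
#' Brood size is Poisson with a log-link on the individual productivity effect
#' `u_broodsize`, the female's size at parturition, and brood-level
#' over-dispersion. Offspring lengths are normal around a brood mean carrying
#' the individual effect `u_offsize`, the size-number trade-off
#' `tradeoff_slope * (brood size - mean)`, the female-size effect, and the
#' mother effect. A configurable fraction of broods is counted but not
#' measured.
#'
#' @param ind One row of [simulate_cohort()] output.
#' @param growth A one-row data.frame with `true_Linf, true_K, true_t0` for
#'   this individual (true parameters or a converged fit's estimates).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list with `broods` (one row per brood: `individual_id, mother_id,
#'   brood_id, age_at_parturition_days, brood_size, measured`) and `offspring`
#'   (one row per measured offspring: `individual_id, brood_id, length_cm`).
#'   Zero broods before the horizon is valid and yields empty tables.
#' @export
simulate_reproduction <- function(ind, growth, config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  Linf_center <- config$vb_Linf_base + config$beta_feed_Linf * config$mean_feeding_min
  onset <- config$onset_base +
    config$onset_slope_Linf * (growth$true_Linf[1L] - Linf_center) +
    stats::rnorm(1L, 0, config$onset_sd)
  onset <- max(onset, 2 * config$gestation_days)

  ages <- numeric(0)
  a <- onset
  while (a <= config$horizon_days) {
    ages <- c(ages, a)
    a <- a + config$gestation_days + stats::rnorm(1L, 0, config$gestation_jitter_sd)
  }
  if (length(ages) == 0L) {
    return(list(
      broods = data.frame(individual_id = character(0), mother_id = character(0),
                          brood_id = character(0), age_at_parturition_days = numeric(0),
                          brood_size = integer(0), measured = logical(0),
                          stringsAsFactors = FALSE),
      offspring = data.frame(individual_id = character(0), brood_id = character(0),
                             length_cm = numeric(0), stringsAsFactors = FALSE)
    ))
  }

  size_at <- vb_length(ages, growth$true_Linf[1L], growth$true_K[1L], growth$true_t0[1L])
  log_mu <- log(config$brood_size_mean) + ind$u_broodsize[1L] +
    config$broodsize_size_slope * (size_at - Linf_center) +
    stats::rnorm(length(ages), 0, config$broodsize_disp_sd)
  bs <- pmax(stats::rpois(length(ages), exp(log_mu)), 1L)

  measured <- stats::runif(length(ages)) >= config$p_brood_unmeasured
  brood_id <- sprintf("%s_b%02d", ind$individual_id[1L], seq_along(ages))

  mean_len <- config$offsize_base + ind$u_offsize[1L] + ind$m_offsize[1L] +
    config$tradeoff_slope * (bs - config$brood_size_mean) +
    config$offsize_size_slope * (size_at - Linf_center) +
    stats::rnorm(length(ages), 0, config$sigma_brood_offsize)

  off <- lapply(which(measured), function(j) {
    data.frame(individual_id = ind$individual_id[1L], brood_id = brood_id[j],
               length_cm = pmax(stats::rnorm(bs[j], mean_len[j], config$sigma_offspring), 0.2),
               stringsAsFactors = FALSE)
  })
  offspring <- if (length(off)) do.call(rbind, off) else
    data.frame(individual_id = character(0), brood_id = character(0),
               length_cm = numeric(0), stringsAsFactors = FALSE)

  list(
    broods = data.frame(individual_id = ind$individual_id[1L],
                        mother_id = ind$mother_id[1L],
                        brood_id = brood_id,
                        age_at_parturition_days = ages,
                        brood_size = as.integer(bs),
                        measured = measured,
                        stringsAsFactors = FALSE),
    offspring = offspring
  )
}

#' Simulate a complete synthetic study
#'
#' Chains the generator end to end under one master seed: latent cohort ->
#' daily behavior table -> true growth parameters (asymptotic length tied to
#' each individual's realized mean feeding time) -> weekly size records ->
#' brood and offspring tables. All randomness is drawn from a single stream
#' seeded by `config$seed`, so identical configs give bit-identical studies.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `config`, `cohort` (latent effects +
#'   true growth parameters + realized mean feeding), `behavior`, `sizes`,
#'   `broods`, `offspring`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_individuals = 5, seed = 7))
#' head(study$behavior)
simulate_study <- function(config) {
  validate_sim_config(config)
  set.seed(as.integer(config$seed))
  cohort <- simulate_cohort(config)
  behavior <- simulate_behavior(cohort, config)

  mf <- tapply(behavior$feeding_min, behavior$individual_id, mean, na.rm = TRUE)
  cohort$mean_feeding <- as.numeric(mf[cohort$individual_id])
  pars <- true_growth_params(cohort, cohort$mean_feeding, config)
  cohort <- cbind(cohort, pars[, c("true_Linf", "true_K", "true_t0")])

  sizes <- simulate_sizes_cohort(pars, config)

  rep_list <- lapply(seq_len(nrow(cohort)), function(i) {
    simulate_reproduction(cohort[i, , drop = FALSE], pars[i, , drop = FALSE], config)
  })
  broods <- do.call(rbind, lapply(rep_list, `[[`, "broods"))
  offspring <- do.call(rbind, lapply(rep_list, `[[`, "offspring"))
  rownames(broods) <- rownames(offspring) <- NULL

  structure(list(config = config, cohort = cohort, behavior = behavior,
                 sizes = sizes, broods = broods, offspring = offspring),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>\n")
  cat(sprintf("  %d individuals; %d behavior rows; %d size records; %d broods (%d measured); %d offspring\n",
              nrow(x$cohort), nrow(x$behavior), nrow(x$sizes),
              nrow(x$broods), sum(x$broods$measured), nrow(x$offspring)))
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes `behavior.csv`, `sizes.csv`, `broods.csv` and `offspring.csv` in the
#' dialect the pipeline readers expect (UTF-8, header row, '.' decimal).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("behavior.csv", "sizes.csv", "broods.csv", "offspring.csv"))
  utils::write.csv(study$behavior, paths[1L], row.names = FALSE)
  utils::write.csv(study$sizes, paths[2L], row.names = FALSE)
  utils::write.csv(study$broods, paths[3L], row.names = FALSE)
  utils::write.csv(study$offspring, paths[4L], row.names = FALSE)
  invisible(paths)
}
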