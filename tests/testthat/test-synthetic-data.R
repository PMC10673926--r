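test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(V_ID_act = -1), "V_ID_act")
  expect_error(sim_config(rho_act_feed = -1.2), "rho_act_feed")
  expect_error(sim_config(zone_w_cm = 30), "zone")
  expect_error(sim_config(step_s = 0), "step_s")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(p_brood_unmeasured = 1.5), "p_brood_unmeasured")
  expect_error(sim_config(vb_Linf_base = -5, beta_feed_Linf = 0), "vb_Linf_base")
})

test_that("identical configs and seeds give bit-identical studies", {
  cfg <- sim_config(n_individuals = 6, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$sizes, s2$sizes)
  expect_identical(s1$broods, s2$broods)
  expect_identical(s1$offspring, s2$offspring)
})

test_that("degenerate variances collapse the latent effects to zero", {
  cfg <- sim_config(n_individuals = 10, V_ID_act = 0)
  cohort <- simulate_cohort(cfg, seed = 4)
  expect_equal(cohort$u_act, rep(0, 10), tolerance = 1e-10)
})

test_that("latent variances are calibrated (Monte Carlo at n = 5000)", {
  cfg <- sim_config(n_individuals = 5000, V_ID_act = 1)
  cohort <- simulate_cohort(cfg, seed = 12)
  expect_equal(var(cohort$u_act), 1, tolerance = 0.05)
  expect_equal(var(cohort$u_feed), cfg$V_ID_feed, tolerance = 0.05 * cfg$V_ID_feed)
  expect_equal(cor(cohort$u_act, cohort$u_feed), cfg$rho_act_feed, tolerance = 0.05)
})

test_that("behavior tables carry the configured variance components", {
  cfg <- sim_config(n_individuals = 300)
  cohort <- simulate_cohort(cfg, seed = 6)
  beh <- simulate_behavior(cohort, cfg, seed = 7)
  fit <- fit_lmm(log(activity_cm_s) ~ 1 + (1 | individual_id), beh)
  truth <- cfg$V_ID_act / (cfg$V_ID_act + cfg$V_res_act)
  expect_equal(repeatability(fit), truth, tolerance = 0.05)
})

test_that("dropout removes recordings at the configured rates", {
  cfg <- sim_config(n_individuals = 34, p_dropout_activity = 11 / 952,
                    p_dropout_feeding = 20 / 952)
  cohort <- simulate_cohort(cfg, seed = 2)
  beh <- simulate_behavior(cohort, cfg, seed = 2)
  expect_equal(nrow(beh), 952)
  expect_lt(sum(is.na(beh$activity_cm_s)), 40)
  expect_gt(sum(is.na(beh$feeding_min)), 2)
})

test_that("zero speed gives a stationary track with zero activity", {
  cfg <- sim_config_scaled(n_individuals = 1, base_speed_cm_s = 0)
  cohort <- simulate_cohort(cfg, seed = 3)
  tr <- simulate_trajectory(cohort, day = 1, cfg, seed = 3)
  act <- tr[tr$phase == "activity", ]
  expect_equal(compute_activity(act, step_s = cfg$step_s), 0)
  expect_equal(length(unique(act$x_cm)), 1L)
})

test_that("extreme zone attraction puts nearly every feeding sample in the zone", {
  cfg <- sim_config_scaled(n_individuals = 1, feed_attraction = 1e6,
                           feeding_phase_h = 0.2)
  cohort <- simulate_cohort(cfg, seed = 5)
  cohort$u_feed <- 5   # a keen feeder
  tr <- simulate_trajectory(cohort, day = 1, cfg, seed = 8)
  feed <- tr[tr$phase == "feeding", ]
  frac <- compute_feeding_time(feed, default_zone(cfg), step_s = cfg$step_s) * 60 /
    (nrow(feed) * cfg$step_s)
  expect_gt(frac, 0.95)
  expect_error(simulate_trajectory(cohort, day = 99, cfg), "day")
})

test_that("trajectory-level simulation preserves behavioral repeatability", {
  cfg <- sim_config_scaled(n_individuals = 8, n_days_behavior = 6,
                           V_ID_act = 1, V_res_act = 0.01)
  cohort <- simulate_cohort(cfg, seed = 21)
  traj <- simulate_trajectories(cohort, cfg, seed = 21)
  beh <- behavior_from_trajectories(traj, default_zone(cfg), step_s = cfg$step_s)
  fit <- fit_lmm(log(activity_cm_s) ~ 1 + (1 | individual_id), beh)
  expect_gt(repeatability(fit), 0.9)
})

test_that("noiseless growth records lie exactly on the curve", {
  cfg <- sim_config(sigma_length = 0, sigma_Linf = 0, vb_K_sd = 0, vb_t0_sd = 0,
                    mother_sd_Linf = 0, beta_feed_Linf = 0)
  cohort <- simulate_cohort(cfg, seed = 30)[1, , drop = FALSE]
  rec <- simulate_growth(cohort, mean_feeding = 30, cfg, seed = 30)
  expect_equal(rec$length_cm,
               vb_length(rec$age_days, cfg$vb_Linf_base, cfg$vb_K_mean, cfg$vb_t0_mean),
               tolerance = 1e-10)
})

test_that("reproduction respects the horizon and the brood-count target", {
  cfg <- sim_config(n_individuals = 1, horizon_days = 50, onset_base = 100)
  cohort <- simulate_cohort(cfg, seed = 9)
  growth <- data.frame(true_Linf = 4.5, true_K = 0.017, true_t0 = -14)
  rp <- simulate_reproduction(cohort, growth, cfg, seed = 9)
  expect_equal(nrow(rp$broods), 0L)
  expect_equal(nrow(rp$offspring), 0L)

  # defaults produce ~4.5 broods per female over 280 days at ~30-day spacing
  big <- simulate_study(sim_config(n_individuals = 150, seed = 13))
  per_female <- table(big$broods$individual_id)
  expect_equal(mean(per_female), 4.5, tolerance = 0.5)
  expect_true(all(big$broods$brood_size >= 1))
  # measured offspring counts match brood sizes
  counts <- table(big$offspring$brood_id)
  meas <- big$broods[big$broods$measured, ]
  expect_equal(unname(counts[meas$brood_id]),
               as.table(setNames(as.numeric(meas$brood_size), meas$brood_id)),
               ignore_attr = TRUE)
})
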