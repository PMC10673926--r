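# A tiny hand-built study for the bookkeeping tests: growth fits from
# noiseless curves, two hand-written broods.
make_toy_fit <- function(id, Linf = 4.5, K = 0.018, t0 = -12) {
  ages <- seq(7, 280, 7)
  fit_vb(data.frame(individual_id = id, age_days = ages,
                    length_cm = vb_length(ages, Linf, K, t0)))
}

test_that("profiles derive onset, sizes, and cumulative output correctly", {
  fits <- list(a = make_toy_fit("a"), b = make_toy_fit("b", Linf = 5))
  broods <- data.frame(
    individual_id = c("a", "a", "b"),
    mother_id = c("M1", "M1", "M2"),
    brood_id = c("a1", "a2", "b1"),
    age_at_parturition_days = c(100, 130, 150),
    brood_size = c(3L, 5L, 4L))
  offspring <- data.frame(
    individual_id = rep(c("a", "a", "b"), c(3, 5, 4)),
    brood_id = rep(c("a1", "a2", "b1"), c(3, 5, 4)),
    length_cm = c(rep(0.9, 3), rep(1.0, 5), rep(1.1, 4)))

  pr <- build_profiles(broods, offspring, fits)
  expect_equal(pr$summary$onset[pr$summary$individual_id == "a"], 100)
  expect_equal(pr$broods$female_size_at_parturition[1],
               predicted_size_at(fits$a, 100))
  expect_equal(pr$broods$mean_offspring_length[pr$broods$brood_id == "a2"], 1.0)

  # cumulative curve: steps 0 -> 3 -> 8, right-continuous, non-decreasing
  expect_equal(cumulative_offspring(pr, "a", c(50, 100, 115, 130, 280)),
               c(0, 3, 3, 8, 8))
  grid <- cumulative_offspring(pr, "a", seq(0, 280, 1))
  expect_true(all(diff(grid) >= 0))
  # conservation: final value equals total offspring
  expect_equal(grid[length(grid)],
               sum(broods$brood_size[broods$individual_id == "a"]))
})

test_that("profile building rejects malformed brood tables", {
  fits <- list(a = make_toy_fit("a"))
  bad_age <- data.frame(individual_id = "a", mother_id = "M1", brood_id = "a1",
                        age_at_parturition_days = -3, brood_size = 2L)
  off <- data.frame(individual_id = "a", brood_id = "a1", length_cm = c(1, 1))
  expect_error(build_profiles(bad_age, off, fits), "before birth")

  dup_age <- data.frame(individual_id = "a", mother_id = "M1",
                        brood_id = c("a1", "a2"),
                        age_at_parturition_days = c(100, 100),
                        brood_size = c(2L, 2L))
  expect_error(build_profiles(dup_age, off, fits), "non-increasing")

  no_fit <- data.frame(individual_id = "zz", mother_id = "M1", brood_id = "z1",
                       age_at_parturition_days = 100, brood_size = 2L)
  expect_error(build_profiles(no_fit, off, fits), "no growth fit")

  over <- data.frame(individual_id = "a", mother_id = "M1", brood_id = "a1",
                     age_at_parturition_days = 100, brood_size = 1L)
  expect_error(build_profiles(over, off, fits), "exceed")
})

test_that("individuals without broods are excluded with a message", {
  fits <- list(a = make_toy_fit("a"), b = make_toy_fit("b"))
  broods <- data.frame(individual_id = "a", mother_id = "M1", brood_id = "a1",
                       age_at_parturition_days = 100, brood_size = 2L)
  off <- data.frame(individual_id = "a", brood_id = "a1", length_cm = c(1, 1))
  expect_message(pr <- build_profiles(broods, off, fits), "no broods")
  expect_equal(pr$n_excluded, 1L)
  expect_equal(nrow(pr$summary), 1L)
})

test_that("successive broods are spaced by roughly one gestation period", {
  study <- simulate_study(sim_config(n_individuals = 60, seed = 41))
  gaps <- unlist(tapply(study$broods$age_at_parturition_days,
                        study$broods$individual_id,
                        function(a) diff(sort(a))))
  expect_equal(mean(gaps), 30, tolerance = 1)
  expect_lt(sd(gaps), 5)
})

test_that("unmeasured broods stay in brood-size analyses but leave offspring models", {
  study <- simulate_study(sim_config(n_individuals = 40, p_brood_unmeasured = 0.15,
                                     seed = 23))
  g <- fit_vb_cohort(study$sizes)
  fits <- Filter(function(f) f$converged, g$fits)
  pr <- suppressMessages(build_profiles(study$broods, study$offspring, fits))
  tm <- tradeoff_models(pr)
  n_all <- nrow(pr$broods)
  n_meas <- sum(!is.na(pr$broods$mean_offspring_length))
  expect_lt(n_meas, n_all)
  expect_equal(tm$n_broods, n_all)
  expect_equal(tm$n_measured, n_meas)
  expect_equal(tm$brood_raw$n_obs, n_all)          # raw brood-size model: all broods
  expect_equal(tm$offspring_raw$n_obs, n_meas)     # offspring models: measured only
  expect_equal(tm$offspring_model$n_obs, n_meas)
})

test_that("trade-off models recover null and negative generating slopes", {
  run_tradeoff <- function(slope, seed) {
    study <- simulate_study(sim_config(n_individuals = 120,
                                       tradeoff_slope = slope, seed = seed))
    g <- fit_vb_cohort(study$sizes)
    pr <- suppressMessages(build_profiles(study$broods, study$offspring,
                                          Filter(function(f) f$converged, g$fits)))
    tradeoff_models(pr)
  }
  tm0 <- run_tradeoff(0, 52)
  expect_lt(abs(tm0$tradeoff_estimate$estimate), 3 * tm0$tradeoff_estimate$se)

  tm1 <- run_tradeoff(-0.013, 53)
  expect_lt(tm1$tradeoff_estimate$estimate, 0)
  expect_lt(abs(tm1$tradeoff_estimate$estimate - (-0.013)),
            3 * tm1$tradeoff_estimate$se)
  # both raw and adjusted repeatabilities are valid fractions of variance
  for (f in list(tm1$offspring_raw, tm1$offspring_model,
                 tm1$brood_raw, tm1$brood_model)) {
    R <- repeatability(f)
    expect_true(R >= 0 && R <= 1)
  }
})
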