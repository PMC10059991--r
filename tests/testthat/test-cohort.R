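test_that("quiescent configuration is a fixed point of the dynamics", {
  cfg <- cohort_config(n_patients = 1, days = 0.5, seed = 5,
                       meal_rate = 0, noise_sd = 0, missing_rate = 0,
                       basal_rate_range = c(0, 0),
                       basal_glucose = c(7.0, 7.0))
  s <- simulate_patient(cfg, 1)
  expect_true(all(s$grid$glucose == 7.0))
})

test_that("simulation is deterministic given (seed, patient_index)", {
  cfg <- cohort_config(n_patients = 2, days = 1, seed = 33)
  expect_identical(simulate_patient(cfg, 1), simulate_patient(cfg, 1))
  expect_false(identical(simulate_patient(cfg, 1)$grid$glucose,
                         simulate_patient(cfg, 2)$grid$glucose))
})

test_that("meal-only response equals the step-by-step oracle", {
  # meals but no insulin, no reversion, no noise: the simulated trace must
  # equal an independent re-simulation from the closed-form kernel, and the
  # cumulative rise must equal alpha * sum(C)
  cfg <- cohort_config(n_patients = 1, days = 0.5, seed = 9, meal_rate = 2,
                       noise_sd = 0, missing_rate = 0,
                       dose_noise_range = c(0, 0),     # no boluses
                       basal_rate_range = c(0, 0),     # no basal
                       gamma_range = c(0, 0),
                       alpha_range = c(0.5, 0.5), basal_glucose = c(6, 6),
                       carb_range = c(50, 50))
  s <- simulate_patient(cfg, 1)
  meals <- which(s$grid$meal > 0)
  expect_gt(length(meals), 0)
  p <- absorption_params()
  C <- numeric(nrow(s$grid))
  for (m in meals) {
    lag <- s$grid$t - s$grid$t[m]
    C <- C + ifelse(lag >= 0,
                    s$grid$meal[m] * p$A_g * lag * exp(-lag / p$t_max) /
                      p$t_max^2, 0)
  }
  G <- 6
  for (i in seq_len(nrow(s$grid) - 1))
    G[i + 1] <- min(25, max(2, G[i] + 0.5 * C[i]))
  expect_equal(s$grid$glucose, G, tolerance = 1e-12)
  if (max(G) < 25)   # no clipping: the analytic total-rise identity holds
    expect_equal(G[length(G)] - 6, 0.5 * sum(C[-length(C)]),
                 tolerance = 1e-10)
})

test_that("simulated cohorts respect the grid, range and imbalance structure", {
  cohort <- simulate_cohort(cohort_config(n_patients = 6, days = 2,
                                          seed = 20230101))
  cls <- integer(0)
  for (s in cohort) {
    expect_true(all(s$grid$t %% 5 == 0))
    g <- s$grid$glucose
    expect_true(all(g >= 2 & g <= 25, na.rm = TRUE))
    ev <- series_events(s)
    expect_true(all(ev$timestamp >= min(s$grid$t) &
                      ev$timestamp <= max(s$grid$t)))
    cls <- c(cls, build_samples(s)$target_class)
  }
  # hypoglycemic bands jointly rare, as in real CGM cohorts
  expect_lt(mean(cls <= 1), 0.10)
  expect_gt(length(unique(cls)), 2)
})

test_that("signal magnitudes fall in the physiological ranges", {
  s <- simulate_patient(cohort_config(n_patients = 1, days = 2, seed = 77,
                                      missing_rate = 0), 1)
  sam <- build_samples(s)
  I <- as.matrix(sam[paste0("i", 0:6)])
  C <- as.matrix(sam[paste0("c", 0:6)])
  expect_true(all(I >= 0 & I <= 12))   # about [0, 10] mU/L
  expect_true(all(C >= 0 & C <= 3))    # about [0, 3] g
})

test_that("chronological split tags the right tail as test", {
  s <- wave_series(100)
  s2 <- assign_split(s, 0.2)
  expect_equal(sum(s2$grid$split == "test"), 20)
  expect_equal(s2$grid$split[81:100], rep("test", 20))
  s3 <- assign_split(wave_series(101), 0.5)
  expect_equal(sum(s3$grid$split == "train"), 50)  # floor on the train side
  expect_equal(sum(s3$grid$split == "test"), 51)
  expect_error(assign_split(s, 0), "0, 1")
  expect_error(assign_split(s, 1), "0, 1")
})

test_that("CSV round-trip is the identity, including missing and splits", {
  s <- simulate_patient(cohort_config(n_patients = 1, days = 1, seed = 12,
                                      missing_rate = 0.05), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(s, f)
  r <- read_patient_csv(f)
  expect_equal(r, s)
  expect_identical(is.na(r$grid$glucose), is.na(s$grid$glucose))
  expect_identical(r$grid$split, s$grid$split)
  # degenerate: no events at all
  w <- wave_series(20)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_patient_csv(w, f2)
  expect_equal(read_patient_csv(f2), w)
  expect_error(read_patient_csv(f3 <- {
    tmp <- withr::local_tempfile(); writeLines("a,b", tmp); tmp
  }), "header")
})

test_that("series invariants are enforced", {
  g <- data.frame(t = c(0, 5, 5), glucose = 5, bolus = 0, basal = 0,
                  meal = 0, split = "train")
  expect_error(patient_series("x", g), "increasing")
  g2 <- data.frame(t = c(0, 3), glucose = 5, bolus = 0, basal = 0,
                   meal = 0, split = "train")
  expect_error(patient_series("x", g2), "multiples")
  g3 <- data.frame(t = c(0, 5), glucose = 5, bolus = 0, basal = 0,
                   meal = 0, split = c("test", "train"))
  expect_error(patient_series("x", g3), "precede")
})
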