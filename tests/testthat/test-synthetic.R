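test_that("kinetic closed forms satisfy boundary conditions and mass flow", {
  kin <- kinetics_config()
  expect_equal(unlist(kinetic_amounts(kin, 0)), c(immature = 0, mature = 0))
  kin0 <- kinetics_config(production_rate = 0)
  a <- kinetic_amounts(kin0, c(0, 1, 5, 24))
  expect_true(all(a$immature == 0 & a$mature == 0))
  expect_error(kinetic_amounts(kin, -1), class = "timerflow_config_error")
  # with no degradation, total protein equals integrated production exactly
  kin_nd <- kinetics_config(degradation_halftime = Inf, production_rate = 500)
  t <- seq(0, 48, by = 0.5)
  a <- kinetic_amounts(kin_nd, t)
  expect_equal(a$immature + a$mature, 500 * t, tolerance = 1e-12)
})

test_that("closed forms satisfy the ODE residual on a time grid", {
  kin <- kinetics_config(initial_immature = 200)
  m <- log(2) / kin$maturation_halftime
  d <- log(2) / kin$degradation_halftime
  t <- seq(0.5, 48, by = 0.5)
  h <- 1e-5
  a <- kinetic_amounts(kin, t)
  ap <- kinetic_amounts(kin, t + h)
  am <- kinetic_amounts(kin, t - h)
  dB <- (ap$immature - am$immature) / (2 * h)
  dR <- (ap$mature - am$mature) / (2 * h)
  expect_lt(max(abs(dB - (kin$production_rate - (m + d) * a$immature))), 1e-4)
  expect_lt(max(abs(dR - (m * a$immature - d * a$mature))), 1e-4)
})

test_that("closed forms match a numerical ODE integration at the defaults", {
  skip_if_not_installed("deSolve")
  kin <- kinetics_config()
  m <- log(2) / kin$maturation_halftime
  d <- log(2) / kin$degradation_halftime
  rhs <- function(t, y, parms) {
    list(c(kin$production_rate - (m + d) * y[1], m * y[1] - d * y[2]))
  }
  times <- c(0, 1, 2, 4, 8, 16, 24, 48)
  num <- deSolve::ode(c(B = 0, R = 0), times, rhs, NULL,
                      method = "ode45", atol = 1e-10, rtol = 1e-10)
  a <- kinetic_amounts(kin, times)
  expect_equal(a$immature[-1], unname(num[-1, "B"]), tolerance = 1e-6)
  expect_equal(a$mature[-1], unname(num[-1, "R"]), tolerance = 1e-6)
})

test_that("the pipeline angle increases with age in the noiseless balanced limit", {
  kin <- kinetics_config()
  t <- seq(0.5, 48, by = 0.5)
  a <- kinetic_amounts(kin, t)
  # gain-balanced, autofluorescence-free: the mature/immature ratio grows
  # with age, so the polar angle of the amounts is strictly increasing
  theta <- trig_transform(a$immature, a$mature)$angle
  expect_true(all(diff(theta) > 0))
})

test_that("pulse-chase fitting recovers the maturation half-time", {
  kin <- kinetics_config(production_rate = 0, degradation_halftime = Inf,
                         initial_immature = 1000)
  t <- 0:24
  a <- kinetic_amounts(kin, t)
  ht <- fit_maturation_halftime(t, a$immature, a$mature)
  expect_equal(ht, 4, tolerance = 0.02)
  # the immature fraction is insensitive to shared degradation
  kin_d <- kinetics_config(production_rate = 0, degradation_halftime = 12,
                           initial_immature = 1000)
  a_d <- kinetic_amounts(kin_d, t)
  expect_equal(fit_maturation_halftime(t, a_d$immature, a_d$mature), 4,
               tolerance = 0.02)
})

test_that("negative-control draws are seeded, lognormal and centred as configured", {
  meas <- measurement_config(n_cells = 1000, seed = 77,
                             autofluorescence_mu_blue = 2.2,
                             autofluorescence_mu_red = 1.8,
                             autofluorescence_sigma = 0.25)
  neg1 <- simulate_negative_control(meas)
  neg2 <- simulate_negative_control(meas)
  expect_identical(as.data.frame(neg1), as.data.frame(neg2))
  expect_equal(nrow(neg1), 1000L)
  # per-channel median of log10 values within 3 standard errors of mu
  se <- 1.2533 * 0.25 / sqrt(1000)   # SE of a Gaussian median
  expect_lt(abs(median(log10(neg1$Timer_Blue)) - 2.2), 3 * se)
  expect_lt(abs(median(log10(neg1$Timer_Red)) - 1.8), 3 * se)
  # shrinking sigma collapses the spread
  tight <- simulate_negative_control(measurement_config(n_cells = 500,
                                                        autofluorescence_sigma = 1e-4))
  expect_lt(sd(log10(tight$Timer_Blue)), 1e-3)
})

test_that("a timer-off sample is indistinguishable from the negative control", {
  meas <- measurement_config(n_cells = 800, seed = 9)
  off <- simulate_sample(kinetics_config(), meas, timer_on_fraction = 0,
                         elapsed_hours = 24)
  neg <- simulate_negative_control(measurement_config(n_cells = 800, seed = 10))
  for (ch in c("Timer_Blue", "Timer_Red")) {
    expect_gt(suppressWarnings(ks.test(off[[ch]], neg[[ch]]))$p.value, 0.01)
  }
})

test_that("fully-on cells with large gains exceed the autofluorescence threshold", {
  meas <- measurement_config(n_cells = 1000, seed = 4,
                             blue_gain = 10, red_gain = 10)
  on <- simulate_sample(kinetics_config(), meas, timer_on_fraction = 1,
                        elapsed_hours = 24)
  neg <- simulate_negative_control(measurement_config(n_cells = 1000, seed = 5))
  thr <- compute_gate_thresholds(neg, threshold_spec("quantile", 0.975),
                                 "Timer_Blue", "Timer_Red")
  pos <- classify_timer_positive(on$Timer_Blue, on$Timer_Red, thr)
  expect_gte(mean(pos), 0.99)
})

test_that("the written time course is deterministic and manifest-ready", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_tiny_timecourse(d1, n_cells = 100)
  m2 <- make_tiny_timecourse(d2, n_cells = 100)
  for (f in basename(m1$entries$path)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(m1$entries$group[m1$entries$role == "sample"],
               c("0h", "8h", "24h"))
  expect_true(file.exists(file.path(d1, "truth", "truth_sample_t008h_rep1.csv")))
  tr <- read.csv(file.path(d1, "truth", "truth_sample_t024h_rep1.csv"))
  expect_true(all(tr$onset_age <= 24))
  expect_true(all(tr$onset_age[tr$timer_on] >= 0))
})
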