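#' Kinetic parameters of the Timer chromophore model
#'
#' A minimal two-compartment linear model of Fluorescent Timer protein
#' turnover: protein is produced in the immature (blue) form at rate `p`,
#' matures irreversibly into the red form with first-order rate
#' `m = ln 2 / maturation_halftime`, and both forms are degraded with
#' shared first-order rate `d = ln 2 / degradation_halftime`:
#' \deqn{dB/dt = p - (m + d) B, \qquad dR/dt = m B - d R.}
#' The default maturation half-time of 4 hours matches the measured
#' blue-to-red maturation of the Fast-FT protein; the remaining defaults
#' are simulation fixture choices, not measurements.
#'
#' @param maturation_halftime hours; blue-to-red chromophore half-time.
#' @param degradation_halftime hours; protein half-life (`Inf` disables
#'   degradation, e.g. for pulse-chase maturation fits).
#' @param production_rate molecules/hour produced per actively
#'   transcribing cell.
#' @param production_cv coefficient of variation of the per-cell
#'   production rate (lognormal across cells; 0 = identical cells).
#' @param initial_immature molecules of immature protein present at time
#'   zero (a pulse/bolus; 0 for expression starting from nothing).
#' @return A `kinetics_config` list.
#' @export
kinetics_config <- function(maturation_halftime = 4,
                            degradation_halftime = 24,
                            production_rate = 1000,
                            production_cv = 0.5,
                            initial_immature = 0) {
  if (maturation_halftime <= 0 || degradation_halftime <= 0) {
    stop_config("halftimes must be > 0")
  }
  if (production_rate < 0 || initial_immature < 0 || production_cv < 0) {
    stop_config("rates and amounts must be >= 0")
  }
  structure(list(maturation_halftime = maturation_halftime,
                 degradation_halftime = degradation_halftime,
                 production_rate = production_rate,
                 production_cv = production_cv,
                 initial_immature = initial_immature),
            class = "kinetics_config")
}

#' Acquisition and background parameters of the simulated cytometer
#'
#' Measured fluorescence is modelled as channel gain x molecular amount x
#' multiplicative lognormal noise, plus additive lognormal
#' autofluorescence that every cell (Timer-positive or not) carries in
#' both channels. Unequal gains reproduce the acquisition-setting bias
#' between the blue and red detectors; the defaults are unbiased.
#'
#' @param blue_gain,red_gain fluorescence units per molecule.
#' @param autofluorescence_mu_blue,autofluorescence_mu_red mean of the
#'   log10 autofluorescence in each channel (log10 raw units).
#' @param autofluorescence_sigma SD of the log10 autofluorescence.
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise on the Timer signal.
#' @param fsc_mean,fsc_cv forward-scatter location and CV (FSC is
#'   simulated as an inert size channel).
#' @param n_cells cells per simulated sample.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A `measurement_config` list.
#' @export
measurement_config <- function(blue_gain = 1, red_gain = 1,
                               autofluorescence_mu_blue = 2,
                               autofluorescence_mu_red = 2,
                               autofluorescence_sigma = 0.25,
                               noise_cv = 0.3,
                               fsc_mean = 5e4, fsc_cv = 0.2,
                               n_cells = 1000, seed = 1L) {
  if (blue_gain <= 0 || red_gain <= 0) stop_config("gains must be > 0")
  if (autofluorescence_sigma <= 0) stop_config("autofluorescence_sigma must be > 0")
  if (noise_cv < 0) stop_config("noise_cv must be >= 0")
  if (n_cells < 1) stop_config("n_cells must be >= 1")
  structure(list(blue_gain = blue_gain, red_gain = red_gain,
                 autofluorescence_mu_blue = autofluorescence_mu_blue,
                 autofluorescence_mu_red = autofluorescence_mu_red,
                 autofluorescence_sigma = autofluorescence_sigma,
                 noise_cv = noise_cv, fsc_mean = fsc_mean, fsc_cv = fsc_cv,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "measurement_config")
}

#' Closed-form immature and mature Timer amounts
#'
#' Evaluates the two-compartment model of [kinetics_config()] at times
#' `t` (hours since expression onset), with initial condition
#' `B(0) = initial_immature`, `R(0) = 0`:
#' \deqn{B(t) = p/k + (B_0 - p/k) e^{-kt}, \quad k = m + d,}
#' and the matching convolution solution for the mature form. The `d = 0`
#' limit is handled analytically, so degradation-free pulses satisfy
#' `B(t) + R(t) = B0 + p t` exactly.
#'
#' @param config a `kinetics_config`.
#' @param t hours since onset; vectorized, all `t >= 0`.
#' @param production_rate optional per-call override of the production
#'   rate (used for per-cell draws).
#' @return Data frame with columns `immature` (B) and `mature` (R).
#' @export
kinetic_amounts <- function(config, t, production_rate = config$production_rate) {
  if (any(t < 0)) stop_config("t must be >= 0")
  m <- log(2) / config$maturation_halftime
  d <- if (is.infinite(config$degradation_halftime)) 0 else
    log(2) / config$degradation_halftime
  k <- m + d
  p <- production_rate
  b0 <- config$initial_immature
  B <- p / k + (b0 - p / k) * exp(-k * t)
  # R(t) = m * [ (p/k) * (1 - e^{-dt})/d + e^{-dt} (B0 - p/k)(1 - e^{-mt})/m ]
  prod_term <- if (d > 0) (1 - exp(-d * t)) / d else t
  R <- m * (p / k) * prod_term + exp(-d * t) * (b0 - p / k) * (1 - exp(-m * t))
  data.frame(immature = B, mature = R)
}

#' Recover the maturation half-time from pulse-chase data
#'
#' In a pulse-chase (production off after a bolus) the immature fraction
#' `B / (B + R)` decays as `exp(-m t)` regardless of shared degradation,
#' so a linear fit of its logarithm against time recovers the maturation
#' rate and hence the half-time `ln 2 / m`.
#'
#' @param t hours.
#' @param immature,mature amounts at `t`.
#' @return Estimated maturation half-time in hours.
#' @export
fit_maturation_halftime <- function(t, immature, mature) {
  frac <- immature / (immature + mature)
  ok <- is.finite(frac) & frac > 0
  if (sum(ok) < 3) stop_data("too few usable time points for the maturation fit")
  fit <- stats::lm(log(frac[ok]) ~ t[ok])
  rate <- -unname(stats::coef(fit)[2])
  if (rate <= 0) stop_data("immature fraction does not decay; cannot fit half-time")
  log(2) / rate
}

draw_autofluorescence <- function(meas, n) {
  data.frame(
    blue = 10^stats::rnorm(n, meas$autofluorescence_mu_blue,
                           meas$autofluorescence_sigma),
    red = 10^stats::rnorm(n, meas$autofluorescence_mu_red,
                          meas$autofluorescence_sigma))
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

#' Simulate a Timer-negative control sample
#'
#' Autofluorescence-only draw: every cell receives lognormal background
#' in the blue and red channels and an FSC value, nothing else. Seeded
#' and reproducible.
#'
#' @param meas a `measurement_config`.
#' @param sample_id sample identifier.
#' @return A [cell_matrix()] with channels `Timer_Blue`, `Timer_Red`,
#'   `FSC`.
#' @export
simulate_negative_control <- function(meas, sample_id = "negative_control") {
  set.seed(meas$seed)
  af <- draw_autofluorescence(meas, meas$n_cells)
  fsc <- meas$fsc_mean * lognormal_noise(meas$n_cells, meas$fsc_cv)
  cell_matrix(data.frame(Timer_Blue = af$blue, Timer_Red = af$red, FSC = fsc),
              sample_id)
}

#' Simulate one Timer-expressing sample
#'
#' A fraction of cells switch Timer expression on at a per-cell onset
#' age drawn uniformly on `[0, elapsed_hours]` (continuous stimulation),
#' with per-cell production rates lognormal around the configured rate.
#' Their immature/mature amounts come from [kinetic_amounts()], are
#' scaled by the channel gains and multiplied by lognormal measurement
#' noise; all cells additionally receive additive lognormal
#' autofluorescence in both channels. The per-cell ground truth (onset
#' age, true amounts, expression flag) is attached as attribute `truth`.
#'
#' @param kin a `kinetics_config`.
#' @param meas a `measurement_config` (its `seed` fixes the draw).
#' @param timer_on_fraction fraction of cells expressing the Timer.
#' @param elapsed_hours hours of stimulation before measurement; onset
#'   ages cannot exceed it.
#' @param sample_id sample identifier.
#' @return A [cell_matrix()] with channels `Timer_Blue`, `Timer_Red`,
#'   `FSC` and attribute `truth`.
#' @export
simulate_sample <- function(kin, meas, timer_on_fraction = 0.8,
                            elapsed_hours = 24, sample_id = "sample") {
  if (!is_scalar_number(timer_on_fraction) ||
      timer_on_fraction < 0 || timer_on_fraction > 1) {
    stop_config("timer_on_fraction must lie in [0, 1]")
  }
  if (elapsed_hours < 0) stop_config("elapsed_hours must be >= 0")
  set.seed(meas$seed)
  n <- meas$n_cells
  on <- stats::runif(n) < timer_on_fraction
  age <- ifelse(on, stats::runif(n, 0, elapsed_hours), 0)
  p_cell <- kin$production_rate * lognormal_noise(n, kin$production_cv)
  amounts <- kinetic_amounts(kin, age, production_rate = p_cell)
  amounts$immature[!on] <- 0
  amounts$mature[!on] <- 0
  af <- draw_autofluorescence(meas, n)
  blue <- meas$blue_gain * amounts$immature * lognormal_noise(n, meas$noise_cv) +
    af$blue
  red <- meas$red_gain * amounts$mature * lognormal_noise(n, meas$noise_cv) +
    af$red
  fsc <- meas$fsc_mean * lognormal_noise(n, meas$fsc_cv)
  out <- cell_matrix(data.frame(Timer_Blue = blue, Timer_Red = red, FSC = fsc),
                     sample_id)
  attr(out, "truth") <- data.frame(timer_on = on, onset_age = age,
                                   true_immature = amounts$immature,
                                   true_mature = amounts$mature)
  out
}

#' Simulate a full stimulation time course and write it to disk
#'
#' Generates one CSV per (timepoint, replicate) — onset ages bounded by
#' the elapsed time — plus one Timer-negative control CSV, ground-truth
#' sidecar files (`truth_*.csv`), and a serialized manifest whose group
#' labels are the timepoints. Every file gets its own deterministic seed
#' derived from `meas$seed`, so reruns are byte-identical. The default
#' layout (11 timepoints x 3 replicates) yields 33 sample files plus the
#' control.
#'
#' @param kin a `kinetics_config`.
#' @param meas a `measurement_config` (template; per-file seeds derived
#'   from `meas$seed`).
#' @param timepoints hours of stimulation.
#' @param samples_per_timepoint replicates per timepoint.
#' @param timer_on_fraction fraction of expressing cells (0 at elapsed
#'   time 0 effectively, since amounts are 0).
#' @param output_dir directory to create/write into.
#' @param blue_channel,red_channel channel names used in the manifest.
#' @return The `sample_manifest` describing the written dataset.
#' @export
simulate_timecourse <- function(kin = kinetics_config(),
                                meas = measurement_config(),
                                timepoints = c(0, 2, 4, 6, 8, 12, 16, 24, 32, 40, 48),
                                samples_per_timepoint = 3,
                                timer_on_fraction = 0.8,
                                output_dir,
                                blue_channel = "Timer_Blue",
                                red_channel = "Timer_Red") {
  if (length(timepoints) == 0) stop_config("timepoints must be nonempty")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(rep = seq_len(samples_per_timepoint), tp = timepoints)
  paths <- character(nrow(grid))
  groups <- character(0)
  for (i in seq_len(nrow(grid))) {
    tp <- grid$tp[i]
    sid <- sprintf("sample_t%03dh_rep%d", as.integer(tp), grid$rep[i])
    meas_i <- meas
    meas_i$seed <- (meas$seed + 7919L * i) %% .Machine$integer.max
    cm <- simulate_sample(kin, meas_i, timer_on_fraction = timer_on_fraction,
                          elapsed_hours = tp, sample_id = sid)
    paths[i] <- file.path(output_dir, paste0(sid, ".csv"))
    write_output_csv(as.data.frame(cm), paths[i])
    truth_dir <- file.path(output_dir, "truth")
    dir.create(truth_dir, showWarnings = FALSE)
    write_output_csv(attr(cm, "truth"),
                     file.path(truth_dir, paste0("truth_", sid, ".csv")))
    groups[sid] <- paste0(tp, "h")
  }
  neg_meas <- meas
  neg_meas$seed <- (meas$seed + 104729L) %% .Machine$integer.max
  neg <- simulate_negative_control(neg_meas)
  neg_path <- file.path(output_dir, "negative_control.csv")
  write_output_csv(as.data.frame(neg), neg_path)
  # the serialized manifest lives in a subdirectory so that the data
  # directory itself contains only per-cell CSVs (globbable as *.csv)
  build_manifest(c(paths, neg_path), negative_control = neg_path,
                 blue_channel = blue_channel, red_channel = red_channel,
                 groups = groups, output_dir = file.path(output_dir, "manifest"))
}
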