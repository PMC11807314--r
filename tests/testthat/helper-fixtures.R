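# Shared fixtures: all test data is generated in code at run time.

write_sample_csv <- function(path, df) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A small seeded time-course dataset on disk (manifest-ready).
make_tiny_timecourse <- function(dir, n_cells = 300, seed = 42,
                                 timepoints = c(0, 8, 24),
                                 samples_per_timepoint = 1) {
  simulate_timecourse(
    kinetics_config(),
    measurement_config(n_cells = n_cells, seed = seed),
    timepoints = timepoints,
    samples_per_timepoint = samples_per_timepoint,
    output_dir = dir)
}

# The per-operation pipeline in its fixed batch order, applied to
# in-memory cell matrices (used for exact invariance checks that must
# not round-trip through 6-digit CSV output).
pipeline_in_memory <- function(samples, neg,
                               blue = "Timer_Blue", red = "Timer_Red",
                               q = 0.975, method = "MAD",
                               normalize = TRUE, log_floor = 1e-9) {
  thr <- compute_gate_thresholds(neg, threshold_spec("quantile", quantile_q = q),
                                 blue, red)
  gated <- gate_negative_cells(neg, thr, blue, red)
  params <- compute_normalization_params(gated, blue, red, method = method,
                                         log_floor = log_floor)
  lapply(samples, transform_sample, thr = thr, params = params,
         blue_channel = blue, red_channel = red, normalize = normalize)
}

# ---- Independent brute-force oracle (plain arithmetic, no package calls) ----

oracle_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- 1 + (n - 1) * q
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_median <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
}

oracle_mad <- function(x) 1.4826 * oracle_median(abs(x - oracle_median(x)))

oracle_sd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))

# Full brute-force evaluation of the preprocessing chain on one tiny
# table: floored log10, max/scale of the gated negative, per-cell
# normalization and polar transform.
oracle_pipeline <- function(sample_blue, sample_red, neg_blue, neg_red,
                            q = 0.975, method = "MAD", log_floor = 1) {
  thr_blue <- oracle_quantile(neg_blue, q)
  thr_red <- oracle_quantile(neg_red, q)
  gated <- neg_blue <= thr_blue & neg_red <= thr_red
  lg <- function(v) log10(ifelse(v < log_floor, log_floor, v))
  gb <- lg(neg_blue[gated]); gr <- lg(neg_red[gated])
  scale_of <- function(v) if (method == "MAD") oracle_mad(v) else oracle_sd(v)
  loc_b <- max(gb); s_b <- scale_of(gb)
  loc_r <- max(gr); s_r <- scale_of(gr)
  bn <- (lg(sample_blue) - loc_b) / s_b
  rn <- (lg(sample_red) - loc_r) / s_r
  bc <- ifelse(bn < 0, 0, bn); rc <- ifelse(rn < 0, 0, rn)
  I <- sqrt(bc^2 + rc^2)
  theta <- ifelse(I > 0, acos(bc / I) * 180 / pi, NA_real_)
  list(thr_blue = thr_blue, thr_red = thr_red, gated = gated,
       loc_b = loc_b, s_b = s_b, loc_r = loc_r, s_r = s_r,
       blue_norm = bn, red_norm = rn, intensity = I, angle = theta)
}
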