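make_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- tempfile("qcfix")
      manifest <- make_tiny_timecourse(dir, n_cells = 200)
      cache <<- list(manifest = manifest,
                     result = timer_transform_batch(manifest, write = FALSE))
    }
    cache
  }
})

test_that("per-sample summaries match hand computation on a toy table", {
  thr <- structure(list(blue = 10, red = 10), class = "gate_thresholds")
  params <- structure(list(method = "SD", log_base = 10, log_floor = 1,
                           blue_location = 1, blue_scale = 0.5,
                           red_location = 1, red_scale = 0.5, n_gated_neg = 10L),
                      class = "normalization_params")
  raw <- cell_matrix(data.frame(Timer_Blue = c(100, 1, 1, 1000, 5),
                                Timer_Red = c(1, 100, 1, 1000, 5),
                                FSC = c(10, 20, 30, 40, 50)), "toy")
  tc <- transform_sample(raw, thr, params, "Timer_Blue", "Timer_Red")
  s <- summarize_sample(tc, raw, "Timer_Blue", "Timer_Red", group = "g1")
  expect_equal(s$n_total, 5L)
  expect_equal(s$n_timer_positive, 3L)
  expect_equal(s$frac_NegNeg, 2 / 5)
  expect_equal(s$frac_BluePosRedNeg, 1 / 5)
  expect_equal(s$frac_BluePosRedPos, 1 / 5)
  expect_equal(s$frac_BlueNegRedPos, 1 / 5)
  expect_equal(s$mfi_blue, mean(c(100, 1, 1, 1000, 5)))
  expect_equal(s$mfi_red, mean(c(1, 100, 1, 1000, 5)))
  expect_equal(s$mean_fsc, 30)
  # cells (100,1): angle 0; (1,100): 90; (1000,1000): 45 -> mean 45
  expect_equal(s$mean_angle, 45)
  expect_equal(s$group, "g1")
  # quadrant fractions always sum to one
  expect_equal(s$frac_NegNeg + s$frac_BluePosRedNeg + s$frac_BluePosRedPos +
                 s$frac_BlueNegRedPos, 1, tolerance = 1e-9)
  # misalignment is fatal
  expect_error(summarize_sample(tc, raw[1:3, ], "Timer_Blue", "Timer_Red"),
               class = "timerflow_data_error")
  # all cells in one quadrant
  raw1 <- cell_matrix(data.frame(Timer_Blue = c(100, 200), Timer_Red = c(1, 2)), "q")
  tc1 <- transform_sample(raw1, thr, params, "Timer_Blue", "Timer_Red")
  s1 <- summarize_sample(tc1, raw1, "Timer_Blue", "Timer_Red")
  expect_equal(s1$frac_BluePosRedNeg, 1)
  expect_true(is.na(s1$mean_fsc))
})

test_that("mean angle is missing when no cell is Timer-positive", {
  thr <- structure(list(blue = 1e9, red = 1e9), class = "gate_thresholds")
  params <- structure(list(method = "SD", log_base = 10, log_floor = 1,
                           blue_location = 1, blue_scale = 1,
                           red_location = 1, red_scale = 1, n_gated_neg = 10L),
                      class = "normalization_params")
  raw <- cell_matrix(data.frame(Timer_Blue = c(10, 20), Timer_Red = c(10, 20)), "s")
  tc <- transform_sample(raw, thr, params, "Timer_Blue", "Timer_Red")
  s <- summarize_sample(tc, raw, "Timer_Blue", "Timer_Red")
  expect_equal(s$n_timer_positive, 0L)
  expect_true(is.na(s$mean_angle))
})

test_that("batch summaries cover every file with its group label", {
  fix <- make_result()
  summ <- summarize_batch(fix$result, fix$manifest)
  expect_equal(nrow(summ), 4L)
  expect_setequal(summ$group, c("0h", "8h", "24h", "unassigned"))
})

test_that("plot data is a pure projection of the result", {
  fix <- make_result()
  res <- fix$result
  pd <- plot_tocky(res, "angle_intensity")
  # every plotted point is an existing (angle, intensity) pair
  for (sid in unique(pd$data$sample_id)) {
    tc <- res$samples[[sid]]
    keep <- tc$timer_positive & !is.na(tc$angle)
    sub <- pd$data[pd$data$sample_id == sid, ]
    expect_equal(sub$x, tc$angle[keep])
    expect_equal(sub$y, tc$intensity[keep])
  }
  expect_true(all(pd$data$x >= 0 & pd$data$x <= 90))

  pd_raw <- plot_tocky(res, "timer_fluorescence")
  n_cells <- sum(vapply(res$samples, nrow, 0L))
  expect_equal(nrow(pd_raw$data), n_cells)

  pd_norm <- plot_tocky(res, "normalized_timer_fluorescence")
  expect_equal(nrow(pd_norm$data), sum(res$counts$n_timer_positive))

  # group_order fixes the panel order
  pd_ord <- plot_tocky(res, "timer_fluorescence",
                       group_order = c("24h", "8h", "0h", "unassigned"))
  expect_equal(levels(pd_ord$data$group), c("24h", "8h", "0h", "unassigned"))

  # written plot data reproduces the in-memory projection
  out <- withr::local_tempdir()
  plot_tocky(res, "angle_intensity", output_dir = out)
  disk <- read.csv(file.path(out, "plotdata_angle_intensity.csv"))
  expect_equal(nrow(disk), nrow(pd$data))
  expect_equal(disk$x, pd$data$x, tolerance = 1e-12)
  expect_true(file.exists(file.path(out, "plot_angle_intensity.png")))
})

test_that("group exclusion removes exactly that group", {
  fix <- make_result()
  res2 <- exclude_group(fix$result, "0h")
  expect_false("0h" %in% res2$counts$group)
  expect_false(any(grepl("t000h", names(res2$samples))))
  expect_equal(length(res2$samples), length(fix$result$samples) - 1L)
  summ <- summarize_batch(res2, fix$manifest)
  expect_false("0h" %in% summ$group)
  err <- expect_error(exclude_group(fix$result, "99h"),
                      class = "timerflow_config_error")
  expect_match(conditionMessage(err), "available")
})
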