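temps_for <- function(n, start = 10, step = 0.1) start - step * (seq_len(n) - 1)

test_that("moving-mean smoothing matches the brute-force window definition", {
  x <- cumsum(rnorm(100))
  tr <- new_trace(x, temps_for(100))
  sm <- smooth_trace(tr, 0.05)
  expect_equal(attr(sm, "smooth_window"), 5L)
  expect_equal(sm$value, oracle_moving_mean(x, 5))
  # 2.5 % fallback window
  sm2 <- smooth_trace(tr, 0.025)
  expect_equal(attr(sm2, "smooth_window"), 2L)
  expect_equal(sm2$value, oracle_moving_mean(x, 2))
  # constants and interior of a linear trace are unchanged
  const <- new_trace(rep(3, 40), temps_for(40))
  expect_equal(smooth_trace(const, 0.1)$value, rep(3, 40))
  # an odd centered window leaves the interior of a linear trace unchanged
  lin <- new_trace(seq(0, 99), temps_for(100))
  sml <- smooth_trace(lin, 0.05)$value
  expect_equal(sml[3:98], seq(0, 99)[3:98])
  expect_error(smooth_trace(new_trace(numeric(0), numeric(0))), "empty")
  expect_error(smooth_trace(const, 0.6), "0.5")
  expect_error(smooth_trace(const, 0), "0.5")
})

test_that("TID flattening finds the end of a sharp increase", {
  # flat trace: no event
  flat <- new_trace(rep(2, 60), temps_for(60))
  expect_true(is.na(detect_tcloud_tid(flat)$t_cloud_app_C))
  # single step: first post-jump frame
  step <- new_trace(c(rep(0, 30), rep(8, 30)), temps_for(60))
  res <- detect_tcloud_tid(step)
  expect_equal(res$flattening_frame, 32L)
  expect_equal(res$t_cloud_app_C, temps_for(60)[32])
  # smoothed sigmoid: detected near the end of the transition
  n <- 400
  temps <- temps_for(n, start = 10, step = 0.05)
  v <- 100 / (1 + exp((temps - 4) / 0.15)) # transition ~ 3.55..4.45 degC
  tr <- smooth_trace(new_trace(v, temps), 0.05)
  res <- detect_tcloud_tid(tr)
  expect_lt(abs(res$t_cloud_app_C - 3.55), 2 * 0.05 + 0.1)
})

test_that("TWP minimum detection honors ties, restriction and noise floor", {
  # V-shaped trace: vertex
  v <- c(seq(50, 0, by = -5), seq(2, 40, by = 2))
  tr <- new_trace(v, temps_for(length(v)))
  res <- detect_tcloud_twp(tr)
  expect_equal(res$minimum_frame, which.min(v))
  expect_equal(res$t_cloud_app_C, tr$temp_C[which.min(v)])
  # monotone increase: absent
  up <- new_trace(seq(0, 59), temps_for(60))
  expect_true(is.na(detect_tcloud_twp(up)$t_cloud_app_C))
  # restriction excludes a deeper late minimum (gray-ice regime)
  w <- c(seq(40, 20, by = -1), rep(20, 10), seq(18, 0, by = -2))
  trw <- new_trace(w, temps_for(length(w)))
  res_all <- detect_tcloud_twp(trw)
  res_cut <- detect_tcloud_twp(trw, search_end = 25)
  expect_equal(res_all$minimum_frame, length(w))
  expect_equal(res_cut$minimum_frame, 21L)
})

test_that("nucleation detection picks the right direction", {
  flat <- new_trace(rep(5, 50), temps_for(50))
  expect_true(is.na(detect_tnuc(flat)$t_nuc_C))
  up <- new_trace(c(rep(10, 30), rep(200, 30)), temps_for(60))
  res_up <- detect_tnuc(up, "auto")
  expect_equal(res_up$max_gradient_frame, 31L)
  expect_equal(res_up$direction, "increase")
  down <- new_trace(c(rep(200, 30), rep(10, 30)), temps_for(60))
  res_dn <- detect_tnuc(down, "auto")
  expect_equal(res_dn$max_gradient_frame, 31L)
  expect_equal(res_dn$direction, "decrease")
  # explicit direction overrides auto
  expect_true(is.na(detect_tnuc(down, "increase")$t_nuc_C))
  # determinism
  expect_identical(detect_tnuc(up, "auto"), detect_tnuc(up, "auto"))
})

test_that("frame-to-temperature lookup follows the logged grid", {
  prof <- cooling_profile(15, -40, rate = 0.1, capture_interval = 30)
  log <- simulate_device_temperature(prof)
  sq <- structure(list(device_temp_C = log$device_temp_C),
                  class = "frame_sequence")
  expect_equal(frame_to_temperature(1, sq), 15)
  expect_equal(frame_to_temperature(nrow(log), sq), -40)
  # 0.1 degC/min at 30 s/frame: 0.05 degC per image
  i <- 500
  expect_equal(frame_to_temperature(i, sq), 15 - 0.05 * (i - 1))
  expect_error(frame_to_temperature(nrow(log) + 1, sq), "range")
})

test_that("noise-free wells recover ground truth across rates and volumes", {
  cases <- rbind(
    data.frame(rate = c(0.5, 1, 2), volume = 20),
    data.frame(rate = 1, volume = c(5, 24))
  )
  for (i in seq_len(nrow(cases))) {
    # ramp deep enough that the lagged sample reaches the nucleation point
    # even at the fastest rate (offset rate/60k can approach 10 degC)
    prof <- short_profile(rate = cases$rate[i], capture_interval = 5,
                          end_temp = -35)
    step <- cases$rate[i] / 60 * 5
    sq <- generate_well_sequence(
      well_spec("protein", true_t_cloud = 4, noise_sd = 0),
      prof, thermal_lag(volume = cases$volume[i]), seed = 21,
      dims = c(32, 32))
    gt <- cloudpoint:::ground_truth_row(sq)
    for (strat in c("TID", "TWP:0.50")) {
      det <- detect_trace_events(extract_trace(sq, strat))
      expect_lt(abs(det$t_cloud_app_C - gt$cloud_end_device_temp_C),
                2 * step + sq$spec$transition_width)
      expect_lt(abs(det$t_nuc_C - gt$nuc_device_temp_C), 2 * step + 1e-9)
    }
  }
})

test_that("detection is reported on the chosen temperature grid", {
  prof <- short_profile()
  sq <- generate_well_sequence(well_spec("protein", true_t_cloud = 4,
                                         noise_sd = 0),
                               prof, thermal_lag(volume = 24), seed = 5,
                               dims = c(32, 32))
  dev <- detect_trace_events(extract_trace(sq, "TID"))
  sam <- detect_trace_events(extract_trace(sq, "TID", temperature = "sample"))
  # device-reported value sits below the sample-reported one by the lag
  expect_lt(dev$t_cloud_app_C, sam$t_cloud_app_C - 0.5)
  # the sample-grid value recovers the true end of the transition
  expect_lt(abs(sam$t_cloud_app_C - 3), 0.3)
})

test_that("per-trace events combine cloud and nucleation detection", {
  prof <- short_profile()
  sq <- generate_well_sequence(well_spec("protein", true_t_cloud = 4),
                               prof, default_lag(), seed = 8, dims = c(32, 32))
  out <- detect_events(sq, strategies = c("TID", "TWP:0.50"))
  expect_equal(nrow(out), 2)
  expect_true(all(!is.na(out$t_cloud_app_C)))
  expect_true(all(!is.na(out$t_nuc_C)))
  expect_true(all(out$t_cloud_app_C > out$t_nuc_C))
  expect_equal(attr(out, "settings")$window_fraction, 0.05)
})
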