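test_that("the three optical regimes are distinct at the 0.50 white level", {
  twp50 <- function(frame) {
    total_white_pixels(binarize(to_gray(frame), 0.5))
  }
  spec <- well_spec("protein", true_t_cloud = 4, noise_sd = 0)
  clear <- render_well_frame(spec, 10)
  turbid <- render_well_frame(spec, 0)
  frozen <- render_well_frame(spec, -25)
  # clear: the specular spot puts pixels above the 0.50 level
  expect_gt(twp50(clear), 0)
  # turbid: spot removed, background below the level
  expect_equal(twp50(turbid), 0)
  # white protein ice: more white pixels than the turbid frame
  expect_gt(twp50(frozen), twp50(turbid))
  expect_equal(twp50(frozen), 64 * 64)

  water <- well_spec("water", noise_sd = 0)
  pre <- render_well_frame(water, -20)
  ice <- render_well_frame(water, -32)
  # gray water ice: fewer white pixels than before freezing
  expect_lt(twp50(ice), twp50(pre))
})

test_that("rendering is deterministic without noise and seeded with it", {
  spec0 <- well_spec("protein", noise_sd = 0)
  expect_identical(render_well_frame(spec0, 2), render_well_frame(spec0, 2))
  spec <- well_spec("protein")
  set.seed(1); a <- render_well_frame(spec, 2)
  set.seed(1); b <- render_well_frame(spec, 2)
  set.seed(2); c <- render_well_frame(spec, 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("raster and spec validation", {
  expect_error(render_well_frame(well_spec("water"), 5, dims = c(8, 8)),
               "16")
  expect_error(well_spec("water", true_t_cloud = 3), "protein")
  expect_error(well_spec("protein", true_t_cloud = -25, true_t_nuc = -20),
               "greater")
  expect_error(well_spec("protein", base_brightness = 1.2), "\\[0, 1\\]")
})

test_that("the clouding transition interpolates over its stated width", {
  spec <- well_spec("protein", true_t_cloud = 4, noise_sd = 0,
                    transition_width = 1)
  mid <- mean_level(render_well_frame(spec, 3.5), "gray")
  hi <- mean_level(render_well_frame(spec, 4.5), "gray")
  lo <- mean_level(render_well_frame(spec, 2.5), "gray")
  expect_lt(mid, hi)
  expect_gt(mid, lo)
  # zero width renders a step
  step <- well_spec("protein", true_t_cloud = 4, noise_sd = 0,
                    transition_width = 0)
  expect_equal(mean_level(render_well_frame(step, 3.999), "gray"),
               mean_level(render_well_frame(step, 2.5), "gray"))
})

test_that("plates are reproducible and share one device log", {
  prof <- short_profile()
  specs <- replicate_specs(well_spec("protein"), 6)
  p1 <- generate_plate(specs, prof, default_lag(), seed = 11, dims = c(16, 16))
  p2 <- generate_plate(specs, prof, default_lag(), seed = 11, dims = c(16, 16))
  expect_identical(p1$wells, p2$wells)
  expect_equal(length(p1$wells), 6)
  for (sq in p1$wells) {
    expect_identical(sq$device_temp_C, p1$device_log$device_temp_C)
  }
  # different seed changes the pixels
  p3 <- generate_plate(specs, prof, default_lag(), seed = 12, dims = c(16, 16))
  expect_false(identical(p1$wells[[1]]$frames, p3$wells[[1]]$frames))
  expect_error(generate_plate(list(), prof, default_lag()), "At least one")
})

test_that("ground truth orders clouding before nucleation and conserves frames", {
  prof <- short_profile()
  plate <- generate_plate(
    list(well_spec("protein", true_t_cloud = 5),
         well_spec("protein", true_t_cloud = 2), well_spec("water")),
    prof, default_lag(), seed = 4, dims = c(16, 16))
  gt <- plate$ground_truth
  protein <- gt[gt$kind == "protein", ]
  expect_true(all(protein$cloud_frame < protein$nuc_frame))
  expect_true(all(protein$cloud_frame <= protein$cloud_end_frame))
  n_expected <- profile_duration(prof) / prof$capture_interval + 1
  for (sq in plate$wells) expect_equal(length(sq$frames), n_expected)
})

test_that("a practically instantaneous lag reproduces device-based crossings", {
  prof <- short_profile(capture_interval = 1)
  spec <- well_spec("protein", true_t_cloud = 5, noise_sd = 0)
  fast <- thermal_lag(volume = 20, lag_coefficient = 1) # k * dt = 1
  plate <- generate_plate(list(spec), prof, fast, seed = 1, dims = c(16, 16))
  gt <- plate$ground_truth
  dev_cloud <- which(plate$device_log$device_temp_C <= 5)[1]
  dev_nuc <- which(plate$device_log$device_temp_C <= spec$true_t_nuc)[1]
  expect_lte(abs(gt$cloud_frame - dev_cloud), 1)
  expect_lte(abs(gt$nuc_frame - dev_nuc), 1)
})

test_that("plates round-trip through PNG stacks and CSV logs", {
  prof <- cooling_profile(6, -24, rate = 2, capture_interval = 10)
  plate <- generate_plate(
    list(well_spec("protein", true_t_cloud = 3), well_spec("water")),
    prof, default_lag(), seed = 2, dims = c(16, 16))
  dir <- withr::local_tempdir()
  write_plate(plate, dir)
  expect_true(file.exists(file.path(dir, "temperature_log.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  rt <- read_well_sequence(dir, "A1")
  expect_equal(length(rt$frames), length(plate$wells$A1$frames))
  expect_identical(rt$frames[[50]], plate$wells$A1$frames[[50]])
  expect_equal(rt$device_temp_C, plate$device_log$device_temp_C)
  expect_equal(rt$capture_interval, 10)
  # a re-extracted trace matches the in-memory one
  tr_mem <- extract_trace(plate$wells$A1, "TWP:0.50")
  tr_disk <- extract_trace(rt, "TWP:0.50")
  expect_equal(tr_disk$value, tr_mem$value)
})
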