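test_that("gray conversion uses the BT.601 luminance weights", {
  mk <- function(r, g, b) {
    f <- array(0L, c(4, 4, 3))
    f[, , 1] <- r; f[, , 2] <- g; f[, , 3] <- b
    f
  }
  expect_true(all(to_gray(mk(90, 90, 90)) == 90))
  expect_true(all(to_gray(mk(255, 0, 0)) == 76))
  expect_true(all(to_gray(mk(0, 0, 255)) == 29))
  expect_error(to_gray(matrix(1, 4, 4)), "RGB")
})

test_that("mean levels equal per-pixel brute-force sums", {
  half <- array(0L, c(4, 4, 3)); half[1:2, , ] <- 200L
  expect_equal(mean_level(half, "red"), 100)
  uni <- array(100L, c(5, 5, 3))
  expect_equal(mean_level(uni, "gray"), 100)
  set.seed(42)
  for (i in 1:5) {
    f <- random_frame()
    for (ch in c("red", "green", "blue")) {
      k <- match(ch, c("red", "green", "blue"))
      expect_equal(mean_level(f, ch), sum(f[, , k]) / (16 * 16))
    }
    expect_equal(mean_level(f, "gray"), sum(to_gray(f)) / (16 * 16))
  }
})

test_that("Otsu threshold separates bimodal images and matches brute force", {
  g <- matrix(c(50L, 200L), 16, 16)
  t <- otsu_threshold(g)
  expect_gt(t, 50 / 255)
  expect_lt(t, 200 / 255)
  expect_equal(otsu_threshold(matrix(77L, 8, 8)), 77 / 255)
  set.seed(7)
  for (i in 1:15) {
    g <- bimodal_gray(lo = sample(30:90, 1), hi = sample(140:220, 1))
    expect_equal(otsu_threshold(g), oracle_otsu(g))
  }
  expect_error(otsu_threshold(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("white levels resolve from the first frame only", {
  expect_equal(resolve_white_level(white_level_spec("fixed", 0.5)), 0.5)
  uni <- array(128L, c(16, 16, 3))
  expect_equal(resolve_white_level(white_level_spec("mean_gray_t0"), uni),
               128 / 255)
  set.seed(3)
  bi <- array(rep(bimodal_gray(c(16, 16)), 3), c(16, 16, 3))
  lvl <- resolve_white_level(white_level_spec("otsu_t0"), bi)
  expect_equal(lvl, oracle_otsu(to_gray(bi)))
  expect_error(white_level_spec("fixed", 1), "inside")
  expect_error(white_level_spec("otsu_t0", 0.5), "fixed")
})

test_that("binarization is strict at the threshold", {
  g <- matrix(c(0L, 100L, 128L, 255L), 2, 2)
  expect_equal(sum(binarize(g, 0)), 3)        # all non-zero pixels
  expect_equal(sum(binarize(g, 1)), 0)
  # 128/255 = 0.502 > 0.50
  expect_true(all(binarize(matrix(128L, 4, 4), 0.5)))
  expect_false(any(binarize(matrix(127L, 4, 4), 0.5)))
  expect_error(binarize(g, 1.2), "\\[0, 1\\]")
})

test_that("white-pixel counts are exact", {
  expect_equal(total_white_pixels(matrix(FALSE, 64, 64)), 0L)
  expect_equal(total_white_pixels(matrix(TRUE, 64, 64)), 4096L)
  checker <- outer(1:64, 1:64, function(i, j) (i + j) %% 2 == 0)
  expect_equal(total_white_pixels(checker), 2048L)
})

test_that("white-pixel count is monotone in the level", {
  set.seed(11)
  for (i in 1:10) {
    g <- to_gray(random_frame())
    lv <- sort(runif(4))
    counts <- vapply(lv, function(l) total_white_pixels(binarize(g, l)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("total intensity difference matches its definition and bounds", {
  f <- random_frame()
  expect_equal(total_intensity_difference(f, f), 0)
  g <- f; g[3, 5, 2] <- g[3, 5, 2] + 10L
  expect_equal(total_intensity_difference(g, f), 10)
  set.seed(5)
  for (i in 1:5) {
    a <- random_frame(); b <- random_frame(); c <- random_frame()
    expect_equal(total_intensity_difference(a, b), oracle_tid(a, b))
    # triangle bound of the absolute-difference definition
    expect_lte(total_intensity_difference(a, b),
               total_intensity_difference(a, c) +
                 total_intensity_difference(c, b))
    expect_gte(total_intensity_difference(a, b), 0)
  }
  expect_error(total_intensity_difference(f, f[1:8, , , drop = FALSE]),
               "shape")
})

test_that("trace extraction honors strategies and contracts", {
  prof <- cooling_profile(6, -24, rate = 2, capture_interval = 10)
  sq <- generate_well_sequence(well_spec("protein", true_t_cloud = 3),
                               prof, default_lag(), seed = 9,
                               dims = c(16, 16))
  tid <- extract_trace(sq, "TID")
  expect_equal(tid$value[1], 0)
  expect_true(all(tid$value >= 0))
  expect_equal(nrow(tid), length(sq$frames))
  expect_equal(tid$temp_C, sq$device_temp_C)

  twp <- extract_trace(sq, "TWP:0.50")
  expect_equal(attr(twp, "white_level"), 0.5)
  expect_true(all(twp$value == floor(twp$value) & twp$value >= 0 &
                    twp$value <= 16 * 16))
  expect_error(extract_trace(sq, "TWP"), "white level")
  expect_error(extract_trace(sq, "nonsense"), "Unknown strategy")

  # a constant sequence gives an all-zero TID trace
  const <- sq
  const$frames <- rep(sq$frames[1], 20)
  const$device_temp_C <- sq$device_temp_C[1:20]
  const$sample_temp_C <- sq$sample_temp_C[1:20]
  const$time_s <- sq$time_s[1:20]
  expect_true(all(extract_trace(const, "TID")$value == 0))

  # data-dependent levels resolve per well from t0
  ot <- extract_trace(sq, "TWP:otsu_t0")
  expect_equal(attr(ot, "white_level"), otsu_threshold(to_gray(sq$frames[[1]])))
  mg <- extract_trace(sq, "TWP:mean_gray_t0")
  expect_equal(attr(mg, "white_level"), mean_level(sq$frames[[1]], "gray") / 255)
})

test_that("mean-level clouding signal stays in the expected small range", {
  prof <- cooling_profile(8, -26, rate = 1, capture_interval = 10)
  sq <- generate_well_sequence(well_spec("protein", true_t_cloud = 4,
                                         noise_sd = 0),
                               prof, default_lag(), seed = 2)
  mgl <- extract_trace(sq, "MGL")
  gt <- cloudpoint:::ground_truth_row(sq)
  before <- mgl$value[gt$cloud_frame - 10]
  after <- mgl$value[gt$cloud_end_frame + 10]
  change <- abs(before - after)
  expect_gt(change, 1)
  expect_lte(change, 10)
})
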