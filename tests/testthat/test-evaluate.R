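uniform_dose <- function(value, mask_idx = NULL, d = c(6, 6, 6),
                         outside = 0) {
  a <- array(outside, d)
  if (is.null(mask_idx)) a[] <- value else a[mask_idx] <- value
  image_volume(a, c(2, 2, 2), modality = "DOSE")
}

test_that("cumulative DVH behaves like its definition", {
  d <- c(6, 6, 6)
  mask <- binary_mask(array(1, d), c(2, 2, 2))
  dose <- uniform_dose(100)
  curve <- dvh(dose, mask, bin_width = 1)
  expect_equal(curve$volume_pct[curve$dose_pct == 0], 100)
  expect_true(all(curve$volume_pct[curve$dose_pct <= 100] == 100))
  expect_true(all(curve$volume_pct[curve$dose_pct > 100] == 0))
  expect_true(all(diff(curve$volume_pct) <= 0))
  # 3-voxel mask, doses {90, 100, 110}: V(95) counts 2 of 3
  m3 <- array(0, d); m3[1:3] <- 1
  dose3 <- uniform_dose(0)
  dose3$data[1:3] <- c(90, 100, 110)
  c3 <- dvh(dose3, binary_mask(m3, c(2, 2, 2)), bin_width = 5)
  expect_equal(c3$volume_pct[c3$dose_pct == 95], 100 * 2 / 3,
               tolerance = 1e-9)
  expect_error(dvh(dose, binary_mask(array(0, d), c(2, 2, 2))), "empty")
})

test_that("plan metrics match brute-force voxel counting", {
  d <- c(6, 6, 6)
  ptv_arr <- array(0, d); ptv_arr[2:5, 2:5, 2:5] <- 1
  ptv <- binary_mask(ptv_arr, c(2, 2, 2))
  # dose >= 100 exactly on the PTV and nowhere else: the ideal CI of 1
  ideal <- uniform_dose(102, which(ptv_arr > 0))
  m <- plan_metrics(ideal, ptv)
  expect_equal(m$ci, 1)
  expect_equal(m$d_min, 102); expect_equal(m$d_max, 102)
  expect_equal(m$d_mean, 102)
  expect_equal(m$v95, 100); expect_equal(m$v100, 100)
  # 100 PTV voxels hot plus 7 outside: CI = 1.07
  d2 <- c(10, 10, 10)
  arr <- array(0, d2); arr[1:100] <- 1
  ptv100 <- binary_mask(arr, c(2, 2, 2))
  dose <- image_volume(array(0, d2), c(2, 2, 2), modality = "DOSE")
  dose$data[1:100] <- 105
  dose$data[101:107] <- 101
  m2 <- plan_metrics(dose, ptv100)
  expect_equal(m2$ci, 1.07, tolerance = 1e-12)
  # invariants
  expect_true(m2$d_min <= m2$d_mean && m2$d_mean <= m2$d_max)
  expect_error(plan_metrics(dose, binary_mask(array(0, d2), c(2, 2, 2))),
               "empty")
})

test_that("pixel dose differences count exactly", {
  f <- smooth_dose_field(21, seed = 3)
  ref <- plane_dose_volume(f)
  roi <- plane_roi(f)
  same <- dose_difference(ref, ref, roi)
  expect_equal(same$mean_abs, 0)
  expect_equal(same$max_abs, 0)
  expect_equal(same$passing_rate, 100)
  # uniform +1.5 offset passes the 2% criterion everywhere
  up <- ref; up$data <- up$data + 1.5
  d15 <- dose_difference(ref, up, roi)
  expect_equal(d15$max_abs, 1.5)
  expect_equal(d15$mean_abs, 1.5)
  expect_equal(d15$passing_rate, 100)
  # one pixel out of N offset by +3: passing = 100 (N-1) / N
  one <- ref
  one$data[11, 2, 11] <- one$data[11, 2, 11] + 3
  d1 <- dose_difference(ref, one, roi)
  n <- length(d1$delta)
  expect_equal(d1$passing_rate, 100 * (n - 1) / n, tolerance = 1e-9)
  expect_equal(d1$max_abs, 3)
  bad <- ref; bad$origin <- bad$origin + 1
  expect_error(dose_difference(ref, bad, roi), "grid")
})

test_that("gamma equals its exhaustive brute-force oracle", {
  f1 <- smooth_dose_field(21, seed = 11)
  f2 <- smooth_dose_field(21, seed = 12)
  ref <- plane_dose_volume(f1); ev <- plane_dose_volume(f2)
  roi <- plane_roi(f1)
  g <- gamma_index(ref, ev, 2, 1, roi)
  oracle <- gamma_oracle(ref, ev, 2, 1, roi)
  expect_lt(max(abs(g$gamma - oracle)), 1e-6)
})

test_that("gamma analytic cases and invariances hold", {
  f <- smooth_dose_field(21, seed = 4)
  ref <- plane_dose_volume(f)
  roi <- plane_roi(f)
  # identical distributions: gamma = 0 everywhere
  g0 <- gamma_index(ref, ref, 2, 1, roi)
  expect_lt(g0$max, 1e-12)
  expect_equal(g0$passing_rate, 100)
  # flat fields 2% apart: gamma = 1 exactly (distance term cannot help)
  flat <- plane_dose_volume(matrix(100, 21, 21))
  flat2 <- plane_dose_volume(matrix(102, 21, 21))
  g1 <- gamma_index(flat, flat2, 2, 1, roi)
  expect_equal(min(g1$gamma), 1, tolerance = 1e-12)
  expect_equal(g1$max, 1, tolerance = 1e-12)
  expect_equal(g1$passing_rate, 100)
  # flat-field symmetry: swapping the offset's carrier changes nothing
  g1b <- gamma_index(flat2, flat, 2, 1, roi)
  expect_equal(g1b$gamma, g1$gamma, tolerance = 1e-12)
  # tightening the criteria never decreases any gamma value
  ev <- plane_dose_volume(smooth_dose_field(21, seed = 5))
  gl <- gamma_index(ref, ev, 2, 1, roi)
  gt <- gamma_index(ref, ev, 1, 0.5, roi)
  expect_true(all(gt$gamma >= gl$gamma - 1e-12))
  # spatial tolerance can only help: gamma pass rate >= |dD| pass rate
  dd <- dose_difference(ref, ev, roi)
  expect_gte(gl$passing_rate, dd$passing_rate)
  expect_error(gamma_index(ref, ev, -2, 1, roi), "positive")
})

test_that("gamma pass rate dominates the dose-difference pass rate on random pairs", {
  for (s in 1:5) {
    f1 <- smooth_dose_field(15, seed = 100 + s)
    f2 <- smooth_dose_field(15, seed = 200 + s) +
      with_seed(300 + s, matrix(rnorm(225, 0, 1.5), 15, 15))
    ref <- plane_dose_volume(f1); ev <- plane_dose_volume(f2)
    roi <- plane_roi(f1, half_size_mm = 14)
    g <- gamma_index(ref, ev, 2, 1, roi)
    d <- dose_difference(ref, ev, roi)
    expect_gte(g$passing_rate, d$passing_rate)
    expect_true(all(g$gamma >= 0))
  }
})
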