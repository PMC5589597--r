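water_box <- function(n = 41, sp = 2, hu = 0) {
  half <- (n - 1) / 2 * sp
  image_volume(array(hu, c(n, n, n)), rep(sp, 3), rep(-half, 3),
               modality = "CT")
}

test_that("HU to electron density follows the calibration anchors", {
  expect_identical(hu_to_density(-1000), 0)
  expect_identical(hu_to_density(0), 1)
  expect_equal(hu_to_density(1500), 1.85)
  expect_equal(hu_to_density(700), 1 + 700 * 0.85 / 1500)
  expect_equal(hu_to_density(-500), 0.5)
  # clamped outside the anchors
  expect_identical(hu_to_density(-2000), 0)
  expect_equal(hu_to_density(3000), 1.85)
  expect_error(hu_to_density(c(0, NA)), "sentinel")
})

test_that("radiological path is the exact density line integral", {
  # 61^3 voxels of 2 mm: the box spans [-61, 61] mm, so a ray from -50 to
  # +50 mm lies entirely in the medium
  dens <- rtpseudo:::density_volume(water_box(n = 61))  # density 1
  expect_equal(radiological_path(dens, c(0, 0, -50), c(0, 0, 50)), 10,
               tolerance = 1e-9)
  air <- rtpseudo:::density_volume(water_box(n = 61, hu = -1000))
  expect_equal(radiological_path(air, c(0, 0, -50), c(0, 0, 50)), 0)
  # density 0.5 for z >= 1 mm: 50 mm * 1 + 50 mm * 0.5 = 7.5 cm
  half <- dens
  half$data[, , 32:61] <- 0.5
  expect_equal(radiological_path(half, c(0, 0, -49), c(0, 0, 51)), 7.5,
               tolerance = 1e-9)
  # oblique ray: integral equals the diagonal chord through the box
  chord <- radiological_path(dens, c(-100, -100, -100), c(100, 100, 100))
  expect_equal(chord, sqrt(3) * 12.2, tolerance = 1e-6)
  expect_error(radiological_path(dens, c(0, 0, 0), c(0, 0, 0)),
               "degenerate")
})

test_that("beam dose matches its closed form", {
  dens <- rtpseudo:::density_volume(water_box())
  b <- beam_spec(0, 0, c(0, 0, 0), sad_mm = 1000, field_mm = 100,
                 weight = 2, mu_cm = 0.05)
  dose <- compute_beam_dose(dens, b, inverse_square = FALSE,
                            penumbra = FALSE)
  # anterior beam: source at y = -1000; check the isocenter voxel
  wepl <- radiological_path(dens, c(0, -1000, 0), c(0, 0, 0))
  expect_equal(dose$data[21, 21, 21], 2 * exp(-0.05 * wepl),
               tolerance = 1e-9)
  # depth difference between two interior points is exact
  expect_equal(radiological_path(dens, c(0, -1000, 0), c(0, 20, 0)) -
                 radiological_path(dens, c(0, -1000, 0), c(0, -20, 0)),
               4, tolerance = 1e-9)
  # d_eff ~ 0 at the entry surface voxel, r = SAD at the isocenter
  dose_inv <- compute_beam_dose(dens, b, inverse_square = TRUE,
                                penumbra = FALSE)
  expect_equal(dose_inv$data[21, 21, 21], 2 * exp(-0.05 * wepl),
               tolerance = 1e-9)
  # inside the field with the smooth aperture, center is ~ weight at d=0
  dose_pen <- compute_beam_dose(dens, b, inverse_square = FALSE,
                                penumbra = TRUE)
  expect_equal(dose_pen$data[21, 1, 21],
               2 * exp(-0.05 * radiological_path(dens, c(0, -1000, 0),
                                                 c(0, -40, 0))),
               tolerance = 1e-6)
  # monotone decrease with depth along the central axis
  prof <- dose_inv$data[21, , 21]
  expect_true(all(diff(prof) < 0))
})

test_that("bone casts a dose shadow (heterogeneity sensitivity)", {
  water <- water_box()
  boned <- water
  boned$data[, 16:19, ] <- 700         # 8 mm skull-like slab
  b <- beam_spec(0, 0, c(0, 0, 0), field_mm = 100)
  d_water <- compute_beam_dose(rtpseudo:::density_volume(water), b)
  d_bone <- compute_beam_dose(rtpseudo:::density_volume(boned), b)
  # 2 cm behind the slab (y index 30 ~ y = +18 mm): > 1% difference
  behind <- c(21, 30, 21)
  rel <- (d_water$data[21, 30, 21] - d_bone$data[21, 30, 21]) /
    d_water$data[21, 30, 21]
  expect_gt(rel, 0.01)
  # and the shadowed dose is strictly lower everywhere behind the slab
  expect_true(all(d_bone$data[21, 20:41, 21] < d_water$data[21, 20:41, 21]))
})

test_that("plans have 5 beams, one non-coplanar, all avoiding the unscanned region", {
  ph <- small_phantom()
  body <- ph$structures$body
  ptv <- ph$structures$ptv_ord
  plan <- make_plan(ptv, NULL)
  expect_length(plan$beams, 5)
  expect_identical(sum(vapply(plan$beams, function(b) b$couch_deg != 0,
                              logical(1))), 1L)
  # with no unscanned region the configured default angles are untouched
  expect_equal(vapply(plan$beams, `[[`, numeric(1), "gantry_deg"),
               c(40, 115, 245, 320, 90))
  # block the anterior half-space: the anterior-facing beams must rotate
  # away and every returned entry ray must miss the mask
  ys <- grid_points(body)[, 2]
  uns_mask <- mask_like(array(ys < -10, dim(body$data)), body)
  plan2 <- make_plan(ptv, uns_mask)
  for (b in plan2$beams)
    expect_false(rtpseudo:::beam_enters_unscanned(b, uns_mask))
  expect_false(all(vapply(plan2$beams, `[[`, numeric(1), "gantry_deg") ==
                     c(40, 115, 245, 320, 90)))
  # no admissible geometry at all
  all_mask <- mask_like(array(TRUE, dim(body$data)), body)
  expect_error(make_plan(ptv, all_mask), "planning error")
  expect_error(make_plan(mask_like(array(FALSE, dim(body$data)), body),
                         NULL), "empty PTV")
})

test_that("plan dose normalization meets the coverage criterion", {
  st <- small_plan_fixture()
  dptv <- st$res$dose$data[st$ptv$data > 0]
  n <- length(dptv)
  # D95 = 100 exactly (to numerical precision)
  expect_equal(rtpseudo:::d95_level(dptv), 100, tolerance = 1e-9)
  # V100 = the smallest fraction >= 95% that the voxel grid can express
  m <- plan_metrics(st$res$dose, st$ptv)
  expect_equal(m$v100, 100 * ceiling(0.95 * n) / n, tolerance = 1e-9)
  expect_lt(abs(m$v100 - 95), 100 / n + 1e-9)
  # maximum PTV dose respects the 110% planning ceiling
  expect_lte(m$d_max, 110 + 0.5)
  # scaling all starting weights leaves the normalized dose unchanged
  plan2 <- st$plan
  plan2$weights <- rep(2, 5)
  res2 <- compute_plan_dose(st$sc, plan2, st$ptv)
  expect_equal(res2$dose$data, st$res$dose$data, tolerance = 1e-12)
  # determinism
  res3 <- compute_plan_dose(st$sc, st$plan, st$ptv)
  expect_identical(res3$dose$data, st$res$dose$data)
  # dose grid is physical: non-negative and finite
  expect_true(all(is.finite(st$res$dose$data)))
  expect_true(all(st$res$dose$data >= 0))
})

test_that("frozen recomputation uses stored weights and normalization", {
  st <- small_plan_fixture()
  same <- recompute_plan_dose(st$sc, st$res$plan)
  expect_equal(same$data, st$res$dose$data, tolerance = 1e-12)
  # denser medium, frozen plan: dose drops, no re-normalization happens
  denser <- st$sc
  denser$data <- denser$data + 80
  lower <- recompute_plan_dose(denser, st$res$plan)
  expect_lt(mean(lower$data[st$ptv$data > 0]),
            mean(st$res$dose$data[st$ptv$data > 0]))
  expect_error(recompute_plan_dose(st$sc, make_plan(st$ptv, NULL)),
               "normalized")
})
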