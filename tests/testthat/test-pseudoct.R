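test_that("outer-body correction applies the excess/deficiency rules exactly", {
  t <- toy_correction_inputs()
  res <- correct_outer_body(t$vol, t$dct, t$ref, t$uns)
  p <- res$pseudo_ct$data
  in_dct <- t$dct$data > 0; in_ref <- t$ref$data > 0; uns <- t$uns$data > 0
  # tissue excess (in diagnostic body, outside reference) -> air HU
  expect_true(all(p[in_dct & !in_ref] == -1000))
  # tissue deficiency (in reference body, outside diagnostic) -> 0 HU
  expect_true(all(p[in_ref & !in_dct & !uns] == 0))
  # unscanned tissue inside the reference body -> 0 HU
  expect_true(all(p[in_ref & uns] == 0))
  # inside both bodies and scanned: copied unchanged
  keep <- in_dct & in_ref & !uns
  expect_identical(p[keep], t$vol$data[keep])
  expect_true(all(p[keep] == 60))
  # outside both: sentinel replaced by air, scanned air copied
  expect_true(all(p[!in_dct & !in_ref & is.na(t$vol$data)] == -1000))
  expect_true(all(p[!in_dct & !in_ref & !is.na(t$vol$data) & !uns] == 30))
  # no sentinel survives
  expect_false(anyNA(p))
})

test_that("correction report counts partition the grid", {
  t <- toy_correction_inputs()
  res <- correct_outer_body(t$vol, t$dct, t$ref, t$uns)
  r <- res$report
  expect_identical(r$excess + r$deficient + r$unscanned_deficient +
                     r$unchanged, r$total)
  expect_identical(r$total, length(t$vol$data))
  # brute-force recount of each class
  in_dct <- t$dct$data > 0; in_ref <- t$ref$data > 0; uns <- t$uns$data > 0
  expect_identical(r$excess, sum(in_dct & !in_ref))
  expect_identical(r$unscanned_deficient, sum(in_ref & uns))
  expect_identical(r$deficient, sum(in_ref & !in_dct & !uns))
  expect_equal(r$excess_cc, r$excess * voxel_volume_cc(t$vol))
})

test_that("outer-body correction is idempotent", {
  t <- toy_correction_inputs()
  once <- correct_outer_body(t$vol, t$dct, t$ref, t$uns)
  twice <- correct_outer_body(once$pseudo_ct, t$dct, t$ref, t$uns)
  expect_identical(twice$pseudo_ct$data, once$pseudo_ct$data)
})

test_that("correction validates grid compatibility", {
  t <- toy_correction_inputs()
  bad <- t$ref
  bad$origin <- bad$origin + 1
  expect_error(correct_outer_body(t$vol, t$dct, bad, t$uns), "grid")
})

test_that("body contouring finds the head and fills cavities", {
  expect_error(contour_body(image_volume(array(-1000, c(8, 8, 8)))),
               "no body")
  ph <- small_phantom()
  body <- contour_body(ph$ct)
  # agreement with the generator truth except a thin surface band
  expect_lt(mask_band_distance(body, ph$structures$body),
            2 * max(ph$ct$spacing))
  expect_gt(sum(body$data & ph$structures$body$data) /
              sum(ph$structures$body$data), 0.98)
  # an internal air pocket (sinus) is swallowed by hole filling
  ct2 <- ph$ct
  ct2$data[40:46, 20:26, 30:36] <- -1000
  body2 <- contour_body(ct2)
  expect_true(all(body2$data[41:45, 21:25, 31:35] == 1))
})

test_that("unscanned detection is exactly the sentinel set", {
  ph <- small_phantom()
  full <- simulate_scan(ph$ct, scan_geometry(0, 2.5, 2, 0))
  onref <- resample_to_grid(full, rigid_transform(), full)
  expect_identical(sum(detect_unscanned(onref)$data), 0)
  cut <- simulate_scan(ph$ct, scan_geometry(0, 2.5, 2, 25))
  big <- resample_to_grid(cut, rigid_transform(), full)
  uns <- detect_unscanned(big)
  expect_identical(sum(uns$data > 0), sum(is.na(big$data)))
  expect_true(all(is.na(big$data[uns$data > 0])))
  expect_false(anyNA(big$data[uns$data == 0]))
  # confined to the inferior slices
  zs <- apply(uns$data > 0, 3, any)
  expect_true(all(which(zs) < which.max(!zs + 0) + sum(zs)))
  expect_true(zs[1])
  expect_false(zs[length(zs)])
})

test_that("a degenerate pipeline (all scans identical) is a no-op", {
  ph <- small_phantom()
  sc <- simulate_scan(ph$ct, scan_geometry(0, 2.5, 2, 0))
  px <- generate_pseudo_ct(sc, sc, sc)
  expect_identical(px$report$excess, 0L)
  expect_identical(px$report$deficient, 0L)
  expect_identical(px$report$unscanned_deficient, 0L)
  expect_identical(px$pseudo_ct$data, sc$data)
})

test_that("the pseudo-CT adopts the reference outer body shape", {
  st <- default_stage()
  body_pseudo <- contour_body(st$px$pseudo_ct)
  expect_lt(mask_band_distance(body_pseudo, st$px$ref_body),
            max(st$px$pseudo_ct$spacing) + 1e-9)
  # interior preservation: scanned voxels inside both bodies are exactly
  # the aligned diagnostic values
  keep <- st$px$dct_body$data > 0 & st$px$ref_body$data > 0 &
    st$px$unscanned$data == 0
  expect_identical(st$px$pseudo_ct$data[keep],
                   st$px$dct_aligned$data[keep])
  # +2 mm scalp change: reported excess within 20% of the analytic
  # ellipsoid shell volume of the dilation
  a <- phantom_spec()$head_semiaxes_mm
  shell_cc <- 4 * pi / 3 * (prod(a + 2) - prod(a)) / 1000
  expect_lt(abs(st$px$report$excess_cc - shell_cc) / shell_cc, 0.2)
})

test_that("MRI-only mode references the body to the planning MR", {
  ph <- small_phantom()
  pmr <- simulate_scan(ph$mr, scan_geometry(0, 2.5, 2, 0))
  dct <- simulate_scan(ph$ct, scan_geometry(6, 4, 1.6, 12),
                       pose = rigid_transform(euler_rotation(rz = 3),
                                              c(3, -2, 1)))
  px <- generate_pseudo_ct(dct, NULL, pmr, list(mode = "mri_only"))
  # reference grid is the PMR grid itself
  expect_identical(px$reference$origin, pmr$origin)
  expect_identical(px$reference$direction, pmr$direction)
  # the corrected scan matches the MR-derived body up to a thin band
  body_pseudo <- contour_body(px$pseudo_ct)
  expect_lt(mask_band_distance(body_pseudo, px$ref_body),
            2 * max(pmr$spacing))
  expect_false(anyNA(px$pseudo_ct$data))
})
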