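test_that("phantom generation is seed-deterministic and anatomically ordered", {
  ph1 <- small_phantom()
  ph2 <- generate_head_phantom(small_spec())
  expect_identical(ph1$ct$data, ph2$ct$data)
  expect_identical(ph1$mr$data, ph2$mr$data)
  expect_identical(ph1$labels$data, ph2$labels$data)
  # different seed, different noise
  ph3 <- generate_head_phantom(small_spec(seed = 6))
  expect_false(identical(ph1$ct$data, ph3$ct$data))

  s <- ph1$structures
  # CT: bone bright, CSF dark; MR: the reverse
  expect_gt(mean(ph1$ct$data[s$skull$data > 0]),
            mean(ph1$ct$data[s$ventricle$data > 0]))
  expect_gt(mean(ph1$mr$data[s$ventricle$data > 0]),
            mean(ph1$mr$data[s$skull$data > 0]))
  # outside the body: air HU plus noise only
  outside <- s$body$data == 0
  spec <- small_spec()
  expect_equal(mean(ph1$ct$data[outside]), -1000,
               tolerance = 0.05 * spec$noise_sd_hu)
  expect_equal(sd(ph1$ct$data[outside]), spec$noise_sd_hu, tolerance = 0.3)
  # the three PTVs exist, are inside the body, and sit where advertised
  for (nm in c("ptv_ord", "ptv_vent", "ptv_skull")) {
    expect_gt(sum(s[[nm]]$data), 100)
    expect_true(all(s$body$data[s[[nm]]$data > 0] > 0))
  }
  # ptv_vent abuts the ventricle, ptv_skull abuts the skull
  dims <- dim(s$body$data)
  d_vent <- rtpseudo:::distance_to(s$ventricle$data > 0, dims,
                                   ph1$labels$spacing)
  expect_lt(min(d_vent[s$ptv_vent$data > 0]), 2 * spec$truth_spacing_mm)
  d_skull <- rtpseudo:::distance_to(s$skull$data > 0, dims,
                                    ph1$labels$spacing)
  expect_lt(min(d_skull[s$ptv_skull$data > 0]), 2 * spec$truth_spacing_mm)
})

test_that("impossible phantom geometry is rejected", {
  expect_error(phantom_spec(head_semiaxes_mm = c(20, 20, 20),
                            scalp_thickness_mm = 8,
                            skull_thickness_mm = 8),
               "impossible")
  expect_error(phantom_spec(scalp_thickness_mm = -1), "positive")
  expect_error(phantom_spec(hu = c(air = -1000)), "cover")
})

test_that("inter-scan change moves only the outer scalp surface", {
  ph <- small_phantom()
  expect_identical(apply_interscan_change(ph$labels, 0)$data,
                   ph$labels$data)
  l2 <- apply_interscan_change(ph$labels, 2)
  # body grows, interior tissue untouched voxel-for-voxel
  expect_gt(sum(l2$data > 0), sum(ph$labels$data > 0))
  interior <- ph$labels$data >= 2  # skull, brain, ventricle
  expect_identical(l2$data[interior], ph$labels$data[interior])
  l1 <- apply_interscan_change(ph$labels, -2)
  expect_lt(sum(l1$data > 0), sum(ph$labels$data > 0))
  expect_identical(l1$data[interior], ph$labels$data[interior])
  # dilation then matching erosion of the convex head is near-identity
  l3 <- apply_interscan_change(l2, -2)
  n0 <- sum(ph$labels$data > 0)
  expect_lt(abs(sum(l3$data > 0) - n0) / n0, 0.02)
  # eroding beyond the scalp shell must fail, not silently eat skull
  expect_error(apply_interscan_change(ph$labels, -6), "scalp")
})

test_that("scan simulation reproduces geometry and preserves tissue means", {
  ph <- small_phantom()
  spec <- small_spec()
  # same spacing, no tilt: identity resample, bit-exact
  sc0 <- simulate_scan(ph$ct, scan_geometry(0, spec$truth_spacing_mm,
                                            spec$truth_spacing_mm, 0))
  expect_identical(dim(sc0$data), dim(ph$ct$data))
  expect_identical(sc0$data, ph$ct$data)
  # tilt encoded exactly in the direction matrix
  sc15 <- simulate_scan(ph$ct, scan_geometry(15, 2.5, 1.5, 0))
  expect_lt(max(abs(sc15$direction - euler_rotation(rx = 15))), 1e-6)
  # inferior cutoff: scan starts above the inferior-most tissue
  cut <- 20
  scc <- simulate_scan(ph$ct, scan_geometry(0, 2.5, 1.5, cut))
  body_zmin <- min(grid_points(ph$labels)[ph$labels$data > 0, 3])
  expect_equal(scc$origin[3], body_zmin + cut, tolerance = 2.5)
  expect_error(simulate_scan(ph$ct, scan_geometry(0, 2.5, 1.5, 500)),
               "cutoff")
  # anti-aliasing: interior tissue means preserved within 2 HU up to 5 mm
  for (thick in c(2.5, 5)) {
    sc <- simulate_scan(ph$ct, scan_geometry(0, thick, 1.5, 0))
    for (nm in c("ventricle", "body")) {
      truth_mean <- if (nm == "ventricle")
        mean(ph$ct$data[ph$structures[[nm]]$data > 0])
      else mean(ph$ct$data[ph$labels$data == 3])   # brain
      msk <- if (nm == "ventricle") ph$structures$ventricle else
        mask_like(ph$labels$data == 3, ph$labels)
      m <- resample_to_grid(msk, rigid_transform(), sc)
      dint <- rtpseudo:::distance_to(!(m$data > 0), dim(m$data), m$spacing)
      interior <- m$data > 0 & dint > max(sc$spacing)
      expect_gt(sum(interior), 50)
      expect_lt(abs(mean(sc$data[interior]) - truth_mean), 2)
    }
  }
})

test_that("diagnostic tilt is drawn from the 0 to 23.3 degree range", {
  tilts <- vapply(1:25, function(s) {
    cfg <- experiment_config(seed = s)
    rtpseudo:::draw_acquisition(cfg)$tilt
  }, numeric(1))
  expect_true(all(tilts >= 0 & tilts <= 23.3))
  expect_gt(diff(range(tilts)), 10)  # the range is actually explored
  # pinning the tilt bypasses the draw
  cfg <- experiment_config(seed = 1, dct_tilt_deg = 7)
  expect_equal(rtpseudo:::draw_acquisition(cfg)$tilt, 7)
})
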