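# Shared fixtures.  Everything is generated in code; the heavier objects
# are built lazily once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small head for fast unit tests (not the study conditions; those are the
# phantom_spec() defaults used in the acceptance suite)
small_spec <- function(seed = 5L, noise_sd_hu = 8, noise_sd_mr = 15) {
  phantom_spec(head_semiaxes_mm = c(50, 60, 56),
               scalp_thickness_mm = 5, skull_thickness_mm = 6,
               ventricle_center_mm = c(0, 0, 6),
               ventricle_semiaxes_mm = c(11, 14, 10),
               noise_sd_hu = noise_sd_hu, noise_sd_mr = noise_sd_mr,
               truth_spacing_mm = 1.5, margin_mm = 9,
               ptv_radius_mm = 10, seed = seed)
}

small_phantom <- function() {
  cache_fixture("small_phantom", function() {
    generate_head_phantom(small_spec())
  })
}

small_pct <- function() {
  cache_fixture("small_pct", function() {
    simulate_scan(small_phantom()$ct, scan_geometry(0, 1.5, 1.5, 0))
  })
}

small_experiment_config <- function(seed = 5L, ...) {
  experiment_config(seed = seed, phantom = small_spec(seed),
                    dct_geom = scan_geometry(0, 4, 1.6, 12),
                    pct_geom = scan_geometry(0, 1.6, 1.6, 0),
                    pmr_geom = scan_geometry(0, 2.5, 2, 0),
                    delta_scalp_mm = 2, dct_tilt_deg = 8,
                    dct_pose_rot_max_deg = 3, dct_pose_trans_max_mm = 5,
                    ...)
}

# study-condition fixtures for the acceptance suite -------------------------

default_phantom <- function() {
  cache_fixture("default_phantom", function() {
    generate_head_phantom(phantom_spec(seed = 1L))
  })
}

default_pct <- function() {
  cache_fixture("default_pct", function() {
    simulate_scan(default_phantom()$ct, scan_geometry(0, 1.25, 1.2, 0))
  })
}

# phantom -> scans -> pseudo-CT under the default study conditions
default_stage <- function() {
  cache_fixture("default_stage", function() {
    ph <- default_phantom()
    spec <- phantom_spec(seed = 1L)
    lab_dct <- apply_interscan_change(ph$labels, 2)
    noise <- rtpseudo:::phantom_noise(spec, dim(ph$labels$data))
    ct_dct <- ph$ct
    ct_dct$data <- rtpseudo:::voxelize_tissue(lab_dct$data, spec$hu) +
      spec$noise_sd_hu * noise$ct
    pose <- rigid_transform(euler_rotation(3, -2, 4), c(5, -6, 3))
    dct <- simulate_scan(ct_dct, scan_geometry(12, 5, 1.2, 25),
                         pose = pose)
    pmr <- simulate_scan(ph$mr, scan_geometry(0, 2.5, 1.5, 0))
    px <- generate_pseudo_ct(dct, default_pct(), pmr)
    ptv <- resample_to_grid(ph$structures$ptv_ord, rigid_transform(),
                            px$reference)
    list(phantom = ph, dct = dct, pct = default_pct(), pmr = pmr,
         px = px, ptv = ptv, pose = pose)
  })
}

# a normalized 5-beam plan on the small phantom
small_plan_fixture <- function() {
  cache_fixture("small_plan", function() {
    ph <- small_phantom()
    sc <- simulate_scan(ph$ct, scan_geometry(0, 2.5, 2, 0))
    ptv <- resample_to_grid(ph$structures$ptv_ord, rigid_transform(), sc)
    plan <- make_plan(ptv, NULL)
    res <- compute_plan_dose(sc, plan, ptv)
    list(sc = sc, ptv = ptv, plan = plan, res = res)
  })
}

# toy grid with every voxel class the correction scheme must handle
toy_correction_inputs <- function() {
  d <- c(6, 6, 6)
  hu <- array(30, d)
  geom <- function(a) binary_mask(array(a, d), c(2, 2, 2))
  dct <- array(0, d); ref <- array(0, d); uns <- array(0, d)
  dct[2:5, 2:5, 2:5] <- 1              # diagnostic body
  ref[3:6, 2:5, 2:5] <- 1              # reference body, shifted in x
  uns[, , 5:6] <- 1                    # top slabs unscanned (cut into ref)
  hu[2:5, 2:5, 2:5] <- 60              # tissue in the diagnostic body
  hu[1, 1, ] <- NA                     # sentinel outside both bodies
  hu[, , 5:6][uns[, , 5:6] > 0] <- NA  # unscanned voxels are sentinel
  vol <- image_volume(hu, c(2, 2, 2), modality = "CT")
  list(vol = vol, dct = geom(dct), ref = geom(ref), uns = geom(uns))
}

# dose-plane helpers --------------------------------------------------------

# wrap a 2D dose matrix into a 3-slice volume so coronal extraction at the
# middle slice returns exactly `mat`
plane_dose_volume <- function(mat, spacing = c(2, 1, 2)) {
  a <- array(0, c(nrow(mat), 3, ncol(mat)))
  for (j in 1:3) a[, j, ] <- mat
  image_volume(a, spacing, c(0, 0, 0), diag(3), "DOSE")
}

plane_roi <- function(mat, spacing = c(2, 1, 2), half_size_mm = 20) {
  list(axis = "coronal",
       center_mm = c((nrow(mat) - 1) / 2 * spacing[1], spacing[2],
                     (ncol(mat) - 1) / 2 * spacing[3]),
       half_size_mm = half_size_mm)
}

smooth_dose_field <- function(n = 21, seed = 1) {
  with_seed(seed, {
    x <- seq(-1, 1, length.out = n)
    f <- outer(x, x, function(u, v)
      100 - 10 * u^2 - 8 * v^2 + 3 * u * v + 2 * sin(3 * u))
    f + matrix(rnorm(n * n, 0, 0.25), n, n)
  })
}

# independent brute-force gamma oracle: per-pixel search over an explicit
# offset list with its own bilinear interpolator (vectorized over offsets,
# scalar over pixels)
gamma_oracle <- function(reference, evaluated, dose_crit, dist_crit, roi) {
  rp <- rtpseudo:::extract_plane(reference, roi$axis, roi$center_mm,
                                 roi$half_size_mm)
  ep <- rtpseudo:::extract_plane(evaluated, roi$axis, roi$center_mm,
                                 roi$half_size_mm + 3 * dist_crit + 1)
  step <- dist_crit / 10
  m <- floor(3 * dist_crit / step)
  offs <- expand.grid(du = step * (-m:m), dv = step * (-m:m))
  offs <- offs[offs$du^2 + offs$dv^2 <= (3 * dist_crit)^2 + 1e-12, ]
  nu <- length(ep$u); nv <- length(ep$v)
  out <- matrix(NA_real_, length(rp$u), length(rp$v))
  for (i in seq_along(rp$u)) {
    for (j in seq_along(rp$v)) {
      iu <- (rp$u[i] + offs$du - ep$u[1]) / ep$spacing[1]
      iv <- (rp$v[j] + offs$dv - ep$v[1]) / ep$spacing[2]
      ok <- iu >= 0 & iu <= nu - 1 & iv >= 0 & iv <= nv - 1
      i0 <- pmin(floor(iu[ok]), nu - 2); j0 <- pmin(floor(iv[ok]), nv - 2)
      fu <- iu[ok] - i0; fv <- iv[ok] - j0
      ev <- (1 - fu) * (1 - fv) * ep$values[cbind(i0 + 1, j0 + 1)] +
            fu * (1 - fv) * ep$values[cbind(i0 + 2, j0 + 1)] +
            (1 - fu) * fv * ep$values[cbind(i0 + 1, j0 + 2)] +
            fu * fv * ep$values[cbind(i0 + 2, j0 + 2)]
      cand <- (ev - rp$values[i, j])^2 / dose_crit^2 +
        (offs$du[ok]^2 + offs$dv[ok]^2) / dist_crit^2
      out[i, j] <- sqrt(min(cand))
    }
  }
  out
}

# rotation / translation error between two rigid transforms, measured as
# the residual rotation angle and the displacement of a reference point
transform_error <- function(recovered, truth, point = c(0, 0, 0)) {
  rot <- rtpseudo:::rotation_angle_deg(t(recovered$rotation) %*%
                                         truth$rotation)
  tra <- sqrt(sum((apply_transform(recovered, point) -
                     apply_transform(truth, point))^2))
  c(rotation_deg = rot, translation_mm = tra)
}

# largest distance (mm) of any disagreeing voxel from the reference mask's
# boundary; 0 when the masks agree everywhere
mask_band_distance <- function(mask, reference) {
  dis <- (mask$data > 0) != (reference$data > 0)
  if (!any(dis)) return(0)
  dims <- dim(reference$data)
  d_out <- rtpseudo:::distance_to(reference$data > 0, dims,
                                  reference$spacing)
  d_in <- rtpseudo:::distance_to(!(reference$data > 0), dims,
                                 reference$spacing)
  band <- pmax(d_out, d_in)   # distance to the opposite phase ~ boundary
  max(band[dis])
}
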