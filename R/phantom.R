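# Digital head phantom: seeded generator of paired diagnostic/planning
# scans with the acquisition differences the pseudo-CT method must
# correct (gantry tilt, thick slices, limited inferior extent, and an
# outer-body change between imaging sessions).

PHANTOM_LABELS <- c(air = 0L, scalp = 1L, skull = 2L, brain = 3L,
                    ventricle = 4L)

#' Head phantom specification
#'
#' Nested ellipsoidal anatomy (scalp shell, skull shell, brain, a CSF
#' ventricle) on an isotropic "truth" grid, with per-tissue CT numbers and
#' MR intensities plus Gaussian scanner noise.  Tissue HU are standard
#' textbook magnitudes (air -1000, soft tissue tens of HU, compact bone
#' several hundred HU); MR intensities are arbitrary units chosen so that
#' CSF is bright and bone dark, the reverse of their CT contrast.
#'
#' @param head_semiaxes_mm outer scalp ellipsoid semi-axes (x = left-right,
#'   y = posterior, z = superior), mm.
#' @param scalp_thickness_mm,skull_thickness_mm shell thicknesses, mm.
#' @param ventricle_center_mm,ventricle_semiaxes_mm CSF ventricle
#'   ellipsoid, mm (center relative to head center).
#' @param hu named HU table covering air, scalp, skull, brain, ventricle.
#' @param mr named MR intensity table over the same labels.
#' @param noise_sd_hu,noise_sd_mr Gaussian noise sigma in HU / MR units.
#' @param truth_spacing_mm isotropic grid step of the underlying anatomy
#'   volume, mm.
#' @param margin_mm air margin around the head, mm.
#' @param ptv_radius_mm radius of the three spherical planning target
#'   volumes, mm.
#' @param seed integer; fully determines the generated volumes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(head_semiaxes_mm = c(75, 92, 88),
                         scalp_thickness_mm = 6,
                         skull_thickness_mm = 7,
                         ventricle_center_mm = c(0, 0, 10),
                         ventricle_semiaxes_mm = c(16, 20, 14),
                         hu = c(air = -1000, scalp = 40, skull = 700,
                                brain = 30, ventricle = 10),
                         mr = c(air = 20, scalp = 450, skull = 120,
                                brain = 600, ventricle = 900),
                         noise_sd_hu = 8,
                         noise_sd_mr = 15,
                         truth_spacing_mm = 1.25,
                         margin_mm = 12,
                         ptv_radius_mm = 13.5,
                         seed = 1L) {
  spec <- list(head_semiaxes_mm = as.numeric(head_semiaxes_mm),
               scalp_thickness_mm = as.numeric(scalp_thickness_mm),
               skull_thickness_mm = as.numeric(skull_thickness_mm),
               ventricle_center_mm = as.numeric(ventricle_center_mm),
               ventricle_semiaxes_mm = as.numeric(ventricle_semiaxes_mm),
               hu = hu, mr = mr,
               noise_sd_hu = as.numeric(noise_sd_hu),
               noise_sd_mr = as.numeric(noise_sd_mr),
               truth_spacing_mm = as.numeric(truth_spacing_mm),
               margin_mm = as.numeric(margin_mm),
               ptv_radius_mm = as.numeric(ptv_radius_mm),
               seed = as.integer(seed))
  needed <- names(PHANTOM_LABELS)
  if (!all(needed %in% names(spec$hu)) || !all(needed %in% names(spec$mr)))
    stop("hu/mr tables must cover labels: ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (spec$scalp_thickness_mm <= 0 || spec$skull_thickness_mm <= 0)
    stop("shell thicknesses must be positive", call. = FALSE)
  if (any(spec$head_semiaxes_mm -
          spec$scalp_thickness_mm - spec$skull_thickness_mm <= 10))
    stop("geometrically impossible spec: shells leave no brain",
         call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

# squared normalized ellipsoid coordinate for point grids
ellipsoid_q <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2
}

#' Generate the head phantom
#'
#' Builds the label volume, noisy CT and MR volumes, and structure masks
#' (body, skull, ventricle, and three spherical PTVs: a deep-brain site,
#' one abutting the ventricle, one abutting the inner skull surface) on the
#' truth grid centered on the head.
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (integer [image_volume()] of tissue codes),
#'   `ct`, `mr` ([image_volume()]s) and `structures` (named list of
#'   [binary_mask()]: body, skull, ventricle, ptv_ord, ptv_vent,
#'   ptv_skull).
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- spec$head_semiaxes_mm + spec$margin_mm
  sp <- spec$truth_spacing_mm
  nx <- 2L * ceiling(ext[1] / sp) + 1L
  ny <- 2L * ceiling(ext[2] / sp) + 1L
  nz <- 2L * ceiling(ext[3] / sp) + 1L
  origin <- -sp * c((nx - 1) / 2, (ny - 1) / 2, (nz - 1) / 2)
  x <- origin[1] + sp * (seq_len(nx) - 1)
  y <- origin[2] + sp * (seq_len(ny) - 1)
  z <- origin[3] + sp * (seq_len(nz) - 1)
  X <- array(rep.int(x, ny * nz), c(nx, ny, nz))
  Y <- array(rep.int(rep(y, each = nx), nz), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))

  labels <- label_anatomy(spec, X, Y, Z)
  geom <- list(spacing = rep(sp, 3), origin = origin, direction = diag(3))

  noise <- phantom_noise(spec, dim(labels))
  ct <- image_volume(voxelize_tissue(labels, spec$hu) +
                       spec$noise_sd_hu * noise$ct,
                     geom$spacing, geom$origin, geom$direction, "CT")
  mr <- image_volume(voxelize_tissue(labels, spec$mr) +
                       spec$noise_sd_mr * noise$mr,
                     geom$spacing, geom$origin, geom$direction, "MR")

  lab_vol <- image_volume(labels * 1.0, geom$spacing, geom$origin,
                          geom$direction, "MASK")
  structures <- phantom_structures(spec, lab_vol, X, Y, Z)
  list(labels = lab_vol, ct = ct, mr = mr, structures = structures)
}

# tissue labels from the analytic ellipsoid model
label_anatomy <- function(spec, X, Y, Z) {
  a <- spec$head_semiaxes_mm
  a_skull <- a - spec$scalp_thickness_mm
  a_brain <- a_skull - spec$skull_thickness_mm
  lab <- array(PHANTOM_LABELS[["air"]], dim = dim(X))
  q_head <- ellipsoid_q(X, Y, Z, c(0, 0, 0), a)
  q_skull <- ellipsoid_q(X, Y, Z, c(0, 0, 0), a_skull)
  q_brain <- ellipsoid_q(X, Y, Z, c(0, 0, 0), a_brain)
  q_vent <- ellipsoid_q(X, Y, Z, spec$ventricle_center_mm,
                        spec$ventricle_semiaxes_mm)
  lab[q_head <= 1] <- PHANTOM_LABELS[["scalp"]]
  lab[q_skull <= 1] <- PHANTOM_LABELS[["skull"]]
  lab[q_brain <= 1] <- PHANTOM_LABELS[["brain"]]
  lab[q_vent <= 1 & q_brain <= 1] <- PHANTOM_LABELS[["ventricle"]]
  lab
}

voxelize_tissue <- function(labels, table) {
  vals <- table[names(PHANTOM_LABELS)]
  array(vals[labels + 1L], dim = dim(labels))
}

phantom_noise <- function(spec, dims) {
  with_seed(spec$seed, {
    list(ct = array(rnorm(prod(dims)), dims),
         mr = array(rnorm(prod(dims)), dims))
  })
}

phantom_structures <- function(spec, lab_vol, X, Y, Z) {
  labels <- lab_vol$data
  g <- function(l) mask_like(l, lab_vol)
  a_brain <- spec$head_semiaxes_mm - spec$scalp_thickness_mm -
    spec$skull_thickness_mm
  r <- spec$ptv_radius_mm
  # deep-brain target: fixed parasagittal site
  c_ord <- c(25, 10, 20)
  # target abutting the ventricle: sphere tangent to its +y pole
  vc <- spec$ventricle_center_mm
  c_vent <- vc + c(0, spec$ventricle_semiaxes_mm[2] + r, 0)
  # target abutting the inner skull: tangent along +x at z = 12
  z0 <- 12
  x_inner <- a_brain[1] * sqrt(max(0, 1 - (z0 / a_brain[3])^2))
  c_skull <- c(x_inner - r, 0, z0)
  sphere <- function(cc) {
    (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= r^2
  }
  list(body = g(labels > 0),
       skull = g(labels == PHANTOM_LABELS[["skull"]]),
       ventricle = g(labels == PHANTOM_LABELS[["ventricle"]]),
       ptv_ord = g(sphere(c_ord)),
       ptv_vent = g(sphere(c_vent)),
       ptv_skull = g(sphere(c_skull)))
}

#' Apply an inter-scan outer-body change to a label volume
#'
#' Dilates (`delta > 0`) or erodes (`delta < 0`) the outer body surface by
#' `|delta|` mm via a Euclidean distance transform, leaving every voxel at
#' or inside the skull untouched; emulates weight change / positioning pads
#' between the diagnostic and planning imaging sessions, confined to the
#' outer scalp.
#'
#' @param labels label [image_volume()] from [generate_head_phantom()].
#' @param delta_scalp_mm signed change of the scalp surface, mm; erosion
#'   must stay within the scalp.
#' @return modified label volume.
#' @export
apply_interscan_change <- function(labels, delta_scalp_mm) {
  if (delta_scalp_mm == 0) return(labels)
  lab <- labels$data
  dims <- dim(lab)
  body <- lab > 0
  # the EDT measures distance to the nearest voxel *center*, which sits on
  # average half a voxel inside the true surface; offset the threshold by
  # half the grid step so the morphological change is |delta| mm of actual
  # surface motion
  eff <- abs(delta_scalp_mm) + mean(labels$spacing) / 2
  if (delta_scalp_mm > 0) {
    dist_to_body <- distance_to(body, dims, labels$spacing)
    add <- !body & dist_to_body <= eff
    lab[add] <- PHANTOM_LABELS[["scalp"]]
  } else {
    dist_to_air <- distance_to(!body, dims, labels$spacing)
    remove <- body & dist_to_air <= eff
    if (any(lab[remove] != PHANTOM_LABELS[["scalp"]]))
      stop("erosion deeper than the scalp shell", call. = FALSE)
    lab[remove] <- PHANTOM_LABELS[["air"]]
  }
  out <- labels
  out$data <- lab
  out
}

#' Scan acquisition geometry
#'
#' @param tilt_deg gantry tilt about the left-right (x) axis, degrees,
#'   within +-30.
#' @param slice_thickness_mm slice spacing along the (tilted) slice normal.
#' @param inplane_spacing_mm in-plane pixel spacing, mm.
#' @param inferior_cutoff_mm scan extent removed from the inferior end of
#'   the coverage (0 = full coverage); emulates a diagnostic scan that
#'   stops above the skull base.
#' @return a `scan_geometry` list.
#' @export
scan_geometry <- function(tilt_deg = 0, slice_thickness_mm = 2.5,
                          inplane_spacing_mm = 1.5,
                          inferior_cutoff_mm = 0) {
  if (slice_thickness_mm <= 0 || inplane_spacing_mm <= 0)
    stop("spacings must be positive", call. = FALSE)
  if (abs(tilt_deg) > 30)
    stop("tilt must lie within +-30 degrees", call. = FALSE)
  structure(list(tilt_deg = as.numeric(tilt_deg),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 inplane_spacing_mm = as.numeric(inplane_spacing_mm),
                 inferior_cutoff_mm = as.numeric(inferior_cutoff_mm)),
            class = "scan_geometry")
}

#' Simulate a scanner acquisition of a truth volume
#'
#' Resamples the truth volume onto a grid whose slice normal is tilted by
#' `geom$tilt_deg` about the left-right axis and whose slice spacing is the
#' slice thickness; thick slices are box-averaged along the slice normal
#' (finite slice sensitivity), in-plane sampling is trilinear.  Slices
#' inferior to the cutoff are absent from the output.  The returned
#' direction matrix encodes the tilt.
#'
#' An optional `pose` (a [rigid_transform()]) models a patient set-up
#' difference: the scan voxel stored at position `x` images the anatomy at
#' `pose(x)`, and the scanner frame does not record it.  The true mapping
#' from this scan's space into the space of an untilted reference scan of
#' the same anatomy is therefore `pose` itself, which is what a
#' registration must recover.
#'
#' @param vol truth [image_volume()] (CT or MR).
#' @param geom a [scan_geometry()].
#' @param pose optional set-up mismatch transform (default identity).
#' @return [image_volume()] of the simulated scan (no sentinel voxels;
#'   outside the truth grid CT reads air, MR reads 0).
#' @export
simulate_scan <- function(vol, geom, pose = rigid_transform()) {
  stopifnot(inherits(geom, "scan_geometry"))
  Rt <- euler_rotation(rx = geom$tilt_deg)
  # bounding box of the truth volume in the tilted frame
  d <- dim(vol$data)
  corners_idx <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                       c(0, d[3] - 1)))
  corners <- index_to_physical(vol, corners_idx) %*% Rt  # = t(Rt) %*% x
  lo <- apply(corners, 2, min)
  hi <- apply(corners, 2, max)
  sp <- c(geom$inplane_spacing_mm, geom$inplane_spacing_mm,
          geom$slice_thickness_mm)
  if (geom$inferior_cutoff_mm > 0) {
    # the cutoff is anatomical: the scan starts `cutoff` mm above the
    # inferior-most tissue, not above the (air-padded) volume edge
    thr <- if (vol$modality == "CT") -400 else
      0.1 * max(vol$data, na.rm = TRUE)
    on <- which(vol$data > thr)
    if (length(on)) {
      d3 <- dim(vol$data)
      idx <- cbind((on - 1) %% d3[1],
                   ((on - 1) %/% d3[1]) %% d3[2],
                   (on - 1) %/% (d3[1] * d3[2]))
      body_lo <- min((index_to_physical(vol, idx) %*% Rt)[, 3])
      lo[3] <- max(lo[3], body_lo) + geom$inferior_cutoff_mm
    }
  }
  n <- pmax(1L, floor((hi - lo) / sp) + 1L)
  if (n[3] < 3)
    stop("inferior cutoff removes (nearly) the whole scan extent",
         call. = FALSE)
  origin <- as.numeric(Rt %*% lo)
  out_geom <- image_volume(array(0, n), sp, origin, Rt, vol$modality)
  pts <- grid_points(out_geom)
  pts <- apply_transform(pose, pts)

  # box average along the slice normal
  k <- max(1L, round(geom$slice_thickness_mm /
                       min(vol$spacing[3], geom$slice_thickness_mm)))
  offsets <- (seq_len(k) - (k + 1) / 2) * (geom$slice_thickness_mm / k)
  normal <- Rt[, 3]
  acc <- 0
  for (o in offsets) {
    p <- pts + matrix(o * normal, nrow(pts), 3, byrow = TRUE)
    v <- sample_at_physical(vol, p, "linear")
    v[is.na(v)] <- if (vol$modality == "CT") -1000 else 0
    acc <- acc + v
  }
  out_geom$data <- array(acc / length(offsets), n)
  out_geom
}
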