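# Pseudo-CT synthesis: density-based body contouring and the outer-body
# HU correction scheme that gives the aligned diagnostic CT the reference
# scan's outer body shape.

#' Delineate the external body contour of a CT volume
#'
#' Thresholds the volume (out-of-scan sentinel voxels count as below
#' threshold), keeps the largest 6-connected component, and fills interior
#' holes both slice-wise and in 3D, so air cavities (sinuses) belong to the
#' body.
#'
#' @param vol a CT-like [image_volume()] (an MR volume is accepted when an
#'   explicit `threshold` on its intensity scale is given).
#' @param threshold voxels strictly above this value are tissue; default
#'   -400 HU separates air from tissue at any realistic noise level.
#' @return the body [binary_mask()].
#' @export
contour_body <- function(vol, threshold = -400) {
  dims <- dim(vol$data)
  fg <- !is.na(vol$data) & vol$data > threshold
  if (!any(fg))
    stop("no body found: no voxels above the density threshold",
         call. = FALSE)
  body <- largest_component(fg, dims)
  body <- fill_holes_slicewise(body, dims)
  body <- fill_holes_3d(body, dims)
  mask_like(body, vol)
}

#' Locate the unscanned region of an aligned diagnostic CT
#'
#' After [resample_to_grid()], anatomy missing from the diagnostic scan's
#' limited extent holds the out-of-scan sentinel; this returns those voxels
#' as a mask.
#'
#' @param dct_aligned CT [image_volume()] on the reference grid.
#' @return [binary_mask()] of sentinel voxels.
#' @export
detect_unscanned <- function(dct_aligned) {
  mask_like(is.na(dct_aligned$data), dct_aligned)
}

#' Outer-body HU correction
#'
#' Applies the tissue excess/deficiency rules that force the aligned
#' diagnostic CT into the reference body shape, in this precedence:
#' \enumerate{
#'   \item inside the reference body and unscanned: 0 HU (soft tissue);
#'   \item inside the reference body, outside the diagnostic body: 0 HU
#'     (tissue deficiency);
#'   \item inside the diagnostic body, outside the reference body:
#'     -1000 HU (tissue excess becomes air);
#'   \item outside both bodies: sentinel voxels become -1000 HU, scanned
#'     voxels are copied;
#'   \item everywhere else (inside both bodies, scanned): copied unchanged.
#' }
#' The output contains no sentinel voxels and is dose-calculable.
#'
#' @param dct_aligned diagnostic CT resampled onto the reference grid.
#' @param dct_body diagnostic-scan body mask (same grid).
#' @param ref_body reference (planning) body mask (same grid).
#' @param unscanned unscanned-region mask (same grid), e.g. from
#'   [detect_unscanned()].
#' @return list with `pseudo_ct` ([image_volume()]) and `report`
#'   (a `correction_report`: voxel counts and volumes of each class).
#' @export
correct_outer_body <- function(dct_aligned, dct_body, ref_body, unscanned) {
  stop_grid_mismatch(dct_aligned, dct_body, "dct_body and dct_aligned")
  stop_grid_mismatch(dct_aligned, ref_body, "ref_body and dct_aligned")
  stop_grid_mismatch(dct_aligned, unscanned, "unscanned and dct_aligned")
  hu <- dct_aligned$data
  in_dct <- dct_body$data > 0
  in_ref <- ref_body$data > 0
  uns <- unscanned$data > 0

  r_unscanned <- in_ref & uns
  r_deficient <- in_ref & !in_dct & !r_unscanned
  r_excess <- in_dct & !in_ref
  r_outside_sentinel <- !in_ref & !in_dct & is.na(hu)

  hu[r_unscanned] <- 0
  hu[r_deficient] <- 0
  hu[r_excess] <- -1000
  hu[r_outside_sentinel] <- -1000

  n_total <- length(hu)
  n_unscanned <- sum(r_unscanned)
  n_deficient <- sum(r_deficient)
  n_excess <- sum(r_excess)
  vcc <- voxel_volume_cc(dct_aligned)
  report <- structure(list(
    excess = n_excess,
    deficient = n_deficient,
    unscanned_deficient = n_unscanned,
    unchanged = n_total - n_excess - n_deficient - n_unscanned,
    total = n_total,
    excess_cc = n_excess * vcc,
    deficient_cc = n_deficient * vcc,
    unscanned_deficient_cc = n_unscanned * vcc
  ), class = "correction_report")

  out <- dct_aligned
  out$data <- hu
  list(pseudo_ct = out, report = report)
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report>\n")
  cat(sprintf("  tissue excess     : %8d voxels (%.2f cc) -> -1000 HU\n",
              x$excess, x$excess_cc))
  cat(sprintf("  tissue deficiency : %8d voxels (%.2f cc) ->     0 HU\n",
              x$deficient, x$deficient_cc))
  cat(sprintf("  unscanned deficit : %8d voxels (%.2f cc) ->     0 HU\n",
              x$unscanned_deficient, x$unscanned_deficient_cc))
  cat(sprintf("  unchanged         : %8d voxels\n", x$unchanged))
  invisible(x)
}

#' Generate a pseudo-CT from a diagnostic CT and the planning scans
#'
#' Orchestrates the five-step workflow: (1) rigid fusion of the planning
#' MR onto the planning CT (skipped in MRI-only mode), (2) rigid
#' registration of the diagnostic CT, (3) interpolation onto the planning-
#' MR grid, (4) density-based body contouring of both scans, (5) outer-body
#' excess/deficiency/unscanned correction.
#'
#' In the default (CT-referenced) mode the reference body is contoured on
#' the planning CT; in MRI-only mode (`config$mode = "mri_only"`) the
#' planning-MR grid is the reference as-is and the reference body comes
#' from the MR intensities.
#'
#' @param dct diagnostic CT [image_volume()] (prior scan, possibly tilted,
#'   thick slices, limited extent).
#' @param pct planning CT [image_volume()] (reference; may be `NULL` in
#'   MRI-only mode).
#' @param pmr planning MR [image_volume()].
#' @param config list of options: `mode` ("pct" or "mri_only"),
#'   `body_threshold_hu` (default -400), `mr_body_threshold` (default
#'   0.1 * max MR), `bone_threshold_hu` (default 300),
#'   `dct_registration` ("bone-CTCT" against the planning CT, the default,
#'   or "intermodal" against the reoriented MR).
#' @return list with `pseudo_ct`, `report`, `transforms` (list of
#'   `pmr_to_pct` and `dct_to_ref`), `reference` (the reference grid
#'   volume), `dct_aligned`, `dct_body`, `ref_body`, `unscanned`.
#' @export
generate_pseudo_ct <- function(dct, pct, pmr, config = list()) {
  cfg <- modifyList(list(mode = "pct", body_threshold_hu = -400,
                         mr_body_threshold = NULL,
                         bone_threshold_hu = 300,
                         dct_registration = "bone-CTCT"),
                    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mri_only <- identical(cfg$mode, "mri_only")
  mr_thr <- cfg$mr_body_threshold
  if (is.null(mr_thr)) mr_thr <- 0.1 * max(pmr$data, na.rm = TRUE)

  if (mri_only) {
    t_pmr <- rigid_transform()
    ref_grid <- pmr
  } else {
    t_pmr <- stage("pmr_fusion",
                   register_rigid(pmr, pct, mode = "intermodal",
                                  body_threshold = cfg$body_threshold_hu))
    # reference grid: the PMR grid carried into PCT space by the fusion
    ref_grid <- image_volume(pmr$data, pmr$spacing,
                             as.numeric(apply_transform(t_pmr, pmr$origin)),
                             t_pmr$rotation %*% pmr$direction,
                             modality = "MR")
  }

  if (mri_only || identical(cfg$dct_registration, "intermodal")) {
    t_dct <- stage("dct_registration",
                   register_rigid(dct, ref_grid, mode = "intermodal",
                                  body_threshold = mr_thr))
  } else {
    t_dct <- stage("dct_registration",
                   register_rigid(dct, pct, mode = "bone-CTCT",
                                  bone_threshold_hu = cfg$bone_threshold_hu,
                                  body_threshold = cfg$body_threshold_hu))
  }

  dct_aligned <- stage("resample",
                       resample_to_grid(dct, t_dct, ref_grid, "linear"))
  dct_body <- stage("dct_contour",
                    contour_body(dct_aligned, cfg$body_threshold_hu))
  ref_body <- stage("ref_contour", {
    if (mri_only) contour_body(pmr, mr_thr)
    else contour_body(resample_to_grid(pct, rigid_transform(), ref_grid,
                                       "linear"),
                      cfg$body_threshold_hu)
  })
  unscanned <- detect_unscanned(dct_aligned)
  corr <- stage("correction",
                correct_outer_body(dct_aligned, dct_body, ref_body,
                                   unscanned))
  list(pseudo_ct = corr$pseudo_ct, report = corr$report,
       transforms = list(pmr_to_pct = t_pmr, dct_to_ref = t_dct),
       reference = ref_grid, dct_aligned = dct_aligned,
       dct_body = dct_body, ref_body = ref_body, unscanned = unscanned)
}
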