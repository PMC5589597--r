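# End-to-end experiment driver: generate paired scans, build the
# pseudo-CT, plan on it, recompute the frozen plan on the reference CT,
# and compare.

#' Experiment configuration
#'
#' Encodes one phantom study: anatomy, the three acquisition geometries,
#' the inter-scan body change, the diagnostic-scan pose mismatch, the
#' target site, plan and evaluation settings, and the master seed that
#' fully determines the run.
#'
#' The diagnostic CT's gantry tilt is drawn uniformly from
#' `dct_tilt_range` (default 0 to 23.3 degrees, the diagnostic tilt
#' range the phantom emulates) unless `dct_tilt_deg` pins it; a patient set-up
#' mismatch for the diagnostic session is drawn uniformly within
#' `dct_pose_rot_max_deg` / `dct_pose_trans_max_mm`.
#'
#' @param seed master integer seed.
#' @param phantom a [phantom_spec()]; its seed is overridden by `seed`.
#' @param dct_geom,pct_geom,pmr_geom [scan_geometry()] for the diagnostic
#'   CT (5 mm tilted slices, limited inferior extent), planning CT
#'   (1.25 mm slices) and planning MR (2.5 mm slices).
#' @param delta_scalp_mm outer-body change between the diagnostic and
#'   planning sessions, mm (positive = thicker scalp at diagnostic time).
#' @param dct_tilt_deg fixed tilt, or `NULL` to draw from
#'   `dct_tilt_range`.
#' @param dct_tilt_range,dct_pose_rot_max_deg,dct_pose_trans_max_mm
#'   sampling ranges for the diagnostic acquisition.
#' @param target_site `"ord"`, `"vent"` or `"skull"`.
#' @param plan,pseudo,eval option lists passed to [make_plan()],
#'   [generate_pseudo_ct()] and the evaluation ROI
#'   (`dose_crit_pct`, `dist_crit_mm`, `axis`, `half_size_mm`).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L,
                              phantom = phantom_spec(),
                              dct_geom = scan_geometry(0, 5, 1.2, 25),
                              pct_geom = scan_geometry(0, 1.25, 1.2, 0),
                              pmr_geom = scan_geometry(0, 2.5, 1.5, 0),
                              delta_scalp_mm = 2,
                              dct_tilt_deg = NULL,
                              dct_tilt_range = c(0, 23.3),
                              dct_pose_rot_max_deg = 5,
                              dct_pose_trans_max_mm = 8,
                              target_site = c("ord", "vent", "skull"),
                              plan = list(), pseudo = list(),
                              eval = list()) {
  target_site <- match.arg(target_site)
  phantom$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), phantom = phantom,
                 dct_geom = dct_geom, pct_geom = pct_geom,
                 pmr_geom = pmr_geom,
                 delta_scalp_mm = delta_scalp_mm,
                 dct_tilt_deg = dct_tilt_deg,
                 dct_tilt_range = dct_tilt_range,
                 dct_pose_rot_max_deg = dct_pose_rot_max_deg,
                 dct_pose_trans_max_mm = dct_pose_trans_max_mm,
                 target_site = target_site,
                 plan = plan, pseudo = pseudo,
                 eval = modifyList(list(dose_crit_pct = 2,
                                        dist_crit_mm = 1,
                                        axis = "coronal",
                                        half_size_mm = 50), eval)),
            class = "experiment_config")
}

# acquisition randomness drawn in a fixed order from the master seed
draw_acquisition <- function(config) {
  with_seed(config$seed + 1000L, {
    tilt <- if (is.null(config$dct_tilt_deg))
      runif(1, config$dct_tilt_range[1], config$dct_tilt_range[2])
    else config$dct_tilt_deg
    rmax <- config$dct_pose_rot_max_deg
    tmax <- config$dct_pose_trans_max_mm
    rot <- runif(3, -rmax, rmax)
    tra <- runif(3, -tmax, tmax)
    list(tilt = tilt,
         pose = rigid_transform(euler_rotation(rot[1], rot[2], rot[3]),
                                tra))
  })
}

#' Run one pseudo-CT verification experiment
#'
#' Pipeline: phantom anatomy -> diagnostic-session anatomy (outer-body
#' change only; the scanner-noise field of the underlying anatomy is drawn
#' once per experiment, so sessions differ purely by morphology and
#' acquisition) -> simulated DCT/PCT/PMR scans -> pseudo-CT -> 5-beam plan
#' on the pseudo-CT -> frozen recomputation on the planning CT ->
#' plan metrics, metric deltas (verification minus original), pixel dose
#' differences and gamma agreement on the isocenter plane.
#'
#' @param config an [experiment_config()].
#' @param keep_volumes keep the large intermediate volumes in the returned
#'   object (default FALSE).
#' @return a `pseudoct_experiment` report list.
#' @export
run_experiment <- function(config, keep_volumes = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ph <- stage("phantom", generate_head_phantom(config$phantom))
  labels_dct <- stage("interscan",
                      apply_interscan_change(ph$labels,
                                             config$delta_scalp_mm))
  noise <- phantom_noise(config$phantom, dim(ph$labels$data))
  ct_dct_truth <- ph$ct
  ct_dct_truth$data <- voxelize_tissue(labels_dct$data, config$phantom$hu) +
    config$phantom$noise_sd_hu * noise$ct

  acq <- draw_acquisition(config)
  dct_geom <- scan_geometry(acq$tilt, config$dct_geom$slice_thickness_mm,
                            config$dct_geom$inplane_spacing_mm,
                            config$dct_geom$inferior_cutoff_mm)
  dct <- stage("simulate_dct",
               simulate_scan(ct_dct_truth, dct_geom, pose = acq$pose))
  pct <- stage("simulate_pct", simulate_scan(ph$ct, config$pct_geom))
  pmr <- stage("simulate_pmr", simulate_scan(ph$mr, config$pmr_geom))

  px <- stage("pseudoct", generate_pseudo_ct(dct, pct, pmr, config$pseudo))
  ref <- px$reference

  ptv <- stage("ptv", resample_to_grid(
    ph$structures[[paste0("ptv_", config$target_site)]],
    rigid_transform(), ref))
  if (!any(ptv$data > 0))
    stop("[ptv] target volume empty on the reference grid", call. = FALSE)

  plan0 <- stage("plan", make_plan(ptv, px$unscanned, config$plan))
  orig <- stage("dose_original",
                compute_plan_dose(px$pseudo_ct, plan0, ptv))
  pct_ref <- stage("verification_ct", fill_sentinel(
    resample_to_grid(pct, rigid_transform(), ref), -1000))
  ver_dose <- stage("dose_verification",
                    recompute_plan_dose(pct_ref, orig$plan))

  m_orig <- plan_metrics(orig$dose, ptv)
  m_ver <- plan_metrics(ver_dose, ptv)
  deltas <- list(d_max = m_ver$d_max - m_orig$d_max,
                 d_mean = m_ver$d_mean - m_orig$d_mean,
                 d_min = m_ver$d_min - m_orig$d_min,
                 v95 = m_ver$v95 - m_orig$v95,
                 v100 = m_ver$v100 - m_orig$v100,
                 ci = m_ver$ci - m_orig$ci)
  roi <- list(axis = config$eval$axis,
              center_mm = orig$plan$isocenter_mm,
              half_size_mm = config$eval$half_size_mm)
  diff <- stage("dose_difference",
                dose_difference(orig$dose, ver_dose, roi,
                                config$eval$dose_crit_pct))
  gam <- stage("gamma",
               gamma_index(orig$dose, ver_dose, config$eval$dose_crit_pct,
                           config$eval$dist_crit_mm, roi))

  out <- list(config = config,
              acquisition = list(tilt_deg = acq$tilt,
                                 pose_parameters = c(
                                   rotation_deg =
                                     rotation_angle_deg(acq$pose$rotation),
                                   translation_mm =
                                     sqrt(sum(acq$pose$translation^2)))),
              correction = px$report,
              transforms = px$transforms,
              plan = orig$plan,
              metrics_original = m_orig,
              metrics_verification = m_ver,
              metric_deltas = deltas,
              dose_difference = diff,
              gamma = gam)
  if (keep_volumes)
    out$volumes <- list(dct = dct, pct = pct, pmr = pmr,
                        pseudo_ct = px$pseudo_ct, reference_ct = pct_ref,
                        ptv = ptv, dose_original = orig$dose,
                        dose_verification = ver_dose,
                        unscanned = px$unscanned,
                        ref_body = px$ref_body)
  class(out) <- "pseudoct_experiment"
  out
}

#' @export
print.pseudoct_experiment <- function(x, ...) {
  cat("<pseudoct_experiment>\n")
  cat(sprintf("  target %-5s  DCT tilt %.1f deg  scalp change %+.1f mm\n",
              x$config$target_site, x$acquisition$tilt_deg,
              x$config$delta_scalp_mm))
  cat(sprintf("  original     : Min %.1f  Mean %.1f  Max %.1f  V95 %.1f  V100 %.1f  CI %.2f\n",
              x$metrics_original$d_min, x$metrics_original$d_mean,
              x$metrics_original$d_max, x$metrics_original$v95,
              x$metrics_original$v100, x$metrics_original$ci))
  cat(sprintf("  verification : Min %.1f  Mean %.1f  Max %.1f  V95 %.1f  V100 %.1f  CI %.2f\n",
              x$metrics_verification$d_min, x$metrics_verification$d_mean,
              x$metrics_verification$d_max, x$metrics_verification$v95,
              x$metrics_verification$v100, x$metrics_verification$ci))
  d <- x$metric_deltas
  cat(sprintf("  deltas       : Max %+.2f  Mean %+.2f  Min %+.2f  V95 %+.2f  V100 %+.2f  CI %+.3f\n",
              d$d_max, d$d_mean, d$d_min, d$v95, d$v100, d$ci))
  cat(sprintf("  |dD| pass %.2f%% (max %.2f); gamma pass %.2f%% (mean %.3f, max %.3f)\n",
              x$dose_difference$passing_rate, x$dose_difference$max_abs,
              x$gamma$passing_rate, x$gamma$mean, x$gamma$max))
  invisible(x)
}

#' @export
summary.pseudoct_experiment <- function(object, ...) {
  print(object)
  cat("\ncorrection report:\n")
  print(object$correction)
  cat("\nplan:\n")
  print(object$plan)
  invisible(object)
}

# JSON-serializable scalar view of a report (used by the CLI and tests)
experiment_report_list <- function(x) {
  num <- function(l) lapply(l, function(v) unname(as.numeric(v)))
  list(seed = x$config$seed,
       target_site = x$config$target_site,
       delta_scalp_mm = x$config$delta_scalp_mm,
       tilt_deg = x$acquisition$tilt_deg,
       correction = num(unclass(x$correction)),
       metrics_original = num(unclass(x$metrics_original)),
       metrics_verification = num(unclass(x$metrics_verification)),
       metric_deltas = num(x$metric_deltas),
       dose_difference = num(x$dose_difference[c("mean_abs", "sd_abs",
                                                 "max_abs",
                                                 "passing_rate")]),
       gamma = num(x$gamma[c("mean", "sd", "max", "passing_rate")]))
}
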