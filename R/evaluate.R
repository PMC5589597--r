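# Feasibility metrics: DVH, plan-quality indicators, pixel dose
# differences, and 2%/1 mm gamma agreement between a pseudo-CT plan and
# its verification recomputation.  Doses are % of prescription throughout
# and both difference and gamma use global normalization.

EQ_TOL <- 1e-6  # tolerance for ">= level" comparisons on normalized dose

#' Cumulative dose-volume histogram
#'
#' @param dose DOSE [image_volume()] in % of prescription.
#' @param mask non-empty [binary_mask()] on the same grid.
#' @param bin_width histogram step in % points, default 0.5.
#' @return data.frame with `dose_pct` and `volume_pct` (monotone
#'   non-increasing; `volume_pct[dose_pct == 0]` is 100).
#' @export
dvh <- function(dose, mask, bin_width = 0.5) {
  stop_grid_mismatch(dose, mask, "dose and mask")
  vals <- dose$data[mask$data > 0]
  if (length(vals) == 0) stop("empty mask", call. = FALSE)
  levels <- seq(0, max(vals) + bin_width, by = bin_width)
  volume <- vapply(levels,
                   function(l) 100 * mean(vals >= l - EQ_TOL), numeric(1))
  data.frame(dose_pct = levels, volume_pct = volume)
}

#' Plan-quality metrics over a PTV
#'
#' Min/mean/max PTV dose, coverage V95%/V100% (% of PTV volume at or above
#' 95% / 100% of prescription), and the conformity index CI = (volume
#' anywhere receiving at least the prescription dose) / (PTV volume);
#' ideal CI is 1.0.
#'
#' @param dose DOSE [image_volume()] in % of prescription.
#' @param ptv non-empty PTV [binary_mask()] on the same grid.
#' @return a `plan_metrics` list: `d_min`, `d_mean`, `d_max`, `v95`,
#'   `v100`, `ci`.
#' @export
plan_metrics <- function(dose, ptv) {
  stop_grid_mismatch(dose, ptv, "dose and ptv")
  in_ptv <- ptv$data > 0
  if (!any(in_ptv)) stop("empty PTV", call. = FALSE)
  dp <- dose$data[in_ptv]
  structure(list(
    d_min = min(dp),
    d_mean = mean(dp),
    d_max = max(dp),
    v95 = 100 * mean(dp >= 95 - EQ_TOL),
    v100 = 100 * mean(dp >= 100 - EQ_TOL),
    ci = sum(dose$data >= 100 - EQ_TOL) / sum(in_ptv)
  ), class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("<plan_metrics> Min %.2f  Mean %.2f  Max %.2f %%\n",
              x$d_min, x$d_mean, x$d_max))
  cat(sprintf("  V95%% %.2f  V100%% %.2f  CI %.3f\n", x$v95, x$v100, x$ci))
  invisible(x)
}

# Extract an axis-aligned plane through `center_mm` as a 2D matrix with
# in-plane physical coordinates (mm, relative to the projected center).
# `axis` names the anatomical normal: coronal = y, axial = z,
# sagittal = x (LPS).  The grid axis best aligned with that normal is
# sliced at the voxel nearest the center.
extract_plane <- function(vol, axis = c("coronal", "axial", "sagittal"),
                          center_mm, half_size_mm = 50) {
  axis <- match.arg(axis)
  normal_world <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
  align <- abs(vol$direction[normal_world, ])
  k_axis <- which.max(align)
  in_plane <- setdiff(1:3, k_axis)
  cidx <- as.numeric(physical_to_index(vol, center_mm))
  d <- dim(vol$data)
  k0 <- min(max(round(cidx[k_axis]), 0), d[k_axis] - 1)

  sel <- lapply(1:3, function(a) {
    if (a == k_axis) return(k0)
    lo <- max(0, ceiling(cidx[a] - half_size_mm / vol$spacing[a]))
    hi <- min(d[a] - 1, floor(cidx[a] + half_size_mm / vol$spacing[a]))
    if (hi < lo) stop("plane ROI lies outside the dose grid",
                      call. = FALSE)
    lo:hi
  })
  values <- vol$data[sel[[1]] + 1, sel[[2]] + 1, sel[[3]] + 1, drop = TRUE]
  dim(values) <- c(length(sel[[in_plane[1]]]), length(sel[[in_plane[2]]]))
  u <- (sel[[in_plane[1]]] - cidx[in_plane[1]]) * vol$spacing[in_plane[1]]
  v <- (sel[[in_plane[2]]] - cidx[in_plane[2]]) * vol$spacing[in_plane[2]]
  list(values = values, u = u, v = v,
       spacing = vol$spacing[in_plane], axis = axis)
}

# bilinear interpolation on an extract_plane result at coordinates
# (pu, pv) in the plane's mm frame; outside the extent -> NA
bilinear_plane <- function(plane, pu, pv) {
  iu <- (pu - plane$u[1]) / plane$spacing[1]
  iv <- (pv - plane$v[1]) / plane$spacing[2]
  nu <- length(plane$u); nv <- length(plane$v)
  ok <- iu >= 0 & iu <= nu - 1 & iv >= 0 & iv <= nv - 1
  out <- rep(NA_real_, length(pu))
  if (!any(ok)) return(out)
  iu <- iu[ok]; iv <- iv[ok]
  i0 <- pmin(floor(iu), nu - 2); j0 <- pmin(floor(iv), nv - 2)
  fu <- iu - i0; fv <- iv - j0
  m <- plane$values
  out[ok] <- (1 - fu) * (1 - fv) * m[cbind(i0 + 1, j0 + 1)] +
             fu * (1 - fv) * m[cbind(i0 + 2, j0 + 1)] +
             (1 - fu) * fv * m[cbind(i0 + 1, j0 + 2)] +
             fu * fv * m[cbind(i0 + 2, j0 + 2)]
  out
}

default_roi <- function(roi, center_fallback) {
  cfg <- modifyList(list(axis = "coronal", center_mm = center_fallback,
                         half_size_mm = 50), roi)
  if (is.null(cfg$center_mm))
    stop("roi$center_mm (plan isocenter) is required", call. = FALSE)
  cfg
}

#' Pixel-to-pixel dose difference on an isocenter plane
#'
#' Signed difference `evaluated - reference` in percentage points of the
#' prescription dose, evaluated pixel-by-pixel on a square axis-aligned
#' plane (default: the coronal 10 x 10 cm plane through `roi$center_mm`).
#'
#' @param reference,evaluated DOSE [image_volume()]s on the same grid.
#' @param roi list: `axis` ("coronal"/"axial"/"sagittal"), `center_mm`
#'   (usually the plan isocenter), `half_size_mm` (default 50).
#' @param criterion_pct pass criterion on |difference|, default 2.
#' @return a `diff_result`: `delta` (signed matrix), `abs_delta`,
#'   `mean_abs`, `sd_abs`, `max_abs`, `passing_rate`.
#' @export
dose_difference <- function(reference, evaluated, roi = list(),
                            criterion_pct = 2) {
  stop_grid_mismatch(reference, evaluated, "dose grids")
  cfg <- default_roi(roi, NULL)
  rp <- extract_plane(reference, cfg$axis, cfg$center_mm, cfg$half_size_mm)
  ep <- extract_plane(evaluated, cfg$axis, cfg$center_mm, cfg$half_size_mm)
  delta <- ep$values - rp$values
  ad <- abs(delta)
  structure(list(delta = delta, abs_delta = ad,
                 mean_abs = mean(ad), sd_abs = sd(as.numeric(ad)),
                 max_abs = max(ad),
                 passing_rate = 100 * mean(ad <= criterion_pct + EQ_TOL),
                 criterion_pct = criterion_pct),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("<diff_result> |dD|: mean %.3f  sd %.3f  max %.3f %%-pts; %.2f%% within %.0f%%\n",
              x$mean_abs, x$sd_abs, x$max_abs, x$passing_rate,
              x$criterion_pct))
  invisible(x)
}

#' Gamma agreement between two dose distributions
#'
#' For each reference pixel p on the ROI plane,
#' `gamma(p) = min_q sqrt((D_e(q) - D_r(p))^2 / dose_crit^2 +
#' ||q - p||^2 / dist_crit^2)` over search positions q on a sub-grid of
#' step `dist_crit / 10` within radius `3 * dist_crit`; the evaluated dose
#' is interpolated bilinearly at q.  Dose normalization is global (% of
#' prescription).  The search is exhaustive (no pruning), so it is exactly
#' the discrete minimum it claims to be.
#'
#' @inheritParams dose_difference
#' @param dose_crit_pct dose criterion in % points, default 2.
#' @param dist_crit_mm distance-to-agreement criterion in mm, default 1.
#' @return a `gamma_result`: `gamma` (matrix), `mean`, `sd`, `max`,
#'   `passing_rate` (% of pixels with gamma <= 1).
#' @export
gamma_index <- function(reference, evaluated, dose_crit_pct = 2,
                        dist_crit_mm = 1, roi = list()) {
  stop_grid_mismatch(reference, evaluated, "dose grids")
  if (dose_crit_pct <= 0 || dist_crit_mm <= 0)
    stop("criteria must be positive", call. = FALSE)
  cfg <- default_roi(roi, NULL)
  search_radius <- 3 * dist_crit_mm
  rp <- extract_plane(reference, cfg$axis, cfg$center_mm, cfg$half_size_mm)
  ep <- extract_plane(evaluated, cfg$axis, cfg$center_mm,
                      cfg$half_size_mm + search_radius + 1)
  gam2 <- gamma_plane_min(rp, ep, dose_crit_pct, dist_crit_mm,
                          search_radius)
  gam <- sqrt(gam2)
  structure(list(gamma = gam, mean = mean(gam), sd = sd(as.numeric(gam)),
                 max = max(gam),
                 passing_rate = 100 * mean(gam <= 1 + EQ_TOL),
                 dose_crit_pct = dose_crit_pct,
                 dist_crit_mm = dist_crit_mm),
            class = "gamma_result")
}

# exhaustive discrete gamma^2 minimization over the offset disc
gamma_plane_min <- function(ref_plane, eval_plane, dose_crit, dist_crit,
                            search_radius) {
  step <- dist_crit / 10
  m <- floor(search_radius / step)
  off <- expand.grid(du = step * (-m:m), dv = step * (-m:m))
  off <- off[off$du^2 + off$dv^2 <= search_radius^2 + 1e-12, ]
  pu <- rep(ref_plane$u, times = length(ref_plane$v))
  pv <- rep(ref_plane$v, each = length(ref_plane$u))
  refv <- as.numeric(ref_plane$values)
  best <- rep(Inf, length(refv))
  for (i in seq_len(nrow(off))) {
    ev <- bilinear_plane(eval_plane, pu + off$du[i], pv + off$dv[i])
    cand <- (ev - refv)^2 / dose_crit^2 +
      (off$du[i]^2 + off$dv[i]^2) / dist_crit^2
    upd <- !is.na(cand) & cand < best
    best[upd] <- cand[upd]
  }
  matrix(best, nrow = length(ref_plane$u))
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: mean %.3f  sd %.3f  max %.3f; passing %.2f%%\n",
              x$dose_crit_pct, x$dist_crit_mm, x$mean, x$sd, x$max,
              x$passing_rate))
  invisible(x)
}
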