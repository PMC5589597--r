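# Rigid registration: multi-resolution Nelder-Mead over 6 pose parameters
# (Euler angles in degrees, translation in mm, rotation about the moving
# body centroid).  Two similarity modes:
#   bone-CTCT  - mean-squared HU difference restricted to bone voxels of
#                the fixed image (skull-driven CT-CT matching);
#   intermodal - negated mutual information over the head (CT-MR / MR-CT).
# Everything is deterministic: sample points are taken on a fixed stride
# and the optimizer is initialized from body-centroid alignment.

params_to_transform <- function(par, center) {
  R <- euler_rotation(par[1], par[2], par[3])
  # T(x) = R (x - c) + c + t
  rigid_transform(R, as.numeric(center - R %*% center) + par[4:6])
}

# deterministic subsample of at most n rows
stride_sample <- function(m, n) {
  if (nrow(m) <= n) return(m)
  m[seq(1, nrow(m), length.out = n), , drop = FALSE]
}

body_centroid <- function(vol, threshold) {
  on <- which(vol$data > threshold & !is.na(vol$data))
  if (length(on) == 0)
    stop("registration failure: no voxels above threshold", call. = FALSE)
  d <- dim(vol$data)
  i <- (on - 1) %% d[1]
  j <- ((on - 1) %/% d[1]) %% d[2]
  k <- (on - 1) %/% (d[1] * d[2])
  colMeans(index_to_physical(vol, cbind(i, j, k)))
}

# metric evaluation points + fixed values at one pyramid level
metric_points <- function(fixed, mode, bone_threshold, body_threshold,
                          max_points = 8000) {
  thr <- if (mode == "bone-CTCT") bone_threshold else body_threshold
  on <- which(fixed$data > thr & !is.na(fixed$data))
  if (length(on) < 50)
    stop("registration failure: too few voxels above the similarity mask threshold",
         call. = FALSE)
  d <- dim(fixed$data)
  idx <- cbind((on - 1) %% d[1],
               ((on - 1) %/% d[1]) %% d[2],
               (on - 1) %/% (d[1] * d[2]))
  keep <- if (length(on) > max_points)
    round(seq(1, length(on), length.out = max_points)) else seq_along(on)
  list(points = index_to_physical(fixed, idx[keep, , drop = FALSE]),
       values = fixed$data[on[keep]])
}

metric_value <- function(par, moving, mp, center, mode, mi_bins = 32) {
  tr <- params_to_transform(par, center)
  pts_mov <- apply_transform(invert_transform(tr), mp$points)
  mv <- sample_at_physical(moving, pts_mov, "linear")
  ok <- !is.na(mv)
  if (mean(ok) < 0.25) return(1e12)  # essentially no overlap
  if (mode == "bone-CTCT") {
    mean((mv[ok] - mp$values[ok])^2)
  } else {
    -mutual_information(mp$values[ok], mv[ok], mi_bins)
  }
}

mutual_information <- function(a, b, bins) {
  cut_idx <- function(x) {
    r <- range(x)
    if (r[2] <= r[1]) return(rep(1L, length(x)))
    pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  }
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins))
  py <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  outer_pp <- outer(px, py)
  sum(p[nz] * log(p[nz] / outer_pp[nz]))
}

#' Rigid registration of two volumes
#'
#' Finds the rigid transform mapping the moving image's physical space
#' into the fixed image's space.  `mode = "bone-CTCT"` minimizes the
#' mean-squared HU difference over voxels above a bone threshold in the
#' fixed image (both images must be CT-like), matching the skulls;
#' `mode = "intermodal"` maximizes mutual information over the head.
#' Optimization is multi-resolution (3 levels, Nelder-Mead), initialized
#' from body-centroid alignment, and fully deterministic.
#'
#' @param moving,fixed [image_volume()]s covering overlapping anatomy.
#' @param mode `"bone-CTCT"` or `"intermodal"`.
#' @param bone_threshold_hu bone mask threshold in the fixed image
#'   (bone-CTCT mode), default 300 HU.
#' @param body_threshold intensity threshold defining the head region for
#'   the intermodal metric (applied to the fixed image), default -400.
#' @param levels integer downsampling factors of the pyramid, coarse to
#'   fine.
#' @param maxit Nelder-Mead iteration budget per level (same length as
#'   `levels`).
#' @return a [rigid_transform()] with attribute `"metric"` (final metric
#'   value) and `"parameters"` (rx, ry, rz degrees; tx, ty, tz mm).
#' @export
register_rigid <- function(moving, fixed,
                           mode = c("bone-CTCT", "intermodal"),
                           bone_threshold_hu = 300,
                           body_threshold = -400,
                           levels = c(4L, 2L, 1L),
                           maxit = c(400L, 250L, 150L)) {
  mode <- match.arg(mode)
  if (mode == "bone-CTCT" &&
      (moving$modality != "CT" || fixed$modality != "CT"))
    stop("bone-CTCT mode requires two CT volumes", call. = FALSE)
  body_thr_fix <- if (fixed$modality == "CT") body_threshold else
    0.1 * max(fixed$data, na.rm = TRUE)
  body_thr_mov <- if (moving$modality == "CT") body_threshold else
    0.1 * max(moving$data, na.rm = TRUE)
  center <- body_centroid(moving, body_thr_mov)
  init_t <- body_centroid(fixed, body_thr_fix) - center
  par <- c(0, 0, 0, init_t)

  par0 <- par
  metrics <- rep(NA_real_, length(levels))
  final_fn <- NULL
  for (li in seq_along(levels)) {
    f <- downsample_volume(fixed, levels[li])
    m <- downsample_volume(moving, levels[li])
    mp <- metric_points(f, mode, bone_threshold_hu, body_thr_fix)
    fn <- function(p) metric_value(p, m, mp, center, mode)
    if (li == 1L) {
      # deterministic multi-start over a coarse rotation lattice; the
      # unrotated candidate comes first so exact ties keep it
      grid <- as.matrix(expand.grid(rx = c(0, -12, 12), ry = c(0, -12, 12),
                                    rz = c(0, -12, 12)))
      ord <- order(rowSums(abs(grid)))
      grid <- grid[ord, , drop = FALSE]
      vals <- apply(grid, 1, function(g) fn(c(g, par[4:6])))
      par <- c(grid[which.min(vals), ], par[4:6])
    }
    # Nelder-Mead with one fresh-simplex restart: a collapsed simplex at a
    # spurious stationary point does not survive re-initialization
    opt <- optim(par, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit[li], reltol = 1e-10,
                                parscale = c(6, 6, 6, 8, 8, 8)))
    opt2 <- optim(opt$par, fn, method = "Nelder-Mead",
                  control = list(maxit = maxit[li], reltol = 1e-10,
                                 parscale = c(2, 2, 2, 3, 3, 3)))
    if (opt2$value < opt$value) opt <- opt2
    par <- opt$par
    metrics[li] <- opt$value
    final_fn <- fn
    if (opt$value >= 1e12)
      stop("registration failure: no overlap between the volumes",
           call. = FALSE)
  }
  # divergence guard: the optimized pose must not score worse than the
  # centroid initialization on the finest level
  init_val <- final_fn(par0)
  if (metrics[length(metrics)] > init_val + 0.05 * abs(init_val) + 1e-9)
    stop("registration failure: metric diverged from its initialization",
         call. = FALSE)
  tr <- params_to_transform(par, center)
  attr(tr, "metric") <- metrics[length(metrics)]
  attr(tr, "parameters") <- par
  tr
}
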