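# Interpolation and grid resampling.

# Trilinear sampling of vol at continuous 0-based index coordinates
# (n x 3).  Points outside the voxel-center hull return NA (out-of-scan).
# Indices within `snap` of an integer are snapped, so sampling exactly at
# grid points reproduces stored values bit-for-bit and an identity
# resample is the identity.
sample_trilinear <- function(vol, idx, snap = 1e-6) {
  d <- dim(vol$data)
  r <- round(idx)
  near <- abs(idx - r) < snap
  idx[near] <- r[near]
  i0 <- floor(idx)
  f <- idx - i0
  inside <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
            idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
            idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(idx))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  f <- f[inside, , drop = FALSE]
  # clamp the +1 neighbour at the upper face (weight there is 0)
  i1 <- pmin(i0 + 1, matrix(d - 1, nrow(i0), 3, byrow = TRUE))
  lin <- function(ix, iy, iz) {
    vol$data[1 + ix + d[1] * (iy + d[2] * iz)]
  }
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * lin(i0[, 1], i0[, 2], i0[, 3]) +
       fx * (1 - fy) * (1 - fz) * lin(i1[, 1], i0[, 2], i0[, 3]) +
       (1 - fx) * fy * (1 - fz) * lin(i0[, 1], i1[, 2], i0[, 3]) +
       fx * fy * (1 - fz) * lin(i1[, 1], i1[, 2], i0[, 3]) +
       (1 - fx) * (1 - fy) * fz * lin(i0[, 1], i0[, 2], i1[, 3]) +
       fx * (1 - fy) * fz * lin(i1[, 1], i0[, 2], i1[, 3]) +
       (1 - fx) * fy * fz * lin(i0[, 1], i1[, 2], i1[, 3]) +
       fx * fy * fz * lin(i1[, 1], i1[, 2], i1[, 3])
  out[inside] <- v
  out
}

sample_nearest <- function(vol, idx) {
  d <- dim(vol$data)
  r <- round(idx)
  inside <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
            r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
            r[, 3] >= 0 & r[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(idx))
  ok <- which(inside)
  out[ok] <- vol$data[1 + r[ok, 1] + d[1] * (r[ok, 2] + d[2] * r[ok, 3])]
  out
}

# Sample vol at physical points (n x 3, in vol's own space).
sample_at_physical <- function(vol, points, method = "linear") {
  idx <- physical_to_index(vol, points)
  if (method == "linear") sample_trilinear(vol, idx)
  else sample_nearest(vol, idx)
}

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Every voxel of the reference grid is mapped back through the inverse
#' transform and the source volume interpolated there.  Voxels that map
#' outside the source's physical extent receive the out-of-scan sentinel
#' (`NA`) for CT volumes, or 0 for masks/MR/dose.
#'
#' @param vol source [image_volume()] (or [binary_mask()]).
#' @param transform [rigid_transform()] mapping `vol`'s space into the
#'   reference space.
#' @param reference [image_volume()] whose grid geometry the output adopts.
#' @param method `"linear"` (default) or `"nearest"`; masks are always
#'   resampled nearest-neighbour.
#' @return A volume with exactly the reference geometry and `vol`'s
#'   modality.
#' @export
resample_to_grid <- function(vol, transform, reference,
                             method = c("linear", "nearest")) {
  method <- match.arg(method)
  is_mask <- inherits(vol, "binary_mask")
  if (is_mask) method <- "nearest"
  pts_ref <- grid_points(reference)
  inv <- invert_transform(transform)
  pts_mov <- apply_transform(inv, pts_ref)
  vals <- sample_at_physical(vol, pts_mov, method)
  if (vol$modality != "CT")
    vals[is.na(vals)] <- 0
  arr <- array(vals, dim = dim(reference$data))
  if (is_mask)
    binary_mask(arr, reference$spacing, reference$origin,
                reference$direction)
  else
    image_volume(arr, reference$spacing, reference$origin,
                 reference$direction, modality = vol$modality)
}

# Box-mean downsample by integer factor per axis (crops any remainder);
# used by the multi-resolution registration pyramid.
downsample_volume <- function(vol, factor) {
  factor <- rep(as.integer(factor), length.out = 3)
  if (all(factor == 1L)) return(vol)
  d <- dim(vol$data)
  nd <- d %/% factor
  if (any(nd < 2)) return(vol)
  crop <- vol$data[seq_len(nd[1] * factor[1]),
                   seq_len(nd[2] * factor[2]),
                   seq_len(nd[3] * factor[3]), drop = FALSE]
  a <- array(crop, dim = c(factor[1], nd[1], factor[2], nd[2],
                           factor[3], nd[3]))
  a <- colMeans(a)                      # (n1, f2, n2, f3, n3)
  a <- colMeans(aperm(a, c(2, 1, 3, 4, 5)))   # (n1, n2, f3, n3)
  pooled <- colMeans(aperm(a, c(3, 1, 2, 4)))  # (n1, n2, n3)
  dim(pooled) <- nd
  # first new voxel center is the mean of the pooled centers
  shift <- (factor - 1) / 2 * vol$spacing
  origin <- vol$origin + as.numeric(vol$direction %*% shift)
  image_volume(pooled, vol$spacing * factor, origin, vol$direction,
               vol$modality)
}
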