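#' @useDynLib rtpseudo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim quantile rnorm runif sd
#' @importFrom utils modifyList
NULL

#' Geometric 3D image volume
#'
#' The carrier for every scan in the pipeline: a 3D scalar array plus the
#' physical geometry needed to place each voxel in patient space.  Physical
#' coordinates are LPS millimetres; voxel indices are 0-based and address
#' voxel centers, so `physical = origin + direction %*% (spacing * index)`.
#'
#' CT-like volumes hold Hounsfield units (air -1000, water 0).  After
#' resampling, voxels that fell outside the source scan's extent hold the
#' out-of-scan sentinel `NA_real_`; no fake HU is ever substituted until the
#' outer-body correction decides what the voxel should be.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @param direction 3x3 orthonormal direction-cosine matrix, det +1.
#' @param modality one of `"CT"`, `"MR"`, `"DOSE"`, `"MASK"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3), modality = "CT") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  direction <- as.matrix(direction)
  check_direction(direction)
  modality <- match.arg(modality, c("CT", "MR", "DOSE", "MASK"))
  if (modality %in% c("MR", "DOSE", "MASK") && anyNA(data))
    stop("out-of-scan sentinel (NA) only permitted in CT-like volumes",
         call. = FALSE)
  if (any(!is.finite(data) & !is.na(data)))
    stop("`data` must be finite (NA sentinel excepted)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         direction = direction, modality = modality),
    class = "image_volume")
}

check_direction <- function(direction, tol = 1e-6) {
  if (!is.matrix(direction) || !all(dim(direction) == c(3L, 3L)))
    stop("`direction` must be a 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > tol)
    stop("`direction` must be orthonormal (tolerance 1e-6)", call. = FALSE)
  if (det(direction) < 0)
    stop("`direction` must have determinant +1 (no axis flip)",
         call. = FALSE)
  invisible(direction)
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels\n",
              x$modality, d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin : (%.2f, %.2f, %.2f) mm LPS\n",
              x$origin[1], x$origin[2], x$origin[3]))
  rng <- suppressWarnings(range(x$data, na.rm = TRUE))
  cat(sprintf("  values : [%.4g, %.4g]%s\n", rng[1], rng[2],
              if (anyNA(x$data))
                sprintf(", %d out-of-scan voxels", sum(is.na(x$data)))
              else ""))
  invisible(x)
}

#' Binary structure mask on a volume grid
#'
#' A body / PTV / unscanned-region indicator sharing the geometry contract
#' of [image_volume()]; values are strictly 0/1.
#'
#' @param data 3D array coercible to 0/1.
#' @inheritParams image_volume
#' @return Object of classes `binary_mask`, `image_volume`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  storage.mode(data) <- "double"
  if (anyNA(data) || !all(data %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  vol <- image_volume(data, spacing, origin, direction, modality = "MASK")
  class(vol) <- c("binary_mask", class(vol))
  vol
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d on (%.2f cc)\n",
              d[1], d[2], d[3], sum(x$data > 0),
              sum(x$data > 0) * voxel_volume_cc(x)))
  invisible(x)
}

#' Mask from a logical array, inheriting a volume's geometry
#' @param logical_data logical 3D array.
#' @param like an `image_volume` supplying the geometry.
#' @return `binary_mask`
#' @export
mask_like <- function(logical_data, like) {
  arr <- array(as.double(logical_data), dim = dim(like$data))
  binary_mask(arr, like$spacing, like$origin, like$direction)
}

#' Voxel volume in cubic centimetres
#' @param vol an `image_volume`.
#' @export
voxel_volume_cc <- function(vol) prod(vol$spacing) / 1000

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share the same grid geometry", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Voxel indices to physical LPS coordinates
#'
#' @param vol an `image_volume`.
#' @param index numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional).
#' @return n x 3 matrix of physical points (mm).
#' @export
index_to_physical <- function(vol, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(index, 2, vol$spacing, `*`) %*% t(vol$direction) +
    matrix(vol$origin, nrow(index), 3, byrow = TRUE)
}

#' Physical LPS coordinates to (fractional) voxel indices
#' @param vol an `image_volume`.
#' @param points numeric matrix (n x 3) of physical points, mm.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
physical_to_index <- function(vol, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- points - matrix(vol$origin, nrow(points), 3, byrow = TRUE)
  sweep(d %*% vol$direction, 2, vol$spacing, `/`)
}

# physical coordinates of every voxel center, as an n x 3 matrix in array
# (column-major) order
grid_points <- function(vol) {
  d <- dim(vol$data)
  idx <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  index_to_physical(vol, idx)
}

#' Rigid spatial transform
#'
#' A 6-DOF mapping `x -> rotation %*% x + translation` taking physical
#' points of a moving image's space into a fixed image's space.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation numeric length-3, mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("`rotation` must be orthonormal with det +1 (tol 1e-8)",
         call. = FALSE)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite values (mm)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to physical points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix (or length-3 vector) of points, mm.
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  points %*% t(transform$rotation) +
    matrix(transform$translation, nrow(points), 3, byrow = TRUE)
}

#' Compose two rigid transforms
#' @param a,b `rigid_transform` objects; the result applies `b` first, then
#'   `a` (i.e. `compose(a, b)(x) = a(b(x))`).
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Rotation matrix from Euler angles (degrees)
#'
#' Intrinsic rotations applied in the order x (left-right axis), then y,
#' then z: `R = Rz %*% Ry %*% Rx`.
#'
#' @param rx,ry,rz angles in degrees about the LPS x, y, z axes.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  cx <- cospi(rx / 180); sx <- sinpi(rx / 180)
  cy <- cospi(ry / 180); sy <- sinpi(ry / 180)
  cz <- cospi(rz / 180); sz <- sinpi(rz / 180)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# magnitude (deg) of the rotation encoded by an orthonormal matrix
rotation_angle_deg <- function(R) {
  ctheta <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  acos(ctheta) * 180 / pi
}

# evaluate a block of code under a fixed RNG seed, restoring RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Replace out-of-scan sentinel voxels by a fixed value
#'
#' @param vol an `image_volume`.
#' @param value replacement value, default -1000 HU (air).
#' @return the volume with no sentinel voxels.
#' @export
fill_sentinel <- function(vol, value = -1000) {
  vol$data[is.na(vol$data)] <- value
  vol
}
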