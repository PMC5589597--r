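# Thin R wrappers around the compiled morphology kernels.

# Euclidean distance (mm) from each voxel to the nearest TRUE voxel.
distance_to <- function(mask_logical, dims, spacing) {
  d <- .edt3d_cpp(as.logical(mask_logical), as.integer(dims),
                  as.numeric(spacing))
  array(d, dim = dims)
}

# 6-connected components; 0 = background, components numbered from 1 in
# deterministic raster order.
connected_components <- function(mask_logical, dims) {
  array(.label3d_cpp(as.logical(mask_logical), as.integer(dims)),
        dim = dims)
}

# Keep only the largest 6-connected component of a logical array.
largest_component <- function(mask_logical, dims) {
  lab <- connected_components(mask_logical, dims)
  if (max(lab) == 0L) return(array(FALSE, dims))
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# Fill 3D holes: any background component that does not touch the volume
# border becomes foreground.
fill_holes_3d <- function(mask_logical, dims) {
  lab <- connected_components(!mask_logical, dims)
  if (max(lab) == 0L) return(mask_logical)
  border <- unique(c(lab[1, , ], lab[dims[1], , ],
                     lab[, 1, ], lab[, dims[2], ],
                     lab[, , 1], lab[, , dims[3]]))
  border <- border[border > 0L]
  mask_logical | (lab > 0L & !(lab %in% border))
}

# Fill 2D holes independently in every slice along the third axis.
fill_holes_slicewise <- function(mask_logical, dims) {
  out <- mask_logical
  for (k in seq_len(dims[3])) {
    sl <- mask_logical[, , k]
    lab <- connected_components(!sl, c(dims[1], dims[2], 1L))[, , 1]
    if (max(lab) == 0L) next
    border <- unique(c(lab[1, ], lab[dims[1], ], lab[, 1], lab[, dims[2]]))
    border <- border[border > 0L]
    out[, , k] <- sl | (lab > 0L & !(lab %in% border))
  }
  out
}
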