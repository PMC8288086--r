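#' Construct an axis-aligned RAS+ affine
#'
#' The package convention throughout is world = affine %*% c(i-1, j-1, k-1, 1)
#' for 1-based voxel indices (i, j, k), i.e. the centre of voxel (1,1,1) sits
#' at the affine translation. Anisotropic voxels (default 3 x 3 x 3.5 mm) are
#' the norm in this acquisition, so all geometry is done in mm.
#'
#' @param voxel_mm length-3 voxel edge lengths in mm
#' @param origin_mm world coordinate of the centre of voxel (1,1,1)
#' @return a 4x4 affine matrix
#' @export
make_affine <- function(voxel_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(voxel_mm) == 3, all(voxel_mm > 0), length(origin_mm) == 3)
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- origin_mm
  aff
}

#' Voxel indices to world coordinates
#'
#' @param ijk n x 3 matrix of 1-based voxel indices (may be fractional)
#' @param affine 4x4 affine
#' @return n x 3 matrix of mm coordinates
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' World coordinates to (fractional) voxel indices
#' @param xyz n x 3 matrix of mm coordinates
#' @param affine 4x4 affine
#' @return n x 3 matrix of 1-based voxel indices
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(affine))
  out[, 1:3, drop = FALSE] + 1
}

#' World coordinates of every voxel centre
#' @param dim length-3 grid size
#' @param affine 4x4 affine
#' @return prod(dim) x 3 matrix, voxels in array (column-major) order
#' @export
grid_world_coords <- function(dim, affine) {
  ijk <- as.matrix(expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                               k = seq_len(dim[3])))
  voxel_to_world(ijk, affine)
}

#' A 4-D BOLD series with acquisition metadata
#'
#' Light-weight container for one functional run: a 4-D array (x, y, z, t)
#' plus the affine, TR, per-slice acquisition time and slice order. Slices
#' are indexed in acquisition order (1 = first acquired); with a descending
#' sequence slice 1 is the topmost z plane.
#'
#' @param data 4-D numeric array (x, y, z, t) or 3-D for a single volume
#' @param affine 4x4 affine
#' @param tr_ms repetition time in ms
#' @param slice_ms per-slice acquisition time in ms
#' @param slice_order "descending" (default) or "ascending"
#' @param dropped_slices integer acquisition-order slice indices excluded from
#'   all analyses (see [drop_slice()])
#' @return an object of class `volume_series`
#' @export
volume_series <- function(data, affine, tr_ms, slice_ms,
                          slice_order = "descending",
                          dropped_slices = integer()) {
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1)
  stopifnot(length(dim(data)) == 4, identical(dim(affine), c(4L, 4L)))
  slice_order <- match.arg(slice_order, c("descending", "ascending"))
  structure(list(data = data, affine = affine, tr_ms = tr_ms,
                 slice_ms = slice_ms, slice_order = slice_order,
                 dropped_slices = as.integer(dropped_slices)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_series: %d x %d x %d voxels, %d volumes, TR %g ms, %s slices\n",
              d[1], d[2], d[3], d[4], x$tr_ms, x$slice_order))
  if (length(x$dropped_slices))
    cat("  dropped slices:", paste(x$dropped_slices, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.volume_series <- function(x) dim(x$data)

#' Map acquisition-order slice index to array z index
#' @param series a `volume_series`
#' @param slice 1-based slice index in acquisition order
#' @return z index into the array's third dimension
#' @export
slice_to_z <- function(series, slice) {
  nz <- dim(series$data)[3]
  stopifnot(all(slice >= 1), all(slice <= nz))
  if (series$slice_order == "descending") nz - slice + 1L else as.integer(slice)
}

#' Logical 3-D mask of planes excluded by drop_slice
#' @param series a `volume_series`
#' @return logical array, TRUE where the voxel is analysable
#' @export
valid_plane_mask <- function(series) {
  d <- dim(series$data)[1:3]
  m <- array(TRUE, d)
  for (s in series$dropped_slices) m[, , slice_to_z(series, s)] <- FALSE
  m
}

# Separable 1-D Gaussian convolution matrix (unnormalised rows; callers
# renormalise against a smoothed weight volume so masked/edge voxels do not
# leak signal).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, function(a, b) (a - b)^2) / (2 * sigma_vox^2))
  K[K < exp(-16)] <- 0
  K
}

# Apply a matrix along one axis of an up-to-4-D array.
apply_along_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- K %*% matrix(a, nrow = d[axis])
  dim(m) <- da
  aperm(m, order(perm))
}

# Separable 3-D Gaussian smoothing of a 3-D or 4-D array with per-axis sigma
# in voxel units. `weights` (3-D, 0/1 or fractional) restricts the kernel
# support; output is renormalised inside the support and zeroed outside.
separable_smooth <- function(arr, sigma_vox, weights = NULL) {
  d <- dim(arr)
  Ks <- lapply(1:3, function(a) gauss_conv_matrix(d[a], sigma_vox[a]))
  sm <- function(x) {
    for (a in 1:3) x <- apply_along_axis(x, Ks[[a]], a)
    x
  }
  if (is.null(weights)) {
    den <- sm(array(1, d[1:3]))
    num <- sm(arr)
  } else {
    stopifnot(identical(dim(weights), d[1:3]))
    den <- sm(weights)
    num <- sm(arr * as.vector(weights))
  }
  den_rep <- as.vector(den)
  out <- num / den_rep   # recycles den over the 4th dimension
  out[!is.finite(out)] <- 0
  if (!is.null(weights)) out <- out * as.vector(weights > 0)
  out
}

# 3-D connected components (6-connectivity) over a logical array, returned as
# a list of voxel-index matrices. Written for the sparse case (a few hundred
# TRUE voxels: fiducial capsules), so it runs a BFS over the TRUE set only.
connected_components_3d <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  d <- dim(mask)
  ijk <- arrayInd(idx, d)
  key <- function(m) (m[, 3] - 1) * d[1] * d[2] + (m[, 2] - 1) * d[1] + m[, 1]
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (r in seq_len(nrow(ijk))) assign(as.character(key(ijk[r, , drop = FALSE])), r, envir = lookup)
  visited <- logical(nrow(ijk))
  offs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  comps <- list()
  for (start in seq_len(nrow(ijk))) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE; members <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      nb <- sweep(offs, 2, ijk[cur, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      for (k in as.character(key(nb[ok, , drop = FALSE]))) {
        r <- lookup[[k]]
        if (!is.null(r) && !visited[r]) { visited[r] <- TRUE; queue <- c(queue, r) }
      }
    }
    comps[[length(comps) + 1L]] <- ijk[members, , drop = FALSE]
  }
  comps
}

# Write a 3-D/4-D array as NIfTI with the package affine in the sform.
write_nifti_vol <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  list(data = a, affine = unclass(RNifti::xform(img))[1:4, 1:4])
}
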