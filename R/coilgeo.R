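#' Coil localization from fiducial capsules
#'
#' Seven vitamin-E capsules are attached to the TMS coil: six in a regular
#' hexagon on the bottom surface and one at the centre of the upper surface.
#' The stimulation axis (entry line) passes through the seventh capsule,
#' perpendicular to the plane of the first six; spherical ROIs are placed on
#' this line inside the brain. All geometry is carried out in world (mm)
#' space via the image affine.
#'
#' @name coilgeo
NULL

#' Detect fiducial capsules in an anatomical image
#'
#' Thresholds the image at the 99.9th intensity percentile of the head,
#' labels connected components outside the brain mask and returns their
#' intensity-weighted centroids in mm. Errors unless exactly 7 components
#' survive.
#'
#' @param anat 3-D intensity array
#' @param brain_mask logical array of the same grid
#' @param affine 4x4 affine
#' @return a `fiducial_set`: list(points 7x3 mm matrix, n_voxels per capsule)
#' @export
detect_fiducials <- function(anat, brain_mask, affine) {
  thr <- stats::quantile(anat[brain_mask], 0.999)
  cand <- anat > thr & !brain_mask
  if (!any(cand))
    stop("no supra-threshold voxels outside the brain; capsules not brighter than the head")
  comps <- connected_components_3d(cand)
  if (length(comps) != 7)
    stop(sprintf("expected 7 bright components outside the brain, found %d (sizes: %s)",
                 length(comps),
                 paste(vapply(comps, nrow, integer(1)), collapse = ", ")))
  pts <- t(vapply(comps, function(m) {
    w <- anat[m]
    colSums(m * w) / sum(w)
  }, numeric(3)))
  world <- voxel_to_world(pts, affine)
  sep <- as.matrix(stats::dist(world))
  diag(sep) <- Inf
  if (min(sep) < 5)
    stop("two fiducial candidates closer than one capsule diameter")
  structure(list(points = world, n_voxels = vapply(comps, nrow, integer(1))),
            class = "fiducial_set")
}

#' Identify the six-capsule base plane and the apex capsule
#'
#' Tries all seven leave-one-out subsets, fits a total-least-squares plane
#' (smallest singular vector of the centred points) to each 6-point subset
#' and keeps the subset with minimal RMS residual; the left-out point is the
#' apex. Errors when two subsets fit comparably well (degenerate, e.g. all
#' seven points coplanar).
#'
#' @param fiducials a `fiducial_set` or a 7x3 matrix of mm points
#' @param toward optional mm point (e.g. brain centroid) used to orient the
#'   plane normal from the apex toward the brain
#' @return list(base 6x3, apex, centre, normal, rms)
#' @export
identify_plane_and_apex <- function(fiducials, toward = NULL) {
  pts <- if (inherits(fiducials, "fiducial_set")) fiducials$points else fiducials
  stopifnot(nrow(pts) == 7, ncol(pts) == 3)
  fit_plane <- function(p) {
    ctr <- colMeans(p)
    sv <- svd(sweep(p, 2, ctr))
    normal <- sv$v[, 3]
    res <- as.vector(sweep(p, 2, ctr) %*% normal)
    list(centre = ctr, normal = normal, rms = sqrt(mean(res^2)))
  }
  fits <- lapply(1:7, function(i) fit_plane(pts[-i, , drop = FALSE]))
  rms <- vapply(fits, `[[`, numeric(1), "rms")
  ord <- order(rms)
  if (rms[ord[2]] < max(2 * rms[ord[1]], 1e-6))
    stop("ambiguous apex: two 6-point subsets fit a plane equally well")
  apex_i <- ord[1]
  fit <- fits[[apex_i]]
  apex <- pts[apex_i, ]
  normal <- fit$normal
  if (!is.null(toward)) {
    if (sum((toward - apex) * normal) < 0) normal <- -normal
  } else {
    # default: orient away from the apex side of the plane
    if (sum((apex - fit$centre) * normal) > 0) normal <- -normal
  }
  list(base = pts[-apex_i, , drop = FALSE], apex = apex,
       centre = fit$centre, normal = normal, rms = rms[apex_i])
}

#' Entry line through the apex capsule
#'
#' The stimulation axis: the line through the apex capsule perpendicular to
#' the base-capsule plane, directed toward the brain. Note the line passes
#' through the apex, not necessarily through the hexagon centre.
#'
#' @param base 6x3 matrix of base-capsule points (mm)
#' @param apex mm point of the seventh capsule
#' @param toward mm point toward which the direction is oriented (brain
#'   centroid)
#' @return an `entry_line`: list(apex, direction unit vector,
#'   hexagon_centre)
#' @export
entry_line <- function(base, apex, toward) {
  ctr <- colMeans(base)
  sv <- svd(sweep(base, 2, ctr))
  normal <- sv$v[, 3]
  if (sum((toward - apex) * normal) < 0) normal <- -normal
  structure(list(apex = apex, direction = normal / sqrt(sum(normal^2)),
                 hexagon_centre = ctr),
            class = "entry_line")
}

#' Brain entry point of the stimulation axis
#'
#' Marches from the apex along the entry direction in 0.1-voxel steps and
#' returns the centre (mm) of the first brain-mask voxel encountered.
#'
#' @param line an `entry_line`
#' @param brain_mask logical 3-D array
#' @param affine 4x4 affine
#' @return mm coordinates of the stimulation spot
#' @export
stimulation_spot <- function(line, brain_mask, affine) {
  d <- dim(brain_mask)
  vx <- abs(diag(affine)[1:3])
  step <- 0.1 * min(vx)
  extent <- sqrt(sum((d * vx)^2))
  for (t in seq(0, 2 * extent, by = step)) {
    p <- line$apex + t * line$direction
    ijk <- round(world_to_voxel(p, affine))
    if (any(ijk < 1) || any(ijk > d)) next
    if (brain_mask[ijk[1], ijk[2], ijk[3]])
      return(as.vector(voxel_to_world(ijk, affine)))
  }
  stop("entry line does not intersect the brain mask")
}

#' Place a spherical ROI on the entry line
#'
#' Marches the candidate centre along the entry line from the stimulation
#' spot inward in 0.5-mm steps and keeps the first (shallowest) centre whose
#' whole sphere lies inside the brain mask. The voxel mask contains voxels
#' whose centres are within `radius` mm of the ROI centre, excluding dropped
#' planes if `exclude_z` is given.
#'
#' @param line an `entry_line`
#' @param brain_mask logical 3-D array
#' @param affine 4x4 affine
#' @param radius sphere radius in mm (the study uses 8, 12, 16, 20)
#' @param exclude_z optional z indices of masked planes
#' @return a `spherical_roi`: list(center, radius, voxels n x 3 index
#'   matrix, coords_mm, depth_mm from the stimulation spot)
#' @export
place_roi <- function(line, brain_mask, affine, radius, exclude_z = integer()) {
  spot <- stimulation_spot(line, brain_mask, affine)
  d <- dim(brain_mask)
  xyz <- grid_world_coords(d, affine)
  inside <- as.vector(brain_mask)
  vx <- abs(diag(affine)[1:3])
  max_depth <- sqrt(sum((d * vx)^2))
  for (depth in seq(0, max_depth, by = 0.5)) {
    ctr <- spot + depth * line$direction
    dist <- sqrt(colSums((t(xyz) - ctr)^2))
    sel <- dist <= radius
    if (!any(sel)) next
    if (all(inside[sel])) {
      vox <- arrayInd(which(sel), d)
      keep <- !(vox[, 3] %in% exclude_z)
      return(structure(list(center = ctr, radius = radius,
                            voxels = vox[keep, , drop = FALSE],
                            coords_mm = xyz[which(sel)[keep], , drop = FALSE],
                            depth_mm = depth),
                       class = "spherical_roi"))
    }
  }
  stop(sprintf("no centre on the entry line fits a %g-mm sphere inside the brain", radius))
}

#' Coil displacement between two stimulation spots
#'
#' Euclidean distance (mm) between the entry points recovered from the
#' anatomical scans at the start and end of a session; the study reports an
#' average displacement of a couple of millimetres.
#'
#' @param spot_a,spot_b mm points in the same space
#' @return distance in mm
#' @export
coil_displacement <- function(spot_a, spot_b) sqrt(sum((spot_a - spot_b)^2))

#' Split an ROI into upper and lower halves relative to the coil
#'
#' Cuts the sphere by the plane through its centre orthogonal to the entry
#' direction. The upper half is the apex (coil) side; voxels exactly on the
#' plane are assigned to the upper half (documented tie-break).
#'
#' @param roi a `spherical_roi`
#' @param line the `entry_line` used to place it
#' @return the roi with logical members `upper` and `lower` (per voxel) and
#'   counts `n_upper`, `n_lower`
#' @export
split_hemispheres <- function(roi, line) {
  proj <- as.vector((roi$coords_mm - matrix(roi$center, nrow(roi$coords_mm), 3,
                                            byrow = TRUE)) %*% line$direction)
  upper <- proj <= 0          # direction points into the brain, away from coil
  roi$upper <- upper
  roi$lower <- !upper
  roi$n_upper <- sum(upper)
  roi$n_lower <- sum(!upper)
  roi
}

#' Logical voxel mask of a spherical ROI
#' @param roi a `spherical_roi`
#' @param dim length-3 grid size
#' @return logical 3-D array
#' @export
roi_mask <- function(roi, dim) {
  m <- array(FALSE, dim)
  m[roi$voxels] <- TRUE
  m
}

#' Full fiducial-to-ROI localization
#'
#' Convenience wrapper: detect capsules, identify the plane and apex, build
#' the entry line toward the brain-mask centroid, find the stimulation spot
#' and place ROIs of the requested radii.
#'
#' @param anat 3-D intensity array
#' @param brain_mask logical array
#' @param affine 4x4 affine
#' @param radii sphere radii in mm
#' @param exclude_z z indices of dropped planes
#' @return list(fiducials, plane, line, spot, rois (named by radius))
#' @export
localize_coil <- function(anat, brain_mask, affine, radii = c(8, 12, 16, 20),
                          exclude_z = integer()) {
  fid <- detect_fiducials(anat, brain_mask, affine)
  ctr_vox <- colMeans(arrayInd(which(brain_mask), dim(brain_mask)))
  brain_ctr <- as.vector(voxel_to_world(ctr_vox, affine))
  plane <- identify_plane_and_apex(fid, toward = brain_ctr)
  line <- entry_line(plane$base, plane$apex, toward = brain_ctr)
  spot <- stimulation_spot(line, brain_mask, affine)
  rois <- lapply(radii, function(r)
    split_hemispheres(place_roi(line, brain_mask, affine, r, exclude_z), line))
  names(rois) <- paste0("r", radii)
  list(fiducials = fid, plane = plane, line = line, spot = spot, rois = rois)
}
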