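test_that("fiducial detection recovers the capsule centroids sub-voxel", {
  cfg <- synth_config(seed = 8)
  an <- make_anatomy(cfg)
  fid <- detect_fiducials(an$anat, an$brain_mask, an$affine)
  expect_equal(nrow(fid$points), 7)
  # match detected to true capsules by nearest neighbour
  errs <- apply(an$truth$fiducials, 1, function(p)
    min(sqrt(colSums((t(fid$points) - p)^2))))
  expect_lt(max(errs), 0.5 * max(cfg$voxel_mm))
  # capsules no brighter than the brain cannot be detected
  dull <- an$anat
  dull[!an$brain_mask] <- pmin(dull[!an$brain_mask],
                               stats::quantile(an$anat[an$brain_mask], 0.999))
  expect_error(detect_fiducials(dull, an$brain_mask, an$affine))
})

test_that("fiducial centroids are equivariant under a rigid affine change", {
  cfg <- synth_config(seed = 9)
  an <- make_anatomy(cfg)
  fid <- detect_fiducials(an$anat, an$brain_mask, an$affine)
  # store the volume rotated 90 degrees in voxel space and give it the
  # affine that undoes the rotation: C[a,b,c] = A[b, d2+1-a, c], so the
  # rotated image occupies the SAME world space and must yield identical
  # world-space centroids
  d <- dim(an$anat)
  rot <- aperm(an$anat, c(2, 1, 3))[d[2]:1, , ]
  rot_mask <- aperm(an$brain_mask, c(2, 1, 3))[d[2]:1, , ]
  aff <- matrix(0, 4, 4); aff[4, 4] <- 1
  aff[1, 2] <- cfg$voxel_mm[1]
  aff[2, 1] <- -cfg$voxel_mm[2]; aff[2, 4] <- (d[2] - 1) * cfg$voxel_mm[2]
  aff[3, 3] <- cfg$voxel_mm[3]
  fid_rot <- detect_fiducials(rot, rot_mask, aff)
  errs <- apply(fid$points, 1, function(p)
    min(sqrt(colSums((t(fid_rot$points) - p)^2))))
  expect_lt(max(errs), 1e-6)
})

test_that("plane/apex identification is exact on clean hexagons and robust to noise", {
  pts <- exact_fiducials()
  fit <- identify_plane_and_apex(pts, toward = c(30, 30, 0))
  expect_equal(fit$apex, c(30, 30, 100), ignore_attr = TRUE)
  expect_lt(fit$rms, 1e-10)
  expect_equal(fit$normal, c(0, 0, -1), ignore_attr = TRUE)
  # Monte-Carlo: capsule noise sd 0.3 mm, correct apex in >= 99/100 trials
  set.seed(13)
  hits <- 0
  for (i in 1:100) {
    noisy <- pts + matrix(stats::rnorm(21, 0, 0.3), 7, 3)
    f <- tryCatch(identify_plane_and_apex(noisy, toward = c(30, 30, 0)),
                  error = function(e) NULL)
    if (!is.null(f) && sqrt(sum((f$apex - noisy[7, ])^2)) < 1e-9)
      hits <- hits + 1
  }
  expect_gte(hits, 99)
  # coplanar seven points are ambiguous
  flat <- pts; flat[7, 3] <- 90
  expect_error(identify_plane_and_apex(flat), "ambiguous")
})

test_that("the entry line runs through the apex along the plane normal", {
  pts <- exact_fiducials()
  line <- entry_line(pts[1:6, ], pts[7, ], toward = c(30, 30, 0))
  expect_equal(line$direction, c(0, 0, -1), ignore_attr = TRUE)
  expect_equal(line$hexagon_centre, c(30, 30, 90), ignore_attr = TRUE)
  # tilted plane: direction equals the analytic normal
  theta <- 0.3
  Rm <- rbind(c(1, 0, 0), c(0, cos(theta), -sin(theta)),
              c(0, sin(theta), cos(theta)))
  tilted <- t(Rm %*% t(pts))
  lt <- entry_line(tilted[1:6, ], tilted[7, ], toward = c(30, 0, 0))
  expected <- as.vector(Rm %*% c(0, 0, -1))
  expect_gt(sum(lt$direction * expected), 1 - 1e-9)
  # off-centre apex: line passes through the apex, not the hexagon centre
  off <- pts; off[7, 1] <- 37
  lo <- entry_line(off[1:6, ], off[7, ], toward = c(30, 30, 0))
  expect_equal(lo$apex[1], 37, ignore_attr = TRUE)
  expect_equal(lo$direction, c(0, 0, -1), ignore_attr = TRUE)
})

test_that("stimulation spot and ROI placement respect the brain geometry", {
  cfg <- synth_config(seed = 10)
  an <- make_anatomy(cfg)
  loc <- localize_coil(an$anat, an$brain_mask, an$affine)
  # round trip: recovered spot within one voxel of the true entry point
  expect_lt(sqrt(sum((loc$spot - an$truth$entry_point)^2)), max(cfg$voxel_mm))
  # ROI centres go strictly deeper as the radius grows; spheres inside brain
  depths <- vapply(loc$rois, `[[`, numeric(1), "depth_mm")
  expect_true(all(diff(depths) > 0))
  for (roi in loc$rois)
    expect_true(all(an$brain_mask[roi$voxels]))
  # a radius exceeding the brain is infeasible
  expect_error(place_roi(loc$line, an$brain_mask, an$affine, radius = 60),
               "sphere")
  # a line that misses the head has no spot
  miss <- loc$line; miss$direction <- c(0, 0, 1)
  expect_error(stimulation_spot(miss, an$brain_mask, an$affine),
               "intersect")
})

test_that("hemisphere split is balanced, tie-broken upward, and displacement is Euclidean", {
  cfg <- synth_config(seed = 11)
  an <- make_anatomy(cfg)
  loc <- localize_coil(an$anat, an$brain_mask, an$affine, radii = 16)
  roi <- loc$rois$r16
  expect_equal(roi$n_upper + roi$n_lower, nrow(roi$voxels))
  # near-symmetric: halves differ by at most one plane of voxels
  plane_vox <- sum(abs((roi$coords_mm - matrix(roi$center, nrow(roi$coords_mm),
                                               3, byrow = TRUE)) %*%
                         loc$line$direction) < max(cfg$voxel_mm) / 2)
  expect_lte(abs(roi$n_upper - roi$n_lower), plane_vox)
  # voxels exactly on the plane go to the upper half
  proj <- (roi$coords_mm - matrix(roi$center, nrow(roi$coords_mm), 3,
                                  byrow = TRUE)) %*% loc$line$direction
  on_plane <- abs(proj) < 1e-9
  if (any(on_plane)) expect_true(all(roi$upper[on_plane]))
  expect_equal(coil_displacement(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(coil_displacement(c(1, 2, 3), c(1, 2, 3)), 0)
})

test_that("a constructed 2.3-mm coil shift is recovered within half a voxel", {
  cfg <- synth_config(seed = 12)
  an1 <- make_anatomy(cfg)
  # second scan: whole coil (all seven capsules) shifted 2.3 mm laterally
  shift <- c(2.3, 0, 0)
  loc1 <- localize_coil(an1$anat, an1$brain_mask, an1$affine)
  f2 <- an1$truth$fiducials + matrix(shift, 7, 3, byrow = TRUE)
  plane2 <- identify_plane_and_apex(f2, toward = an1$truth$brain_centre)
  line2 <- entry_line(plane2$base, plane2$apex, toward = an1$truth$brain_centre)
  spot2 <- stimulation_spot(line2, an1$brain_mask, an1$affine)
  d <- coil_displacement(loc1$spot, spot2)
  expect_lt(abs(d - 2.3), 0.5 * max(cfg$voxel_mm))
})
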