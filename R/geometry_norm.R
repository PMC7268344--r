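#' Extract a colony's XY projection and XZ diametric cross-section
#'
#' The XY plane is the colony's pixel set with per-channel sum-projected
#' intensities (pixel units). The XZ plane is the stack slice through the
#' row nearest the colony centroid (optionally a slab of rows, averaged),
#' restricted to the colony's x-extent and converted to physical units
#' (micrometres); a voxel belongs to the colony's axial silhouette when its
#' detection-channel intensity exceeds the frame threshold `th`.
#'
#' @param stacks Named list of [zstack()]s, one per channel, sharing shape
#'   and pixel sizes.
#' @param colony A kept `colony_object`.
#' @param th Frame threshold used for the XZ silhouette mask.
#' @param detection_channel Name or index of the boundary-marker channel in
#'   `stacks` (default the first).
#' @param xz_slab_rows Number of adjacent rows to average for the XZ slice
#'   (default 1, the diametric plane only).
#' @return A `plane_set`: data frames `xy` (columns `x`, `y` in px plus one
#'   intensity column per channel) and `xz` (columns `x`, `z` in um plus
#'   intensities), the XY mass centre, pixel sizes, and slots for the
#'   alignment angle and scale factors filled by [align_planes()] and
#'   [compute_scales()].
#' @export
extract_planes <- function(stacks, colony, th, detection_channel = 1L,
                           xz_slab_rows = 1L) {
  if (inherits(stacks, "zstack")) stacks <- list(stacks)
  if (!length(stacks) || !all(vapply(stacks, inherits, logical(1), "zstack")))
    cp_abort("`stacks` must be a list of zstacks", "validation")
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    names(stacks) <- vapply(seq_along(stacks), function(i)
      if (nzchar(stacks[[i]]$channel_name)) stacks[[i]]$channel_name
      else sprintf("ch%d", i - 1L), character(1))
  d <- dim(stacks[[1]]$data)
  for (s in stacks) {
    if (!identical(dim(s$data), d))
      cp_abort("all channel stacks must share the same shape", "validation")
    if (!isTRUE(all.equal(s$pixel_xy_um, stacks[[1]]$pixel_xy_um)) ||
        !isTRUE(all.equal(s$pixel_z_um, stacks[[1]]$pixel_z_um)))
      cp_abort("all channel stacks must share pixel sizes", "validation")
  }
  if (!inherits(colony, "colony_object"))
    cp_abort("`colony` must be a colony_object", "validation")
  det <- if (is.character(detection_channel)) detection_channel
         else names(stacks)[detection_channel]
  if (is.na(det) || !det %in% names(stacks))
    cp_abort("detection channel not found in `stacks`", "validation")
  pxy <- stacks[[1]]$pixel_xy_um; pz <- stacks[[1]]$pixel_z_um

  rows <- colony$pixel_rows; cols <- colony$pixel_cols
  xy <- data.frame(x = cols, y = rows)
  for (ch in names(stacks))
    xy[[ch]] <- sum_projection(stacks[[ch]])[cbind(rows, cols)]
  attr(xy, "lattice_ij") <- cbind(cols, rows)

  r0 <- as.integer(round(colony$centroid_xy[["y"]]))
  half <- (as.integer(xz_slab_rows) - 1L) %/% 2L
  slab <- (r0 - half):(r0 - half + as.integer(xz_slab_rows) - 1L)
  slab <- slab[slab >= 1L & slab <= d[2]]
  if (!length(slab))
    cp_abort("colony centroid row outside the frame", "degenerate_colony")
  xr <- min(cols):max(cols)
  slice <- function(stack) {
    sl <- stack$data[, slab, xr, drop = FALSE]
    apply(sl, c(1, 3), mean)  # (Z, X), averaged over the slab
  }
  det_slice <- slice(stacks[[det]])
  keep <- det_slice > th
  if (!any(keep))
    cp_abort("no XZ voxels above threshold: degenerate colony",
             "degenerate_colony")
  zi <- row(det_slice)[keep]; xi <- col(det_slice)[keep]
  xz <- data.frame(x = (xr[xi] - 1) * pxy, z = (zi - 1) * pz)
  for (ch in names(stacks)) {
    s <- if (ch == det) det_slice else slice(stacks[[ch]])
    xz[[ch]] <- s[keep]
  }
  attr(xz, "lattice_ij") <- cbind(xi, zi)
  if (diff(range(xz$z)) <= 0)
    cp_abort("flat colony: all XZ voxels on one plane (height 0)",
             "degenerate_colony")
  structure(
    list(xy = xy, xz = xz,
         cm_xy = c(x = mean(xy$x), y = mean(xy$y)),
         cm_xz = NA, theta_rad = NA_real_,
         radius_R = NA_real_, height_H = NA_real_, base_h = NA_real_,
         pixel_xy_um = pxy, pixel_z_um = pz,
         colony_label = colony$label),
    class = "plane_set"
  )
}

#' Horizontally align an XZ point cloud by its principal axis
#'
#' The orientation of the silhouette's major axis is the image-moments
#' orientation `theta = atan2(2 * mu11, mu20 - mu02) / 2` computed from the
#' unweighted second-order central moments; all points are rotated about the
#' cloud's mass centre by `-theta`, which is an isometry and leaves the
#' principal axis horizontal.
#'
#' @param xz Data frame with columns `x` and `z` (physical units) and any
#'   number of intensity columns, which are carried through unchanged.
#' @return A list with `points` (the aligned data frame) and `theta_rad`
#'   (the estimated orientation of the major axis before alignment).
#' @export
align_xz <- function(xz) {
  if (!is.data.frame(xz) || !all(c("x", "z") %in% names(xz)))
    cp_abort("`xz` must be a data frame with columns x and z", "validation")
  if (nrow(xz) < 3L)
    cp_abort("need at least 3 XZ points to align", "alignment")
  cx <- mean(xz$x); cz <- mean(xz$z)
  dx <- xz$x - cx; dz <- xz$z - cz
  mu20 <- mean(dx^2); mu02 <- mean(dz^2); mu11 <- mean(dx * dz)
  tr <- mu20 + mu02
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lmin <- tr / 2 - disc
  if (tr <= 0 || lmin / tr < 1e-12)
    cp_abort("XZ points are collinear: cannot estimate orientation",
             "alignment")
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  co <- cos(theta); si <- sin(theta)
  out <- xz
  out$x <- cx + co * dx + si * dz   # rotation by -theta about the mass centre
  out$z <- cz - si * dx + co * dz
  list(points = out, theta_rad = theta)
}

#' Align the XZ plane of a plane_set
#'
#' Convenience wrapper around [align_xz()] that stores the aligned points,
#' the rotation angle and the XZ mass centre back into the `plane_set`.
#' With `align = FALSE` the points are kept as-is and `theta_rad` is set
#' to 0 (the XY projection never needs alignment).
#'
#' @param plane_set A `plane_set` from [extract_planes()].
#' @param align Perform the principal-axis alignment (default `TRUE`).
#' @return The updated `plane_set`.
#' @export
align_planes <- function(plane_set, align = TRUE) {
  if (!inherits(plane_set, "plane_set"))
    cp_abort("`plane_set` must be a plane_set", "validation")
  if (align) {
    al <- align_xz(plane_set$xz)
    plane_set$xz <- al$points
    plane_set$theta_rad <- al$theta_rad
  } else {
    plane_set$theta_rad <- 0
  }
  plane_set$cm_xz <- c(x = mean(plane_set$xz$x), z = mean(plane_set$xz$z))
  plane_set
}

#' Colony scale factors: radius, height and base height
#'
#' `R` is the maximum Euclidean distance (pixel units) from an XY point to
#' the XY mass centre; `H` is the axial extent (max z - min z, um) of the
#' aligned XZ silhouette and `h` its minimum z (where the colony base lays).
#'
#' @param plane_set An aligned `plane_set` (see [align_planes()]).
#' @return The `plane_set` with `radius_R`, `height_H` and `base_h` filled.
#' @export
compute_scales <- function(plane_set) {
  if (!inherits(plane_set, "plane_set"))
    cp_abort("`plane_set` must be a plane_set", "validation")
  if (is.na(plane_set$theta_rad))
    cp_abort("align the plane_set before computing scales", "validation")
  dx <- plane_set$xy$x - plane_set$cm_xy[["x"]]
  dy <- plane_set$xy$y - plane_set$cm_xy[["y"]]
  R <- max(sqrt(dx^2 + dy^2))
  if (R <= 0)
    cp_abort("zero colony radius", "degenerate_colony")
  zr <- range(plane_set$xz$z)
  H <- diff(zr)
  if (H <= 0)
    cp_abort("zero colony height", "degenerate_colony")
  plane_set$radius_R <- R
  plane_set$height_H <- H
  plane_set$base_h <- zr[1]
  plane_set
}

#' Map a colony onto the dimensionless reference frame
#'
#' Similarity transform to the normalized domain: XY coordinates are centred
#' on the XY mass centre and divided by the colony radius `R` (so
#' `x_hat, y_hat` lie in `[-1, 1]`); XZ x-coordinates are centred on the XZ
#' mass centre and divided by `R` expressed in micrometres, while z becomes
#' `(z - h) / H` in `[0, 1]`. Intensities are carried through unchanged.
#'
#' @param plane_set A `plane_set` with scales computed ([compute_scales()]).
#' @return A `normalized_cloud`: data frames `xy` and `xz` of dimensionless
#'   coordinates with per-channel intensities, plus the source colony label.
#' @export
normalize_points <- function(plane_set) {
  if (!inherits(plane_set, "plane_set"))
    cp_abort("`plane_set` must be a plane_set", "validation")
  R <- plane_set$radius_R; H <- plane_set$height_H; h <- plane_set$base_h
  if (!is.finite(R) || !is.finite(H))
    cp_abort("compute scales before normalizing", "validation")
  if (R <= 0 || H <= 0)
    cp_abort("zero scale factor", "validation")
  xy <- plane_set$xy
  xy$x <- (xy$x - plane_set$cm_xy[["x"]]) / R
  xy$y <- (xy$y - plane_set$cm_xy[["y"]]) / R
  xz <- plane_set$xz
  R_um <- R * plane_set$pixel_xy_um
  xz$x <- (xz$x - plane_set$cm_xz[["x"]]) / R_um
  xz$z <- (xz$z - h) / H
  structure(
    list(xy = xy, xz = xz, colony_label = plane_set$colony_label,
         radius_R = R, height_H = H, base_h = h,
         theta_rad = plane_set$theta_rad),
    class = "normalized_cloud"
  )
}

#' Full geometric normalization of one colony
#'
#' Chains [extract_planes()], [align_planes()], [compute_scales()] and
#' [normalize_points()].
#'
#' @inheritParams extract_planes
#' @param align Align the XZ plane (default `TRUE`).
#' @return A list with `cloud` (the `normalized_cloud`) and `planes` (the
#'   final `plane_set`, carrying R, H, h and theta for audit).
#' @export
normalize_colony <- function(stacks, colony, th, detection_channel = 1L,
                             xz_slab_rows = 1L, align = TRUE) {
  ps <- extract_planes(stacks, colony, th,
                       detection_channel = detection_channel,
                       xz_slab_rows = xz_slab_rows)
  ps <- align_planes(ps, align = align)
  ps <- compute_scales(ps)
  list(cloud = normalize_points(ps), planes = ps)
}
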