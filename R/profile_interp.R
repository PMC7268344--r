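#' Fixed dimensionless reference grids
#'
#' Regular lattices covering the normalized XY domain `[-1, 1]^2` and XZ
#' domain `[-1, 1] x [0, 1]`, boundaries inclusive. Defaults follow the
#' method's reference resolution: 256 x 256 points for XY projections and
#' 256 x 10 points for XZ planes.
#'
#' @param grid_xy Integer pair `(n_x, n_y)` for the XY lattice.
#' @param grid_xz Integer pair `(n_x, n_z)` for the XZ lattice.
#' @return A `reference_grid` with strictly increasing axis vectors
#'   `xy_x`, `xy_y`, `xz_x`, `xz_z`.
#' @export
reference_grid <- function(grid_xy = c(256L, 256L), grid_xz = c(256L, 10L)) {
  chk <- function(v, name) {
    if (length(v) != 2L || any(v < 2) || any(v != round(v)))
      cp_abort(sprintf("`%s` must be two integers >= 2", name), "validation")
    as.integer(v)
  }
  grid_xy <- chk(grid_xy, "grid_xy"); grid_xz <- chk(grid_xz, "grid_xz")
  structure(
    list(xy_x = seq(-1, 1, length.out = grid_xy[1]),
         xy_y = seq(-1, 1, length.out = grid_xy[2]),
         xz_x = seq(-1, 1, length.out = grid_xz[1]),
         xz_z = seq(0, 1, length.out = grid_xz[2]),
         dims_xy = grid_xy, dims_xz = grid_xz),
    class = "reference_grid"
  )
}

# Triangulate a set of integer lattice sites by pixel adjacency: every
# complete unit cell contributes two triangles. For points sampled from a
# pixel grid this is a Delaunay triangulation of the (unrotated) lattice,
# carried unchanged through the similarity transform, and is immune to the
# cocircular degeneracies that defeat general-purpose Delaunay codes on
# regular grids.
lattice_triangles <- function(ij) {
  key <- paste(ij[, 1], ij[, 2])
  idx <- seq_len(nrow(ij))
  m10 <- match(paste(ij[, 1] + 1L, ij[, 2]), key)
  m01 <- match(paste(ij[, 1], ij[, 2] + 1L), key)
  m11 <- match(paste(ij[, 1] + 1L, ij[, 2] + 1L), key)
  ok <- !is.na(m10) & !is.na(m01) & !is.na(m11)
  rbind(cbind(idx[ok], m10[ok], m01[ok]),
        cbind(m10[ok], m11[ok], m01[ok]))
}

# Interpolate one scattered plane onto a lattice. Returns a matrix of shape
# (length(yo), length(xo)); lattice points outside the convex hull of the
# data are NA (never extrapolated). Exact duplicate coordinates are averaged
# before triangulation. When the points carry pixel-lattice indices, the
# triangulation is built from lattice adjacency instead of a general
# Delaunay code.
interp_scattered <- function(x, y, values, xo, yo, lattice = NULL) {
  tr <- NULL
  if (!is.null(lattice) && nrow(lattice) == length(x)) {
    tr <- lattice_triangles(lattice)
    if (nrow(tr) < 1L) tr <- NULL  # e.g. a single row of pixels
  }
  if (is.null(tr)) {
    key <- paste(x, y, sep = "\r")
    if (anyDuplicated(key)) {
      f <- factor(key, levels = unique(key))
      x <- tapply(x, f, mean)[levels(f)]
      y <- tapply(y, f, mean)[levels(f)]
      values <- lapply(values, function(v) as.vector(tapply(v, f, mean)[levels(f)]))
      x <- as.vector(x); y <- as.vector(y)
    }
    if (length(x) < 4L)
      cp_abort("fewer than 4 distinct points: cannot triangulate",
               "interpolation")
    tm <- tryCatch(suppressWarnings(interp::tri.mesh(x, y)),
                   error = function(e)
                     cp_abort(sprintf("Delaunay triangulation failed (%s)",
                                      conditionMessage(e)), "interpolation"))
    tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
    if (nrow(tr) < 1L)
      cp_abort("degenerate (collinear) point set: cannot triangulate",
               "interpolation")
  }
  nx <- length(xo); ny <- length(yo)
  qx <- rep(xo, each = ny); qy <- rep(yo, times = nx)
  lapply(values, function(v) {
    g <- cp_estimate_gradients(x, y, v, tr)
    matrix(cp_ct_eval(x, y, v, g, tr, qx, qy), nrow = ny, ncol = nx)
  })
}

#' Interpolate a normalized colony onto the reference grids
#'
#' Piecewise-cubic C1 (Clough-Tocher) interpolation on a Delaunay
#' triangulation of the scattered normalized coordinates, per plane and per
#' channel. Grid points outside the convex hull of the colony's data are
#' marked invalid (`NA`), never extrapolated. Duplicate coordinates (several
#' voxels mapping to one normalized point) are averaged before
#' triangulation.
#'
#' @param cloud A `normalized_cloud` from [normalize_points()].
#' @param grid A [reference_grid()].
#' @return A `normalized_profile`: per-channel value matrices `xy_values`
#'   (shape `n_y x n_x`) and `xz_values` (shape `n_z x n_x`), validity masks
#'   `xy_valid` / `xz_valid`, and the colony id.
#' @export
interpolate_to_grid <- function(cloud, grid = reference_grid()) {
  if (!inherits(cloud, "normalized_cloud"))
    cp_abort("`cloud` must be a normalized_cloud", "validation")
  if (!inherits(grid, "reference_grid"))
    cp_abort("`grid` must be a reference_grid", "validation")
  channels_xy <- setdiff(names(cloud$xy), c("x", "y"))
  channels_xz <- setdiff(names(cloud$xz), c("x", "z"))
  xy_vals <- interp_scattered(cloud$xy$x, cloud$xy$y,
                              cloud$xy[channels_xy],
                              grid$xy_x, grid$xy_y,
                              lattice = attr(cloud$xy, "lattice_ij"))
  xz_vals <- interp_scattered(cloud$xz$x, cloud$xz$z,
                              cloud$xz[channels_xz],
                              grid$xz_x, grid$xz_z,
                              lattice = attr(cloud$xz, "lattice_ij"))
  structure(
    list(xy_values = xy_vals, xz_values = xz_vals,
         xy_valid = !is.na(xy_vals[[1]]), xz_valid = !is.na(xz_vals[[1]]),
         grid = grid, colony_id = cloud$colony_label),
    class = "normalized_profile"
  )
}

#' Stack replicate profiles for statistics
#'
#' Collects interpolated profiles that share a reference grid into
#' replicate-indexed arrays, one per plane and channel, tracking the
#' per-grid-point replicate count (the number of profiles valid at that
#' point).
#'
#' @param profiles Non-empty list of `normalized_profile`s on identical
#'   grids.
#' @param group_key Condition label attached to the stack (e.g. `"M"`).
#' @return A `profile_stack`: lists `xy` and `xz` of arrays with dimensions
#'   `(replicate, grid rows, grid cols)` per channel, count matrices `xy_n`
#'   and `xz_n`, the grid, colony ids and the condition label.
#' @export
stack_profiles <- function(profiles, group_key = "") {
  if (!length(profiles))
    cp_abort("empty profile list: nothing to stack", "validation")
  if (!all(vapply(profiles, inherits, logical(1), "normalized_profile")))
    cp_abort("`profiles` must be a list of normalized_profiles", "validation")
  g0 <- profiles[[1]]$grid
  for (p in profiles) {
    if (!identical(p$grid$dims_xy, g0$dims_xy) ||
        !identical(p$grid$dims_xz, g0$dims_xz))
      cp_abort("profiles use mismatched reference grids", "validation")
  }
  nrep <- length(profiles)
  build <- function(plane_field) {
    chans <- names(profiles[[1]][[plane_field]])
    out <- list()
    for (ch in chans) {
      m0 <- profiles[[1]][[plane_field]][[ch]]
      arr <- array(NA_real_, c(nrep, nrow(m0), ncol(m0)))
      for (i in seq_len(nrep)) arr[i, , ] <- profiles[[i]][[plane_field]][[ch]]
      out[[ch]] <- arr
    }
    out
  }
  xy <- build("xy_values"); xz <- build("xz_values")
  count <- function(arr) {
    n <- colSums(!is.na(arr), dims = 1)
    matrix(n, nrow = dim(arr)[2], ncol = dim(arr)[3])
  }
  structure(
    list(xy = xy, xz = xz,
         xy_n = count(xy[[1]]), xz_n = count(xz[[1]]),
         grid = g0, condition = as.character(group_key),
         colony_ids = vapply(profiles, function(p)
           as.character(p$colony_id %||% NA_character_), character(1))),
    class = "profile_stack"
  )
}
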