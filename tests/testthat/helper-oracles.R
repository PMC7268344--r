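# Brute-force reference implementations, kept independent of the package's
# code paths, plus small fixture builders.

# per-pixel loop sum projection
oracle_sum_projection <- function(arr) {
  d <- dim(arr)
  out <- matrix(0, d[2], d[3])
  for (i in seq_len(d[2]))
    for (j in seq_len(d[3]))
      for (z in seq_len(d[1]))
        out[i, j] <- out[i, j] + arr[z, i, j]
  out
}

# queue-based flood fill labeling
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# labelings as comparable canonical partitions (pixel-index sets ordered by
# their smallest member, so label numbering is irrelevant)
part_sorted <- function(p) unname(p[order(vapply(p, min, numeric(1)))])

canonical_partition <- function(lab) {
  idx <- which(lab > 0)
  part_sorted(lapply(split(idx, lab[idx]), sort))
}

# per-grid-point loop statistics over replicate stack (rep, ny, nx)
oracle_point_stats <- function(arr) {
  d <- dim(arr)
  mn <- md <- sdv <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    v <- arr[, i, j]; v <- v[!is.na(v)]
    if (length(v) >= 1) { mn[i, j] <- mean(v); md[i, j] <- median(v) }
    if (length(v) >= 2) sdv[i, j] <- sd(v)
  }
  list(mean = mn, median = md, std = sdv)
}

make_disk_mask <- function(nr, nc, cy, cx, r) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

make_ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if (((i - cy) / ry)^2 + ((j - cx) / rx)^2 <= 1) m[i, j] <- TRUE
  m
}

# hand-built plane_set for unit tests of the geometry operations
make_plane_set <- function(xy, xz, pixel_xy_um = 1, pixel_z_um = 1,
                           theta_rad = NA_real_) {
  structure(
    list(xy = xy, xz = xz,
         cm_xy = c(x = mean(xy$x), y = mean(xy$y)),
         cm_xz = c(x = mean(xz$x), z = mean(xz$z)),
         theta_rad = theta_rad,
         radius_R = NA_real_, height_H = NA_real_, base_h = NA_real_,
         pixel_xy_um = pixel_xy_um, pixel_z_um = pixel_z_um,
         colony_label = 1L),
    class = "plane_set")
}

# hand-built normalized cloud (already dimensionless)
make_cloud <- function(xy, xz, label = 1L) {
  structure(list(xy = xy, xz = xz, colony_label = label,
                 radius_R = NA, height_H = NA, base_h = NA, theta_rad = NA),
            class = "normalized_cloud")
}

# dense dome-interior point cloud (an idealized XZ silhouette): points on a
# lattice inside z <= h * (1 - (x/a)^2), symmetric about x = 0
dome_silhouette <- function(a = 50, h = 6, dx = 0.5, dz = 0.25) {
  xs <- seq(-a, a, by = dx)
  pts <- do.call(rbind, lapply(xs, function(x) {
    zmax <- h * (1 - (x / a)^2)
    zz <- seq(0, zmax, by = dz)
    if (!length(zz)) return(NULL)
    cbind(x = x, z = zz)
  }))
  as.data.frame(pts)
}

rotate_xz <- function(df, theta, cx = 0, cz = 0) {
  out <- df
  dx <- df$x - cx; dz <- df$z - cz
  out$x <- cx + cos(theta) * dx - sin(theta) * dz
  out$z <- cz + sin(theta) * dx + cos(theta) * dz
  out
}
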