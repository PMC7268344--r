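detect_one <- function(sim) {
  proy <- sum_projection(sim$stacks$detection)
  th <- compute_threshold(proy)
  obs <- label_components(filter_and_binarize(proy, th))
  flt <- apply_shape_filters(obs)
  list(th = th, kept = flt$kept)
}

test_that("extracted planes cover the colony pixel set and its diameter", {
  sim <- generate_stack(colony_spec(c(60, 64), radius_px = 30,
                                    height_um = 12),
                        frame = c(160L, 160L, 10L), pixel_z_um = 2,
                        seed = 1)
  det <- detect_one(sim)
  ob <- det$kept[[1]]
  ps <- extract_planes(sim$stacks, ob, det$th,
                       detection_channel = "detection")
  expect_identical(nrow(ps$xy), ob$area_px)
  # XZ x-range equals the colony diameter within one pixel either side
  xr_px <- diff(range(ps$xz$x)) / sim$stacks$detection$pixel_xy_um
  expect_lt(abs(xr_px - 2 * 30), 2.5)
  expect_identical(sort(names(ps$xy)), sort(c("x", "y", "detection", "reporter")))
})

test_that("a flat single-plane colony is a degenerate-colony error", {
  a <- array(0, c(1, 20, 20))
  a[1, , ][make_disk_mask(20, 20, 10, 10, 6)] <- 120
  st <- list(det = zstack(a, "det", 1, 1))
  ob <- label_components(a[1, , ] > 10)[[1]]
  expect_error(extract_planes(st, ob, th = 10, detection_channel = "det"),
               class = "colonyprof_degenerate_colony_error")
})

test_that("principal-axis alignment recovers synthetic rotations exactly", {
  sil <- dome_silhouette(a = 50, h = 6)
  al0 <- align_xz(sil)
  expect_equal(al0$theta_rad, 0, tolerance = 1e-9)
  expect_equal(al0$points$x, sil$x, tolerance = 1e-9)
  expect_equal(al0$points$z, sil$z, tolerance = 1e-9)

  rot <- rotate_xz(sil, 0.1)
  al <- align_xz(rot)
  expect_lt(abs(al$theta_rad - 0.1), 1e-6)
  # aligned cloud matches the original up to the (translation-invariant)
  # centroid shift
  expect_equal(al$points$x - mean(al$points$x), sil$x - mean(sil$x),
               tolerance = 1e-6)
  expect_equal(al$points$z - mean(al$points$z), sil$z - mean(sil$z),
               tolerance = 1e-6)
  # re-estimating on the aligned cloud gives a horizontal principal axis
  expect_lt(abs(align_xz(al$points)$theta_rad), 1e-6)
})

test_that("alignment is an isometry on coordinates", {
  set.seed(13)
  pts <- data.frame(x = runif(40, -30, 30), z = runif(40, 0, 8),
                    I = runif(40))
  al <- align_xz(pts)
  i <- sample(40, 15); j <- sample(40, 15)
  d0 <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$z[i] - pts$z[j])^2)
  d1 <- sqrt((al$points$x[i] - al$points$x[j])^2 +
             (al$points$z[i] - al$points$z[j])^2)
  expect_equal(d1, d0, tolerance = 1e-9)
  expect_identical(al$points$I, pts$I)  # intensities untouched
})

test_that("collinear XZ clouds cannot be aligned", {
  vert <- data.frame(x = rep(2, 10), z = 1:10)
  expect_error(align_xz(vert), class = "colonyprof_alignment_error")
  expect_error(align_xz(data.frame(x = 1:2, z = c(0, 0))),
               class = "colonyprof_alignment_error")
})

test_that("scale factors R, H, h follow their definitions", {
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  xy <- data.frame(x = 100 + 50 * cos(ang), y = 80 + 50 * sin(ang), I = 1)
  xz <- data.frame(x = seq(-40, 40, by = 2), z = NA, I = 1)
  xz$z <- 12 + 30 * (1 - (xz$x / 40)^2)  # spans [12, 42]
  ps <- make_plane_set(xy, xz, theta_rad = 0)
  ps <- compute_scales(ps)
  expect_equal(ps$radius_R, 50, tolerance = 1e-9)
  expect_equal(ps$height_H, 30, tolerance = 1e-9)
  expect_equal(ps$base_h, 12, tolerance = 1e-9)

  flat <- make_plane_set(xy, data.frame(x = 1:5, z = rep(3, 5), I = 1),
                         theta_rad = 0)
  expect_error(compute_scales(flat),
               class = "colonyprof_degenerate_colony_error")
})

test_that("generator ground truth for R and H is recovered within a voxel", {
  sim <- generate_stack(colony_spec(c(90, 90), radius_px = 36,
                                    height_um = 14),
                        frame = c(280L, 280L, 12L), pixel_z_um = 1.5,
                        seed = 2)
  det <- detect_one(sim)
  nc <- normalize_colony(sim$stacks, det$kept[[1]], det$th,
                         detection_channel = "detection")
  expect_lt(abs(nc$planes$radius_R - 36), 1.5)
  expect_lt(abs(nc$planes$height_H - 14), 1.6)  # one z-plane spacing
})

test_that("normalized coordinates are bounded and anchored by construction", {
  sim <- generate_stack(colony_spec(c(60, 60), radius_px = 28,
                                    height_um = 12),
                        frame = c(128L, 128L, 10L), seed = 3)
  det <- detect_one(sim)
  nc <- normalize_colony(sim$stacks, det$kept[[1]], det$th,
                         detection_channel = "detection")
  cl <- nc$cloud
  r_xy <- sqrt(cl$xy$x^2 + cl$xy$y^2)
  expect_lte(max(abs(cl$xy$x)), 1 + 1e-9)
  expect_lte(max(abs(cl$xy$y)), 1 + 1e-9)
  expect_equal(max(r_xy), 1, tolerance = 1e-12)       # farthest point defines R
  expect_equal(min(cl$xz$z), 0, tolerance = 1e-12)    # lowest point -> 0
  expect_equal(max(cl$xz$z), 1, tolerance = 1e-12)    # highest point -> 1
})

test_that("the normalized cloud is similarity-invariant and intensity-preserving", {
  set.seed(17)
  ang <- runif(400, 0, 2 * pi); rad <- sqrt(runif(400))
  xy <- data.frame(x = 30 * rad * cos(ang) + 50, y = 30 * rad * sin(ang) + 40,
                   I = runif(400, 10, 200))
  sil <- dome_silhouette(a = 45, h = 9, dx = 1.5, dz = 0.75)
  xz <- cbind(sil, I = runif(nrow(sil), 10, 200))

  norm_of <- function(xy, xz, pxy = 1) {
    ps <- make_plane_set(xy, xz, pixel_xy_um = pxy)
    ps <- align_planes(ps)
    normalize_points(compute_scales(ps))
  }
  a <- norm_of(xy, xz)

  # uniform scale x2, translation, and XZ rotation by 0.07 rad
  xy2 <- transform(xy, x = 2 * x + 17, y = 2 * y - 5)
  xz2 <- rotate_xz(transform(xz, x = 2 * x + 30, z = 2 * z + 4), 0.07,
                   cx = 30, cz = 4)
  b <- norm_of(xy2, xz2)

  expect_equal(b$xy$x, a$xy$x, tolerance = 1e-9)
  expect_equal(b$xy$y, a$xy$y, tolerance = 1e-9)
  expect_equal(b$xz$x, a$xz$x, tolerance = 1e-6)
  expect_equal(b$xz$z, a$xz$z, tolerance = 1e-6)
  # intensity multisets unchanged by normalization
  expect_identical(sort(a$xy$I), sort(xy$I))
  expect_identical(sort(a$xz$I), sort(xz$I))
  expect_identical(b$xz$I, a$xz$I)
})
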