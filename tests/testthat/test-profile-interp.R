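scatter_cloud <- function(n_xy = 900, n_xz = 500, f_xy, f_xz, seed = 19) {
  set.seed(seed)
  # cover the full normalized domains so every grid point is in-hull
  xy <- data.frame(x = runif(n_xy, -1.05, 1.05), y = runif(n_xy, -1.05, 1.05))
  xy$I <- f_xy(xy$x, xy$y)
  xz <- data.frame(x = runif(n_xz, -1.05, 1.05), z = runif(n_xz, -0.05, 1.05))
  xz$I <- f_xz(xz$x, xz$z)
  make_cloud(xy, xz)
}

test_that("reference grids cover the closed normalized domains at the default resolution", {
  g <- reference_grid()
  expect_identical(g$dims_xy, c(256L, 256L))
  expect_identical(g$dims_xz, c(256L, 10L))
  expect_equal(range(g$xy_x), c(-1, 1))
  expect_equal(range(g$xy_y), c(-1, 1))
  expect_equal(range(g$xz_z), c(0, 1))
  expect_true(all(diff(g$xy_x) > 0) && all(diff(g$xz_z) > 0))
  expect_error(reference_grid(c(1, 5)), class = "colonyprof_validation_error")
})

test_that("linear fields are reproduced within 1e-6 on the default grids", {
  cl <- scatter_cloud(f_xy = function(x, y) 2 * x + 3 * y - 1,
                      f_xz = function(x, z) 0.5 * x - 2 * z + 4)
  prof <- interpolate_to_grid(cl, reference_grid())
  g <- reference_grid()
  want_xy <- outer(g$xy_y, g$xy_x, function(y, x) 2 * x + 3 * y - 1)
  err_xy <- abs(prof$xy_values$I - want_xy)
  expect_lt(max(err_xy[prof$xy_valid]), 1e-6)
  want_xz <- outer(g$xz_z, g$xz_x, function(z, x) 0.5 * x - 2 * z + 4)
  err_xz <- abs(prof$xz_values$I - want_xz)
  expect_lt(max(err_xz[prof$xz_valid]), 1e-6)
  # near-complete coverage (the random hull can miss extreme corners)
  expect_gt(mean(prof$xy_valid), 0.99)
  expect_gt(mean(prof$xz_valid), 0.99)
})

test_that("interpolation honours data sites and reproduces constants", {
  g <- reference_grid(c(32L, 32L), c(16L, 8L))
  set.seed(23)
  xy <- data.frame(x = runif(300, -1, 1), y = runif(300, -1, 1))
  xy$I <- sin(xy$x * 3) + cos(xy$y * 2)
  # plant data points exactly on grid nodes
  xy$x[1:3] <- g$xy_x[c(5, 17, 30)]
  xy$y[1:3] <- g$xy_y[c(8, 22, 11)]
  xy$I <- sin(xy$x * 3) + cos(xy$y * 2)
  xz <- data.frame(x = runif(200, -1, 1), z = runif(200, 0, 1))
  xz$I <- 5
  prof <- interpolate_to_grid(make_cloud(xy, xz), g)
  expect_equal(prof$xy_values$I[8, 5], xy$I[1], tolerance = 1e-9)
  expect_equal(prof$xy_values$I[22, 17], xy$I[2], tolerance = 1e-9)
  expect_equal(prof$xy_values$I[11, 30], xy$I[3], tolerance = 1e-9)
  vals <- prof$xz_values$I[prof$xz_valid]
  expect_equal(vals, rep(5, length(vals)), tolerance = 1e-9)
})

test_that("grid points outside the data hull are invalid, never extrapolated", {
  set.seed(29)
  ang <- runif(600, 0, 2 * pi); r <- sqrt(runif(600)) * 0.8
  xy <- data.frame(x = r * cos(ang), y = r * sin(ang), I = r)
  xz <- data.frame(x = runif(100, -1, 1), z = runif(100, 0, 1),
                   I = runif(100))
  g <- reference_grid(c(64L, 64L), c(16L, 6L))
  prof <- interpolate_to_grid(make_cloud(xy, xz), g)
  rr <- sqrt(outer(g$xy_y^2, g$xy_x^2, "+"))
  expect_true(all(is.na(prof$xy_values$I[rr > 0.81])))
  expect_true(all(!prof$xy_valid[rr > 0.81]))
  expect_true(all(is.finite(prof$xy_values$I[prof$xy_valid])))
})

test_that("exact duplicate points are averaged before triangulation", {
  xy <- data.frame(x = c(0.25, 0.25, -0.5, 0.5, 0, -0.6, 0.1),
                   y = c(0.25, 0.25, -0.5, -0.5, 0.6, 0.3, -0.2),
                   I = c(10, 20, 1, 1, 1, 1, 1))
  xz <- data.frame(x = c(-1, 1, -1, 1, 0), z = c(0, 0, 1, 1, 0.5),
                   I = 1:5)
  # a bespoke grid whose node (2, 2) coincides with the duplicated site
  g3 <- structure(list(xy_x = c(-1, 0.25, 1), xy_y = c(-1, 0.25, 1),
                       xz_x = c(-1, 0, 1), xz_z = c(0, 0.5, 1),
                       dims_xy = c(3L, 3L), dims_xz = c(3L, 3L)),
                  class = "reference_grid")
  prof3 <- interpolate_to_grid(make_cloud(xy, xz), g3)
  expect_equal(prof3$xy_values$I[2, 2], 15, tolerance = 1e-9)
})

test_that("degenerate point sets raise classed interpolation failures", {
  good_xz <- data.frame(x = c(-1, 1, -1, 1), z = c(0, 0, 1, 1), I = 1)
  few <- make_cloud(data.frame(x = c(0, 1, 0), y = c(0, 0, 1), I = 1),
                    good_xz)
  expect_error(interpolate_to_grid(few, reference_grid(c(4L, 4L), c(4L, 4L))),
               class = "colonyprof_interpolation_error")
  coll <- make_cloud(data.frame(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1), I = 1),
                     good_xz)
  expect_error(interpolate_to_grid(coll, reference_grid(c(4L, 4L), c(4L, 4L))),
               class = "colonyprof_interpolation_error")
})

test_that("refining the grid leaves values at shared lattice points nearly unchanged", {
  f <- function(x, y) exp(-(x^2 + y^2)) * cos(2 * x)
  cl <- scatter_cloud(2000, 500, f, function(x, z) 1)
  # 65x65 and 129x129 grids share the 65x65 lattice (every 2nd node)
  p1 <- interpolate_to_grid(cl, reference_grid(c(65L, 65L), c(8L, 4L)))
  p2 <- interpolate_to_grid(cl, reference_grid(c(129L, 129L), c(8L, 4L)))
  shared1 <- p1$xy_values$I
  shared2 <- p2$xy_values$I[seq(1, 129, 2), seq(1, 129, 2)]
  ok <- !is.na(shared1) & !is.na(shared2)
  expect_equal(shared2[ok], shared1[ok], tolerance = 1e-12)  # same interpolant
})

test_that("the interpolant agrees with an independent Clough-Tocher implementation", {
  set.seed(31)
  n <- 400
  x <- runif(n, -1, 1); y <- runif(n, -1, 1)
  f <- exp(-(x^2 + y^2)) + 0.3 * sin(2 * x) * cos(y)
  qx <- runif(300, -0.7, 0.7); qy <- runif(300, -0.7, 0.7)
  tmp <- withr::local_tempdir()
  datf <- file.path(tmp, "dat.csv"); qf <- file.path(tmp, "q.csv")
  outf <- file.path(tmp, "out.csv")
  write.csv(data.frame(x = x, y = y, f = f), datf, row.names = FALSE)
  write.csv(data.frame(x = qx, y = qy), qf, row.names = FALSE)
  py <- file.path(tmp, "ct.py")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.interpolate import CloughTocher2DInterpolator",
    "d = np.loadtxt(sys.argv[1], delimiter=',', skiprows=1)",
    "q = np.loadtxt(sys.argv[2], delimiter=',', skiprows=1)",
    "ip = CloughTocher2DInterpolator(d[:, :2], d[:, 2])",
    "np.savetxt(sys.argv[3], ip(q))"), py)
  st <- system2("python", c(py, datf, qf, outf), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(outf), info = paste(st, collapse = "\n"))
  ref <- scan(outf, quiet = TRUE)

  # evaluate this package's interpolant at the same scattered queries
  tm <- interp::tri.mesh(x, y)
  tr <- interp::triangles(tm)[, 1:3]
  gr <- colonyprof:::cp_estimate_gradients(x, y, f, tr)
  mine <- colonyprof:::cp_ct_eval(x, y, f, gr, tr, qx, qy)
  ok <- !is.na(mine) & !is.na(ref)
  expect_gt(mean(ok), 0.95)
  # same family of C1 cubics; differences come from gradient estimation
  expect_lt(max(abs(mine[ok] - ref[ok])), 0.05)
  expect_lt(mean(abs(mine[ok] - ref[ok])), 0.005)
})

test_that("profile stacking tracks per-point replicate counts", {
  cl <- scatter_cloud(500, 300, function(x, y) x + y, function(x, z) x * z)
  g <- reference_grid(c(16L, 16L), c(8L, 4L))
  p <- interpolate_to_grid(cl, g)
  st <- stack_profiles(list(p, p, p), "M")
  expect_identical(dim(st$xy$I), c(3L, 16L, 16L))
  expect_true(all(st$xy_n[p$xy_valid] == 3))
  expect_identical(st$condition, "M")

  # disjoint valid masks: counts reflect the union bookkeeping
  p1 <- p; p2 <- p
  half <- col(p$xy_values$I) <= 8
  p1$xy_values$I[!half] <- NA; p1$xy_valid <- !is.na(p1$xy_values$I)
  p2$xy_values$I[half] <- NA; p2$xy_valid <- !is.na(p2$xy_values$I)
  st2 <- stack_profiles(list(p1, p2), "D")
  expect_true(all(st2$xy_n[p$xy_valid] == 1))

  expect_error(stack_profiles(list(), "E"),
               class = "colonyprof_validation_error")
  pq <- interpolate_to_grid(cl, reference_grid(c(8L, 8L), c(8L, 4L)))
  expect_error(stack_profiles(list(p, pq), "F"),
               class = "colonyprof_validation_error")
})
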