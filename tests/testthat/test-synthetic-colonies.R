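detect_objects <- function(sim) {
  proy <- sum_projection(sim$stacks$detection)
  th <- compute_threshold(proy)
  obs <- label_components(filter_and_binarize(proy, th))
  flt <- apply_shape_filters(obs)
  list(th = th, objects = obs, kept = flt$kept, rejected = flt$rejected)
}

test_that("generation is deterministic per seed, down to the bit", {
  sp <- colony_spec(c(60, 60), 25, 10, pattern = pattern_ring(0.5),
                    noise_sd = 4)
  a <- generate_stack(sp, frame = c(128L, 128L, 10L), seed = 7)
  b <- generate_stack(sp, frame = c(128L, 128L, 10L), seed = 7)
  expect_identical(a$stacks$detection$data, b$stacks$detection$data)
  expect_identical(a$stacks$reporter$data, b$stacks$reporter$data)
  c_ <- generate_stack(sp, frame = c(128L, 128L, 10L), seed = 8)
  expect_false(identical(a$stacks$reporter$data, c_$stacks$reporter$data))
})

test_that("invalid colony layouts are rejected up front", {
  expect_error(
    generate_stack(colony_spec(c(10, 64), 25, 10),
                   frame = c(128L, 128L, 10L)),
    class = "colonyprof_validation_error")          # XY overflow
  expect_error(
    generate_stack(colony_spec(c(64, 64), 25, 30),
                   frame = c(128L, 128L, 10L), pixel_z_um = 2),
    class = "colonyprof_validation_error")          # taller than the stack
  two <- list(colony_spec(c(50, 64), 25, 8), colony_spec(c(80, 64), 25, 8))
  expect_error(generate_stack(two, frame = c(160L, 128L, 10L)),
               class = "colonyprof_validation_error")  # overlap
  sim <- generate_stack(two, frame = c(160L, 128L, 10L),
                        allow_overlap = TRUE, seed = 1)
  expect_s3_class(sim, "colony_sim")
})

test_that("K well-separated colonies yield exactly K kept objects", {
  specs <- list(colony_spec(c(70, 70), 30, 12, pattern = pattern_uniform(90)),
                colony_spec(c(210, 80), 24, 10, pattern = pattern_gaussian()),
                colony_spec(c(140, 200), 34, 13, pattern = pattern_ring(0.5)))
  sim <- generate_stack(specs, frame = c(280L, 280L, 12L), seed = 9)
  det <- detect_objects(sim)
  expect_length(det$objects, 3L)
  expect_length(det$kept, 3L)
  # noise: single frame, noisy colonies, still K kept
  specs_n <- lapply(specs, function(s) { s$noise_sd <- 5; s })
  det_n <- detect_objects(generate_stack(specs_n, frame = c(280L, 280L, 12L),
                                         seed = 10))
  expect_length(det_n$kept, 3L)
})

test_that("a merged colony pair is detected as one object and rejected by the axis-ratio rule", {
  pair <- list(colony_spec(c(90, 110), 28, 10),
               colony_spec(c(130, 110), 28, 10))  # centres 40 px apart
  sim <- generate_stack(pair, frame = c(220L, 220L, 10L),
                        allow_overlap = TRUE, seed = 11)
  det <- detect_objects(sim)
  expect_length(det$objects, 1L)
  expect_length(det$kept, 0L)
  expect_identical(det$rejected[[1]]$rejection_reason, "axis-ratio")
})

test_that("a tilted baseline is recovered by the alignment stage within 1e-3 rad", {
  sp <- colony_spec(c(160, 160), radius_px = 48, height_um = 10,
                    tilt_rad = 0.1, base_um = 10)
  sim <- generate_stack(sp, frame = c(320L, 320L, 40L),
                        pixel_xy_um = 1.5, pixel_z_um = 0.75,
                        background_level = 0, seed = 13)
  det <- detect_objects(sim)
  expect_length(det$kept, 1L)
  ps <- extract_planes(sim$stacks, det$kept[[1]], det$th,
                       detection_channel = "detection")
  al <- align_xz(ps$xz)
  expect_lt(abs(al$theta_rad - 0.1), 1e-3)
})

test_that("a programmed ring pattern is recovered in the normalized profile", {
  sp <- colony_spec(c(120, 120), radius_px = 44, height_um = 14,
                    pattern = pattern_ring(0.6), noise_sd = 3)
  sim <- generate_stack(sp, frame = c(240L, 240L, 12L), seed = 17)
  det <- detect_objects(sim)
  nc <- normalize_colony(sim$stacks, det$kept[[1]], det$th,
                         detection_channel = "detection")
  g <- reference_grid(c(128L, 128L), c(64L, 8L))
  prof <- interpolate_to_grid(nc$cloud, g)
  rp <- radial_profile(prof$xy_values$reporter, g, nbins = 64)
  peak <- rp$r[which.max(rp$value)]
  # 2 grid cells on the 128-point lattice
  expect_lt(abs(peak - 0.6), 0.05)
})

test_that("colonies differing only by uniform scale give matching normalized profiles", {
  mk <- function(radius, height, frame) {
    sp <- colony_spec(c(frame / 2, frame / 2), radius, height,
                      pattern = pattern_ring(0.6), noise_sd = 0)
    sim <- generate_stack(sp, frame = c(frame, frame, 36L),
                          pixel_z_um = 0.75, background_level = 0.5,
                          seed = 19)
    det <- detect_objects(sim)
    nc <- normalize_colony(sim$stacks, det$kept[[1]], det$th,
                           detection_channel = "detection")
    interpolate_to_grid(nc$cloud, reference_grid(c(96L, 96L), c(64L, 8L)))
  }
  small <- mk(30, 12, 224L)
  large <- mk(60, 24, 640L)
  # projected intensity scales with optical path length, so compare after
  # the package's own min-max normalization; 0.15 is the documented
  # discretization tolerance: pixel pitch (~h^2 |f''|) plus optical-section
  # quantization of the projection plus interpolation overshoot
  for (plane in c("xy_values", "xz_values")) {
    a <- normalize_minmax(small[[plane]]$reporter)
    b <- normalize_minmax(large[[plane]]$reporter)
    ok <- !is.na(a) & !is.na(b)
    expect_gt(mean(ok), 0.4)
    expect_lt(max(abs(a[ok] - b[ok])), 0.15)
  }
})

test_that("fixtures round-trip through the TIFF writer with ground truth attached", {
  tmp <- withr::local_tempdir()
  sim <- generate_stack(colony_spec(c(60, 60), 22, 9), frame = c(128L, 128L, 8L),
                        seed = 23)
  p <- write_fixture(sim, tmp, "fix")
  expect_true(file.exists(p$tiff) && file.exists(p$truth))
  s0 <- read_stack(p$tiff, 0)
  s1 <- read_stack(p$tiff, 1)
  expect_identical(s0$data, sim$stacks$detection$data)
  expect_identical(s1$data, sim$stacks$reporter$data)
  truth <- jsonlite::read_json(p$truth, simplifyVector = TRUE)
  expect_equal(truth$colonies$radius_px, 22)
})
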