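#' Fluorescence pattern specifications for synthetic colonies
#'
#' Patterns are evaluated in each colony's own normalized frame (radius 1),
#' so the same pattern on colonies of different sizes produces geometrically
#' similar reporter distributions — the property the pipeline is built to
#' exploit.
#'
#' @param level,amp Peak intensity of the pattern (arbitrary camera counts).
#' @param sigma Gaussian width in normalized radius.
#' @param r0 Ring centre in normalized radius, in `(0, 1)`.
#' @param width Ring Gaussian half-width in normalized radius.
#' @return A pattern specification list.
#' @export
pattern_uniform <- function(level = 150) {
  stopifnot_scalar_pos(level, "level")
  list(type = "uniform", level = level)
}

#' @rdname pattern_uniform
#' @export
pattern_gaussian <- function(sigma = 0.35, amp = 150) {
  stopifnot_scalar_pos(sigma, "sigma"); stopifnot_scalar_pos(amp, "amp")
  list(type = "gaussian", sigma = sigma, amp = amp)
}

#' @rdname pattern_uniform
#' @export
pattern_ring <- function(r0 = 0.6, width = 0.12, amp = 150) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0 || r0 >= 1)
    cp_abort("`r0` must lie strictly between 0 and 1", "validation")
  stopifnot_scalar_pos(width, "width"); stopifnot_scalar_pos(amp, "amp")
  list(type = "ring", r0 = r0, width = width, amp = amp)
}

#' Specification of one synthetic colony
#'
#' Describes a dome-shaped colony with circular XY symmetry: a spherical-cap
#' (default) or truncated-Gaussian dome of programmed radius and height,
#' optionally tilted (emulating agar surface curvature), carrying a
#' programmable reporter pattern with additive Gaussian noise.
#'
#' @param center_xy_px Pixel coordinates `(x, y)` of the colony centre.
#' @param radius_px Colony radius in pixels.
#' @param height_um Dome apex height in micrometres.
#' @param dome_profile `"spherical_cap"` or `"gaussian"`.
#' @param tilt_rad Baseline tilt angle (rotation of the whole dome about the
#'   y axis through its base centre), radians.
#' @param pattern A pattern from [pattern_uniform()], [pattern_gaussian()]
#'   or [pattern_ring()].
#' @param noise_sd Additive Gaussian noise s.d. applied to the colony's
#'   voxels in both channels (clipped at zero).
#' @param base_um Height of the colony base above the first Z plane.
#' @return A `colony_spec`.
#' @export
colony_spec <- function(center_xy_px, radius_px, height_um,
                        dome_profile = c("spherical_cap", "gaussian"),
                        tilt_rad = 0, pattern = pattern_uniform(),
                        noise_sd = 0, base_um = 0) {
  dome_profile <- match.arg(dome_profile)
  if (length(center_xy_px) != 2L || !all(is.finite(center_xy_px)))
    cp_abort("`center_xy_px` must be two finite numbers", "validation")
  stopifnot_scalar_pos(radius_px, "radius_px")
  stopifnot_scalar_pos(height_um, "height_um")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    cp_abort("`noise_sd` must be >= 0", "validation")
  if (!is.numeric(base_um) || base_um < 0)
    cp_abort("`base_um` must be >= 0", "validation")
  structure(
    list(center_xy_px = as.numeric(center_xy_px), radius_px = radius_px,
         height_um = height_um, dome_profile = dome_profile,
         tilt_rad = tilt_rad, pattern = pattern, noise_sd = noise_sd,
         base_um = base_um),
    class = "colony_spec"
  )
}

dome_height_fun <- function(spec, R_um) {
  h0 <- spec$height_um
  if (spec$dome_profile == "spherical_cap") {
    rho <- (R_um^2 + h0^2) / (2 * h0)
    function(r) ifelse(r <= R_um, sqrt(pmax(rho^2 - r^2, 0)) - (rho - h0), 0)
  } else {
    sg <- R_um / 2
    base <- exp(-R_um^2 / (2 * sg^2))
    function(r) ifelse(r <= R_um,
                       h0 * (exp(-r^2 / (2 * sg^2)) - base) / (1 - base), 0)
  }
}

pattern_value <- function(pattern, r_hat) {
  switch(pattern$type,
    uniform = rep(pattern$level, length(r_hat)),
    gaussian = pattern$amp * exp(-r_hat^2 / (2 * pattern$sigma^2)),
    ring = pattern$amp *
      exp(-(r_hat - pattern$r0)^2 / (2 * pattern$width^2)),
    cp_abort(sprintf("unknown pattern type '%s'", pattern$type), "validation"))
}

#' Generate a two-channel synthetic Z-stack with ground truth
#'
#' Renders dome-shaped colonies into a detection channel (constant occupancy
#' intensity, emulating a constitutive boundary marker such as mCherry) and
#' a reporter channel (the colony's pattern evaluated in its own normalized
#' frame, emulating e.g. GFP). Intensities are integer camera counts;
#' additive Gaussian noise is clipped at zero and rounded, so output is
#' bit-identical for a given seed.
#'
#' @param specs List of [colony_spec()]s.
#' @param frame Integer triple `(P_x, P_y, Z_stack)`.
#' @param pixel_xy_um XY pixel pitch, um (default the reference acquisition
#'   pitch 1.5137).
#' @param pixel_z_um Z plane spacing, um.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param detection_level Occupancy intensity of the detection channel.
#' @param background_level Constant background added to both channels.
#' @param allow_overlap Permit overlapping colonies (used to build merged
#'   colony fixtures); otherwise overlap is a validation error.
#' @return A `colony_sim`: `stacks` (named list of two [zstack()]s,
#'   `detection` and `reporter`) and `truth` (frame, pixel sizes, seed and
#'   the colony specs).
#' @export
generate_stack <- function(specs, frame = c(384L, 384L, 14L),
                           pixel_xy_um = 1.5137, pixel_z_um = 2,
                           seed = NULL, detection_level = 200,
                           background_level = 2, allow_overlap = FALSE) {
  if (inherits(specs, "colony_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, logical(1), "colony_spec")))
    cp_abort("`specs` must be a list of colony_specs", "validation")
  if (length(frame) != 3L || any(frame < 1))
    cp_abort("`frame` must be (P_x, P_y, Z_stack)", "validation")
  frame <- as.integer(frame)
  px <- frame[1]; py <- frame[2]; nz <- frame[3]
  z_max_um <- (nz - 1) * pixel_z_um
  for (s in specs) {
    c_xy <- s$center_xy_px; r <- s$radius_px
    if (c_xy[1] - r < 1 || c_xy[1] + r > px ||
        c_xy[2] - r < 1 || c_xy[2] + r > py)
      cp_abort("colony extends outside the XY frame", "validation")
    R_um <- r * pixel_xy_um
    top <- s$base_um + s$height_um * cos(s$tilt_rad) +
      R_um * abs(sin(s$tilt_rad))
    if (top > z_max_um)
      cp_abort("colony extends above the last Z plane", "validation")
  }
  if (!allow_overlap && length(specs) > 1L) {
    for (i in seq_len(length(specs) - 1L)) {
      for (j in (i + 1L):length(specs)) {
        d <- sqrt(sum((specs[[i]]$center_xy_px - specs[[j]]$center_xy_px)^2))
        if (d < specs[[i]]$radius_px + specs[[j]]$radius_px)
          cp_abort("colonies overlap; pass allow_overlap = TRUE for merged fixtures",
                   "validation")
      }
    }
  }

  det <- array(background_level, c(nz, py, px))
  rep_ch <- array(background_level, c(nz, py, px))
  z_um <- (seq_len(nz) - 1) * pixel_z_um

  with_local_seed(seed, {
    for (s in specs) {
      cx <- s$center_xy_px[1]; cy <- s$center_xy_px[2]
      r_px <- s$radius_px; R_um <- r_px * pixel_xy_um
      xs <- max(1L, floor(cx - r_px)):min(px, ceiling(cx + r_px))
      ys <- max(1L, floor(cy - r_px)):min(py, ceiling(cy + r_px))
      sfun <- dome_height_fun(s, R_um)
      # voxel grid of the bounding box, physical colony-local coordinates
      dx <- rep((xs - cx) * pixel_xy_um, each = length(ys))
      dy <- rep((ys - cy) * pixel_xy_um, times = length(xs))
      nvox_xy <- length(dx)
      co <- cos(s$tilt_rad); si <- sin(s$tilt_rad)
      for (zi in seq_len(nz)) {
        dz <- z_um[zi] - s$base_um
        # rotate into the colony frame (tilt about the y axis through the
        # base centre)
        u <- co * dx + si * dz
        w <- -si * dx + co * dz
        r <- sqrt(u^2 + dy^2)
        inside <- r <= R_um & w >= 0 & w <= sfun(r)
        if (!any(inside)) next
        idx <- which(inside)
        val_det <- rep(detection_level, length(idx))
        val_rep <- pattern_value(s$pattern, r[idx] / R_um)
        if (s$noise_sd > 0) {
          val_det <- val_det + rnorm(length(idx), 0, s$noise_sd)
          val_rep <- val_rep + rnorm(length(idx), 0, s$noise_sd)
        }
        # bounding-box (y, x) offsets of the inside voxels
        oy <- ((idx - 1L) %% length(ys)) + 1L
        ox <- ((idx - 1L) %/% length(ys)) + 1L
        lin <- zi + (ys[oy] - 1L) * nz + (xs[ox] - 1L) * nz * py
        det[lin] <- det[lin] + val_det
        rep_ch[lin] <- rep_ch[lin] + val_rep
      }
    }
  })
  det <- round(pmin(pmax(det, 0), 65535))
  rep_ch <- round(pmin(pmax(rep_ch, 0), 65535))
  structure(
    list(stacks = list(
           detection = zstack(det, "detection", pixel_xy_um, pixel_z_um,
                              "synthetic"),
           reporter = zstack(rep_ch, "reporter", pixel_xy_um, pixel_z_um,
                             "synthetic")),
         truth = list(frame = frame, pixel_xy_um = pixel_xy_um,
                      pixel_z_um = pixel_z_um, seed = seed,
                      detection_level = detection_level,
                      background_level = background_level,
                      colonies = specs)),
    class = "colony_sim"
  )
}

#' Write a synthetic stack as a TIFF fixture with ground-truth sidecar
#'
#' Emits the two-channel stack via [write_stack()] plus a
#' `<basename>_truth.json` file recording every colony spec for downstream
#' assertions.
#'
#' @param sim A `colony_sim` from [generate_stack()].
#' @param dir Output directory.
#' @param basename File stem (default `"stack"`).
#' @return Invisibly, a list with `tiff`, `sidecar` and `truth` paths.
#' @export
write_fixture <- function(sim, dir, basename = "stack") {
  if (!inherits(sim, "colony_sim"))
    cp_abort("`sim` must be a colony_sim", "validation")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(basename, ".tif"))
  paths <- write_stack(sim$stacks, tif)
  truth <- file.path(dir, paste0(basename, "_truth.json"))
  tr <- sim$truth
  tr$colonies <- lapply(tr$colonies, unclass)
  jsonlite::write_json(tr, truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, list(truth = truth)))
}

#' Simulate a full experimental condition as TIFF fixtures
#'
#' Generates `n_images` frames, each holding `colonies_per_image`
#' well-separated colonies of randomized radius and height sharing one
#' reporter pattern, and writes them (with ground truth) into `dir`. Colony
#' centres are placed on a jittered grid so colonies never overlap.
#'
#' @param dir Output directory.
#' @param condition Condition label used in file names (e.g. `"M"`).
#' @param n_images Number of frames.
#' @param colonies_per_image Colonies per frame (1..4 with the default
#'   frame).
#' @param pattern Reporter pattern shared by all colonies.
#' @param radius_px_range,height_um_range Uniform sampling ranges emulating
#'   natural colony size variability.
#' @param tilt_rad_range Uniform range of baseline tilt per colony.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param frame,pixel_xy_um,pixel_z_um Frame geometry (see
#'   [generate_stack()]).
#' @param seed RNG seed for the whole condition.
#' @return A data frame manifest: one row per image with file paths, plus
#'   attribute `"sims"` holding the `colony_sim` objects.
#' @export
simulate_condition <- function(dir, condition = "M", n_images = 4L,
                               colonies_per_image = 3L,
                               pattern = pattern_ring(0.6),
                               radius_px_range = c(30, 52),
                               height_um_range = c(10, 18),
                               tilt_rad_range = c(0, 0),
                               noise_sd = 3,
                               frame = c(384L, 384L, 14L),
                               pixel_xy_um = 1.5137, pixel_z_um = 2,
                               seed = 1L) {
  if (colonies_per_image > 4L)
    cp_abort("at most 4 colonies per image with the default layout",
             "validation")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 2 x 2 cell layout; each colony centred in its own cell with jitter
  cells <- list(c(0.27, 0.27), c(0.73, 0.27), c(0.27, 0.73), c(0.73, 0.73))
  rows <- list(); sims <- list()
  with_local_seed(seed, {
    for (img in seq_len(n_images)) {
      specs <- lapply(seq_len(colonies_per_image), function(k) {
        ctr <- cells[[k]] * frame[1:2] + runif(2, -6, 6)
        colony_spec(
          center_xy_px = ctr,
          radius_px = runif(1, radius_px_range[1], radius_px_range[2]),
          height_um = runif(1, height_um_range[1], height_um_range[2]),
          tilt_rad = runif(1, tilt_rad_range[1], tilt_rad_range[2]),
          pattern = pattern, noise_sd = noise_sd)
      })
      sim <- generate_stack(specs, frame = frame, pixel_xy_um = pixel_xy_um,
                            pixel_z_um = pixel_z_um,
                            seed = sample.int(2^31 - 1, 1))
      base <- sprintf("%s_img%02d", condition, img)
      paths <- write_fixture(sim, dir, base)
      rows[[img]] <- data.frame(condition = condition, image = img,
                                tiff = paths$tiff, truth = paths$truth,
                                n_colonies = colonies_per_image,
                                stringsAsFactors = FALSE)
      sims[[img]] <- sim
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "sims") <- sims
  out
}
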