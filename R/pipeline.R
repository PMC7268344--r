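#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the batch pipeline. `conditions` maps condition
#' labels to TIFF paths or glob patterns; processing order within a
#' condition is sorted by path for determinism. Control-based normalization
#' activates only when both control labels name existing conditions.
#'
#' @param conditions Named list: condition label -> character vector of TIFF
#'   paths or glob patterns.
#' @param out_dir Output directory.
#' @param pixel_xy_um,pixel_z_um Pixel sizes (um); may be `NULL` when every
#'   input carries metadata.
#' @param detection_channel_index,reporter_channel_index 0-based channel
#'   indices in the input files.
#' @param channel_names Labels for the two channels.
#' @param threshold_factor Multiplier on the mean projected intensity.
#' @param min_equiv_circle_diameter_px,min_area_mode,max_axis_ratio_excess
#'   Shape-filter settings (see [apply_shape_filters()]).
#' @param connectivity Labeling connectivity, 8 or 4.
#' @param xz_slab_rows Rows averaged for the XZ slice.
#' @param align_xz Align XZ planes by principal axis (default `TRUE`).
#' @param grid_xy,grid_xz Reference grid sizes.
#' @param normalization `"raw"`, `"controls"` or `"minmax"`.
#' @param controls List with `positive` and `negative` condition labels
#'   (for `normalization = "controls"`).
#' @param minmax_per_colony Min-max normalize each colony profile before
#'   stacking instead of the aggregated mean (default `FALSE`).
#' @param min_replicates_flag Low-n flag threshold (default 10).
#' @param formats Output formats passed to [write_profile_outputs()].
#' @param seed Seed recorded in the run (the pipeline itself is
#'   deterministic given inputs).
#' @return A validated `run_config`.
#' @export
run_config <- function(conditions, out_dir,
                       pixel_xy_um = NULL, pixel_z_um = NULL,
                       detection_channel_index = 0L,
                       reporter_channel_index = 1L,
                       channel_names = c("detection", "reporter"),
                       threshold_factor = 1.10,
                       min_equiv_circle_diameter_px = 20,
                       min_area_mode = "diameter",
                       max_axis_ratio_excess = 0.15,
                       connectivity = 8L,
                       xz_slab_rows = 1L,
                       align_xz = TRUE,
                       grid_xy = c(256L, 256L),
                       grid_xz = c(256L, 10L),
                       normalization = c("raw", "controls", "minmax"),
                       controls = list(positive = NULL, negative = NULL),
                       minmax_per_colony = FALSE,
                       min_replicates_flag = 10L,
                       formats = c("csv", "array", "png"),
                       seed = 1L) {
  normalization <- match.arg(normalization)
  if (!is.list(conditions) || !length(conditions) ||
      is.null(names(conditions)) || any(!nzchar(names(conditions))))
    cp_abort("`conditions` must be a non-empty named list of path sets",
             "validation")
  if (normalization == "controls") {
    if (is.null(controls$positive) || is.null(controls$negative))
      cp_abort("controls normalization needs both control labels", "validation")
    missing <- setdiff(c(controls$positive, controls$negative),
                       names(conditions))
    if (length(missing))
      cp_abort(sprintf("control condition(s) not in `conditions`: %s",
                       paste(missing, collapse = ", ")), "validation")
  }
  cfg <- list(conditions = conditions, out_dir = out_dir,
              pixel_xy_um = pixel_xy_um, pixel_z_um = pixel_z_um,
              detection_channel_index = as.integer(detection_channel_index),
              reporter_channel_index = as.integer(reporter_channel_index),
              channel_names = as.character(channel_names),
              threshold_factor = threshold_factor,
              min_equiv_circle_diameter_px = min_equiv_circle_diameter_px,
              min_area_mode = min_area_mode,
              max_axis_ratio_excess = max_axis_ratio_excess,
              connectivity = as.integer(connectivity),
              xz_slab_rows = as.integer(xz_slab_rows),
              align_xz = isTRUE(align_xz),
              grid_xy = as.integer(grid_xy), grid_xz = as.integer(grid_xz),
              normalization = normalization, controls = controls,
              minmax_per_colony = isTRUE(minmax_per_colony),
              min_replicates_flag = as.integer(min_replicates_flag),
              formats = formats, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    cp_abort(sprintf("config file not found: %s", path), "io")
  raw <- yaml::read_yaml(path)
  if (!is.list(raw$conditions))
    cp_abort("config must contain a `conditions` mapping", "validation")
  raw$conditions <- lapply(raw$conditions, unlist)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

expand_inputs <- function(patterns) {
  out <- unlist(lapply(patterns, function(p) {
    if (file.exists(p)) p else Sys.glob(p)
  }), use.names = FALSE)
  sort(unique(out))
}

#' Run the batch pipeline over a directory of stacks
#'
#' End-to-end driver: for every condition, each input stack is loaded, the
#' detection channel is sum-projected, thresholded and labeled; shape
#' filters select quasi-circular colonies; kept colonies are aligned,
#' geometrically normalized and interpolated onto the reference grids;
#' profiles are stacked per condition and summarized (mean, median, CV).
#' Outputs: per-condition statistics (CSV / RDS / PNG), a per-colony audit
#' table naming the rule behind every rejection, the serialized
#' configuration, a JSON manifest and a plain-text log. Deterministic given
#' the configuration and inputs.
#'
#' @param config A `run_config` (or a YAML path).
#' @return Invisibly, a list with `status` (0 on success), `audit` (data
#'   frame), `stats` (per-condition `profile_stats`), `manifest` and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    cp_abort("`config` must be a run_config or a YAML path", "validation")
  files <- lapply(config$conditions, expand_inputs)
  empty <- names(files)[!vapply(files, length, integer(1))]
  if (length(empty))
    cp_abort(sprintf("no input files for condition(s): %s",
                     paste(empty, collapse = ", ")), "validation")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  logf <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }
  grid <- reference_grid(config$grid_xy, config$grid_xz)
  chn <- config$channel_names
  audit <- list(); stats <- list(); n_read_fail <- 0L; n_files <- 0L

  for (cond in names(files)) {
    logf("condition %s: %d input file(s)", cond, length(files[[cond]]))
    profiles <- list()
    cond_read <- 0L
    for (f in files[[cond]]) {
      n_files <- n_files + 1L
      stacks <- tryCatch({
        det <- read_stack(f, config$detection_channel_index,
                          config$pixel_xy_um, config$pixel_z_um,
                          channel_name = chn[1], quiet = TRUE)
        rep_ <- read_stack(f, config$reporter_channel_index,
                           config$pixel_xy_um, config$pixel_z_um,
                           channel_name = chn[2], quiet = TRUE)
        stats::setNames(list(det, rep_), chn)
      }, colonyprof_error = function(e) {
        logf("SKIP unreadable %s: %s", f, conditionMessage(e))
        NULL
      })
      if (is.null(stacks)) { n_read_fail <- n_read_fail + 1L; next }
      cond_read <- cond_read + 1L
      proy <- sum_projection(stacks[[1]])
      th <- compute_threshold(proy, config$threshold_factor)
      mask <- filter_and_binarize(proy, th)
      objects <- label_components(mask, config$connectivity)
      flt <- apply_shape_filters(objects,
                                 config$min_equiv_circle_diameter_px,
                                 config$max_axis_ratio_excess,
                                 config$min_area_mode)
      logf("%s: threshold %.3f, %d object(s), %d kept", basename(f), th,
           length(objects), length(flt$kept))
      all_obj <- c(flt$kept, flt$rejected)
      rows <- colony_table(all_obj)
      if (nrow(rows)) {
        rows$condition <- cond; rows$file <- basename(f)
        rows$R_px <- NA_real_; rows$H_um <- NA_real_; rows$h_um <- NA_real_
        rows$theta_rad <- NA_real_
      }
      for (ob in flt$kept) {
        res <- tryCatch({
          nc <- normalize_colony(stacks, ob, th,
                                 detection_channel = chn[1],
                                 xz_slab_rows = config$xz_slab_rows,
                                 align = config$align_xz)
          prof <- interpolate_to_grid(nc$cloud, grid)
          prof$colony_id <- sprintf("%s#%d", basename(f), ob$label)
          list(prof = prof, planes = nc$planes)
        }, colonyprof_error = function(e) e)
        i <- which(rows$label == ob$label)
        if (inherits(res, "error")) {
          reason <- if (inherits(res, "colonyprof_degenerate_colony_error"))
            "degenerate"
          else if (inherits(res, "colonyprof_alignment_error"))
            "alignment-failure"
          else if (inherits(res, "colonyprof_interpolation_error"))
            "interpolation-failure"
          else "error"
          rows$kept[i] <- FALSE
          rows$rejection_reason[i] <- reason
          logf("%s colony %d dropped: %s (%s)", basename(f), ob$label,
               reason, conditionMessage(res))
        } else {
          ps <- res$planes
          rows$R_px[i] <- ps$radius_R; rows$H_um[i] <- ps$height_H
          rows$h_um[i] <- ps$base_h; rows$theta_rad[i] <- ps$theta_rad
          profiles[[length(profiles) + 1L]] <- res$prof
        }
      }
      if (nrow(rows)) audit[[length(audit) + 1L]] <- rows
    }
    if (!length(profiles)) {
      if (cond_read > 0L)
        cp_warn(sprintf("no colonies survive filtering in condition %s", cond))
      logf("condition %s: EMPTY (no surviving colonies)", cond)
      stats[[cond]] <- NULL
      next
    }
    if (config$minmax_per_colony) {
      profiles <- lapply(profiles, function(p) {
        for (plane in c("xy_values", "xz_values"))
          p[[plane]] <- lapply(p[[plane]], normalize_minmax)
        p
      })
    }
    pstack <- stack_profiles(profiles, group_key = cond)
    stats[[cond]] <- central_tendency(pstack, config$min_replicates_flag)
    logf("condition %s: %d profile(s) stacked", cond, length(profiles))
  }
  if (n_read_fail == n_files)
    cp_abort("all input files failed to read", "io")

  if (config$normalization == "controls") {
    cp <- config$controls$positive; cn <- config$controls$negative
    if (!is.null(stats[[cp]]) && !is.null(stats[[cn]])) {
      for (cond in names(stats)) {
        if (cond %in% c(cp, cn) || is.null(stats[[cond]])) next
        stats[[cond]] <- normalize_stats(stats[[cond]], "controls",
                                         pos_stats = stats[[cp]],
                                         neg_stats = stats[[cn]])
      }
    } else {
      logf("controls normalization skipped: empty control condition")
    }
  } else if (config$normalization == "minmax" && !config$minmax_per_colony) {
    for (cond in names(stats))
      if (!is.null(stats[[cond]]))
        stats[[cond]] <- normalize_stats(stats[[cond]], "minmax")
  }

  manifest <- data.frame(file = character(), format = character(),
                         plane = character(), channel = character(),
                         stringsAsFactors = FALSE)
  for (cond in names(stats)) {
    if (is.null(stats[[cond]])) next
    m <- write_profile_outputs(stats[[cond]], config$out_dir,
                               config$formats, prefix = cond)
    manifest <- rbind(manifest, m)
  }
  audit <- if (length(audit)) do.call(rbind, audit)
           else colony_table(list())
  audit_path <- file.path(config$out_dir, "audit.csv")
  write.csv(audit, audit_path, row.names = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  log_path <- file.path(config$out_dir, "pipeline.log")
  writeLines(log_lines, log_path)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(
    list(outputs = manifest, audit = audit_path, config = cfg_path,
         log = log_path),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, audit = audit, stats = stats,
                 manifest = manifest, out_dir = config$out_dir))
}
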