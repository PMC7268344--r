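#' Single-channel confocal Z-stack
#'
#' Container for one fluorescence channel of a confocal Z-stack together with
#' its pixel-size metadata. The intensity array is ordered `(Z, Y, X)`:
#' `data[z, , ]` is the image plane acquired at axial position
#' `(z - 1) * pixel_z_um` micrometres. Pixel indices are 1-based and a pixel's
#' coordinate is its index (pixel centres).
#'
#' @param data 3D numeric array of non-negative finite intensities, ordered
#'   `(Z, Y, X)`.
#' @param channel_name Text label for the channel (e.g. `"mCherry"`).
#' @param pixel_xy_um XY pixel pitch in micrometres (> 0).
#' @param pixel_z_um Z plane spacing in micrometres (> 0).
#' @param source_path Provenance string, typically the file the stack was
#'   read from.
#' @return An object of class `"zstack"`.
#' @export
zstack <- function(data, channel_name = "", pixel_xy_um, pixel_z_um,
                   source_path = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    cp_abort("`data` must be a 3D array ordered (Z, Y, X)", "validation")
  if (any(dim(data) < 1L))
    cp_abort("all stack dimensions must be >= 1", "validation")
  if (!all(is.finite(data)) || any(data < 0))
    cp_abort("stack intensities must be finite and >= 0", "validation")
  stopifnot_scalar_pos(pixel_xy_um, "pixel_xy_um")
  stopifnot_scalar_pos(pixel_z_um, "pixel_z_um")
  storage.mode(data) <- "double"
  structure(
    list(data = data, channel_name = as.character(channel_name),
         pixel_xy_um = pixel_xy_um, pixel_z_um = pixel_z_um,
         source_path = as.character(source_path)),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<zstack> channel '%s': %d plane(s) of %d x %d px (Y x X), %g um/px XY, %g um/plane Z\n",
    x$channel_name, d[1], d[2], d[3], x$pixel_xy_um, x$pixel_z_um))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$data)

# Parse the subset of OME-XML this package needs from an ImageDescription
# string. Returns NULL when the string is not OME-XML.
parse_ome_metadata <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else as.numeric(v)
  }
  int_attr <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else as.integer(v)
  }
  chn <- xml2::xml_find_all(doc, ".//Channel")
  ch_names <- if (length(chn)) xml2::xml_attr(chn, "Name") else character()
  list(
    size_c = int_attr(px, "SizeC") %||% 1L,
    size_z = int_attr(px, "SizeZ") %||% 1L,
    size_t = int_attr(px, "SizeT") %||% 1L,
    dimension_order = xml2::xml_attr(px, "DimensionOrder"),
    physical_x = num_attr(px, "PhysicalSizeX"),
    physical_z = num_attr(px, "PhysicalSizeZ"),
    channel_names = ch_names
  )
}

sidecar_path <- function(path) {
  cand <- c(sub("\\.(tiff?|TIFF?)$", ".json", path), paste0(path, ".json"))
  cand <- cand[cand != path]
  hit <- cand[file.exists(cand)]
  if (length(hit)) hit[[1]] else NULL
}

#' Read one channel of a multi-page TIFF / OME-TIFF Z-stack
#'
#' Supports three metadata sources, in order of precedence: embedded OME-XML
#' (OME-TIFF), a JSON sidecar (as written by [write_stack()]), and the
#' caller-declared layout (`n_channels`, `plane_order`). Pixel sizes found in
#' OME or sidecar metadata override the supplied arguments with a notice.
#'
#' @param path Path to a multi-page TIFF or OME-TIFF file.
#' @param channel_index 0-based channel to extract.
#' @param pixel_xy_um,pixel_z_um Pixel pitch / plane spacing in micrometres;
#'   may be omitted when the file (or its sidecar) carries them.
#' @param n_channels Declared channel count for plain TIFFs without metadata.
#' @param plane_order Plane interleaving for plain TIFFs: `"CZ"` means the
#'   channel index varies fastest from page to page, `"ZC"` means all planes
#'   of channel 0 come first.
#' @param channel_name Optional channel label; metadata names take precedence.
#' @param quiet Suppress the metadata-override notice.
#' @return A [zstack()] with axes ordered `(Z, Y, X)`.
#' @export
read_stack <- function(path, channel_index = 0L, pixel_xy_um = NULL,
                       pixel_z_um = NULL, n_channels = NULL,
                       plane_order = c("CZ", "ZC"), channel_name = NULL,
                       quiet = FALSE) {
  plane_order <- match.arg(plane_order)
  if (!is.numeric(channel_index) || length(channel_index) != 1L ||
      channel_index < 0 || channel_index != round(channel_index))
    cp_abort("`channel_index` must be a single non-negative integer",
             "validation")
  channel_index <- as.integer(channel_index)
  if (!file.exists(path))
    cp_abort(sprintf("file not found: %s", path), "io")
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e)
      cp_abort(sprintf("not a readable TIFF file: %s (%s)",
                       path, conditionMessage(e)), "format")
  )
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    cp_abort("multi-sample (RGB) TIFF pages are not supported", "format")

  ome <- parse_ome_metadata(attr(pages[[1]], "description"))
  side <- NULL
  if (is.null(ome)) {
    sp <- sidecar_path(path)
    if (!is.null(sp))
      side <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                       error = function(e) NULL)
  }

  n_pages <- length(pages)
  meta_px <- NULL; meta_pz <- NULL; ch_names <- character()
  if (!is.null(ome)) {
    if ((ome$size_t %||% 1L) > 1L)
      cp_abort("time series (SizeT > 1) are not supported", "format")
    n_c <- ome$size_c; n_z <- ome$size_z
    ord <- ome$dimension_order %||% "XYCZT"
    c_fastest <- regexpr("C", ord) < regexpr("Z", ord)
    meta_px <- ome$physical_x; meta_pz <- ome$physical_z
    ch_names <- ome$channel_names
    meta_src <- "OME-XML"
  } else if (!is.null(side)) {
    n_c <- as.integer(side$n_channels %||% 1L)
    n_z <- as.integer(side$n_z %||% (n_pages / max(n_c, 1L)))
    c_fastest <- identical(side$plane_order %||% "CZ", "CZ")
    meta_px <- if (!is.null(side$pixel_xy_um)) as.numeric(side$pixel_xy_um)
    meta_pz <- if (!is.null(side$pixel_z_um)) as.numeric(side$pixel_z_um)
    ch_names <- as.character(side$channel_names %||% character())
    meta_src <- "sidecar JSON"
  } else {
    n_c <- as.integer(n_channels %||% 1L)
    if (n_pages %% n_c != 0L)
      cp_abort(sprintf("page count %d is not a multiple of n_channels %d",
                       n_pages, n_c), "format")
    n_z <- n_pages %/% n_c
    c_fastest <- plane_order == "CZ"
    meta_src <- NULL
  }
  if (n_pages != n_c * n_z)
    cp_abort(sprintf("page count %d does not match %d channel(s) x %d plane(s)",
                     n_pages, n_c, n_z), "format")
  if (channel_index >= n_c)
    cp_abort(sprintf("channel_index %d out of range: file has %d channel(s)",
                     channel_index, n_c), "validation")

  if (!is.null(meta_px)) {
    if (!quiet && !is.null(pixel_xy_um) && !isTRUE(all.equal(meta_px, pixel_xy_um)))
      message(sprintf("pixel_xy_um %g from %s overrides supplied %g",
                      meta_px, meta_src, pixel_xy_um))
    pixel_xy_um <- meta_px
  }
  if (!is.null(meta_pz)) {
    if (!quiet && !is.null(pixel_z_um) && !isTRUE(all.equal(meta_pz, pixel_z_um)))
      message(sprintf("pixel_z_um %g from %s overrides supplied %g",
                      meta_pz, meta_src, pixel_z_um))
    pixel_z_um <- meta_pz
  }
  if (is.null(pixel_xy_um) || is.null(pixel_z_um))
    cp_abort("pixel sizes not in file metadata; supply pixel_xy_um and pixel_z_um",
             "validation")

  idx <- if (c_fastest) channel_index + 1L + (0:(n_z - 1L)) * n_c
         else channel_index * n_z + 1:n_z
  planes <- pages[idx]
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  dat <- array(0, c(n_z, ny, nx))
  for (z in seq_len(n_z)) dat[z, , ] <- planes[[z]]
  name <- channel_name %||%
    (if (length(ch_names) > channel_index && nzchar(ch_names[channel_index + 1L]) &&
         !is.na(ch_names[channel_index + 1L]))
       ch_names[channel_index + 1L]
     else sprintf("ch%d", channel_index))
  zstack(dat, channel_name = name, pixel_xy_um = pixel_xy_um,
         pixel_z_um = pixel_z_um, source_path = path)
}

#' Write a multi-channel Z-stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are interleaved channel-fastest (`"CZ"`); the sidecar records the
#' layout, pixel sizes and channel names so [read_stack()] can restore the
#' stack without further arguments. Intensities must be integers in
#' `[0, 2^bits - 1]`; integer-valued data round-trips bit-exactly.
#'
#' @param channels A single [zstack()] or a list of them (one per channel),
#'   all with identical dimensions and pixel sizes.
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param bits_per_sample 8 or 16.
#' @return Invisibly, a list with the `tiff` and `sidecar` paths.
#' @export
write_stack <- function(channels, path, bits_per_sample = 16L) {
  if (inherits(channels, "zstack")) channels <- list(channels)
  if (!length(channels) || !all(vapply(channels, inherits, logical(1), "zstack")))
    cp_abort("`channels` must be a zstack or a list of zstacks", "validation")
  d <- dim(channels[[1]]$data)
  for (ch in channels) {
    if (!identical(dim(ch$data), d))
      cp_abort("all channels must share the same dimensions", "validation")
  }
  if (!bits_per_sample %in% c(8L, 16L))
    cp_abort("bits_per_sample must be 8 or 16", "validation")
  top <- 2^bits_per_sample - 1
  mx <- max(vapply(channels, function(ch) max(ch$data), numeric(1)))
  if (mx > top)
    cp_abort(sprintf("intensities exceed %d; rescale before writing", top),
             "validation")
  n_c <- length(channels); n_z <- d[1]
  pages <- vector("list", n_c * n_z)
  k <- 0L
  for (z in seq_len(n_z)) {
    for (ci in seq_len(n_c)) {
      k <- k + 1L
      pages[[k]] <- channels[[ci]]$data[z, , ] / top
    }
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({tiff::writeTIFF(pages, path,
                                  bits.per.sample = bits_per_sample,
                                  compression = "LZW"); TRUE},
                 error = function(e) FALSE)
  if (!ok) cp_abort(sprintf("cannot write TIFF to %s", path), "io")
  sp <- sub("\\.(tiff?|TIFF?)$", ".json", path)
  if (sp == path) sp <- paste0(path, ".json")
  jsonlite::write_json(
    list(n_channels = n_c, n_z = n_z, plane_order = "CZ",
         pixel_xy_um = channels[[1]]$pixel_xy_um,
         pixel_z_um = channels[[1]]$pixel_z_um,
         channel_names = vapply(channels, function(ch) ch$channel_name,
                                character(1)),
         bits_per_sample = bits_per_sample),
    sp, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = path, sidecar = sp))
}

# Render a matrix as a false-colour PNG heatmap (viridis ramp, NA = grey).
write_heatmap_png <- function(values, path, palette = "viridis") {
  cols <- grDevices::hcl.colors(256L, palette)
  rgbm <- grDevices::col2rgb(cols) / 255
  rng <- range(values, na.rm = TRUE)
  v <- if (diff(rng) > 0) (values - rng[1]) / diff(rng)
       else values * 0
  idx <- pmin(pmax(1L, 1L + floor(v * 255.999)), 256L)
  nr <- nrow(values); nc <- ncol(values)
  img <- array(0.5, c(nr, nc, 3))
  ok <- !is.na(idx)
  for (k in 1:3) {
    plane <- matrix(0.5, nr, nc)
    plane[ok] <- rgbm[k, idx[ok]]
    img[, , k] <- plane
  }
  png::writePNG(img, path)
  path
}

#' Write profile statistics to disk
#'
#' Writes any combination of three formats: `"array"` (an RDS bundle of the
#' full [profile_stats] object at double precision), `"csv"` (one row per
#' grid point per plane and channel, columns `grid_x`, `grid_y`/`grid_z`,
#' `mean`, `median`, `cv`, `n`) and `"png"` (false-colour heatmaps of the
#' mean and CV per plane and channel).
#'
#' @param stats A `profile_stats` object from [central_tendency()].
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("array", "csv", "png")`; empty writes nothing.
#' @param prefix Filename prefix, default the condition label.
#' @return A data frame manifest of written files (columns `file`, `format`,
#'   `plane`, `channel`).
#' @export
write_profile_outputs <- function(stats, out_dir,
                                  formats = c("array", "csv", "png"),
                                  prefix = NULL) {
  if (!inherits(stats, "profile_stats"))
    cp_abort("`stats` must be a profile_stats object", "validation")
  bad <- setdiff(formats, c("array", "csv", "png"))
  if (length(bad))
    cp_abort(sprintf("unknown formats: %s", paste(bad, collapse = ", ")),
             "validation")
  manifest <- data.frame(file = character(), format = character(),
                         plane = character(), channel = character(),
                         stringsAsFactors = FALSE)
  if (!length(formats)) return(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    cp_abort(sprintf("cannot create output directory %s", out_dir), "io")
  probe <- file.path(out_dir, ".cp_write_probe")
  ok <- tryCatch({file.create(probe, showWarnings = FALSE)}, error = function(e) FALSE)
  if (!isTRUE(ok)) cp_abort(sprintf("directory not writable: %s", out_dir), "io")
  unlink(probe)
  prefix <- prefix %||% (if (nzchar(stats$condition)) stats$condition else "profile")
  add <- function(file, format, plane = "", channel = "") {
    manifest[nrow(manifest) + 1L, ] <<- list(file, format, plane, channel)
  }
  if ("array" %in% formats) {
    f <- file.path(out_dir, paste0(prefix, "_stats.rds"))
    saveRDS(stats, f)
    add(f, "array")
  }
  grid <- stats$grid
  axes <- list(xy = list(x = grid$xy_x, y = grid$xy_y, ylab = "grid_y"),
               xz = list(x = grid$xz_x, y = grid$xz_z, ylab = "grid_z"))
  for (plane in c("xy", "xz")) {
    ax <- axes[[plane]]
    for (ch in names(stats[[plane]])) {
      s <- stats[[plane]][[ch]]
      if ("csv" %in% formats) {
        df <- data.frame(
          grid_x = rep(ax$x, each = length(ax$y)),
          gy = rep(ax$y, times = length(ax$x)),
          mean = as.vector(s$mean), median = as.vector(s$median),
          cv = as.vector(s$cv), n = as.vector(stats[[paste0(plane, "_n")]]))
        names(df)[2] <- ax$ylab
        f <- file.path(out_dir, sprintf("%s_%s_%s.csv", prefix, plane, ch))
        write.csv(df, f, row.names = FALSE)
        add(f, "csv", plane, ch)
      }
      if ("png" %in% formats) {
        for (what in c("mean", "cv")) {
          f <- file.path(out_dir,
                         sprintf("%s_%s_%s_%s.png", prefix, plane, ch, what))
          write_heatmap_png(s[[what]], f)
          add(f, "png", plane, ch)
        }
      }
    }
  }
  manifest
}
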