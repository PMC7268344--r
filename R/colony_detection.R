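#' Sum projection of a Z-stack
#'
#' Collapses a stack to a single 2D image by summing intensities along the
#' axial (Z) direction at every XY pixel. The summed projection of the
#' constitutive boundary-marker channel is the stencil on which colonies are
#' detected.
#'
#' @param stack A [zstack()].
#' @return A numeric matrix of shape `(P_y, P_x)`.
#' @export
sum_projection <- function(stack) {
  if (!inherits(stack, "zstack"))
    cp_abort("`stack` must be a zstack", "validation")
  colSums(stack$data)
}

#' Global detection threshold from the mean projected intensity
#'
#' The threshold is the mean intensity of the whole projection image
#' multiplied by a fixed factor (default 1.10).
#'
#' @param proy Sum-projection matrix.
#' @param factor Multiplier applied to the image mean.
#' @return Scalar threshold.
#' @export
compute_threshold <- function(proy, factor = 1.10) {
  if (length(proy) == 0L)
    cp_abort("`proy` must be a non-empty matrix", "validation")
  stopifnot_scalar_pos(factor, "factor")
  factor * mean(proy)
}

#' Threshold-filter and binarize a projection image
#'
#' Composition of the filter operator (keep values strictly above the
#' threshold, zero otherwise) and the binarizer (1 where the filtered value
#' is strictly positive): the resulting foreground is exactly
#' `proy > th`.
#'
#' @param proy Sum-projection matrix.
#' @param th Scalar threshold.
#' @return Logical mask of the same shape.
#' @export
filter_and_binarize <- function(proy, th) {
  if (!is.numeric(th) || length(th) != 1L || !is.finite(th))
    cp_abort("`th` must be a single finite number", "validation")
  proy > th
}

new_colony_object <- function(label, rows, cols) {
  width_x <- diff(range(cols)) + 1
  height_y <- diff(range(rows)) + 1
  structure(
    list(label = as.integer(label),
         pixel_rows = as.integer(rows), pixel_cols = as.integer(cols),
         area_px = length(rows),
         centroid_xy = c(x = mean(cols), y = mean(rows)),
         major_axis_px = max(width_x, height_y),
         minor_axis_px = min(width_x, height_y),
         passed_filters = NA, rejection_reason = NA_character_),
    class = "colony_object"
  )
}

#' @export
print.colony_object <- function(x, ...) {
  cat(sprintf(
    "<colony_object> label %d: area %d px, centroid (%.1f, %.1f), axes %g/%g%s\n",
    x$label, x$area_px, x$centroid_xy[["x"]], x$centroid_xy[["y"]],
    x$major_axis_px, x$minor_axis_px,
    if (is.na(x$passed_filters)) "" else if (x$passed_filters) ", kept"
    else sprintf(", rejected (%s)", x$rejection_reason)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' Finds the connected foreground components (candidate colonies) and
#' computes each object's zeroth moment (area = pixel count), first moments
#' (centroid, in pixel units) and axis lengths derived from the coordinate
#' extents (`max - min + 1` over rows and columns; the larger is the major
#' axis).
#'
#' @param mask Logical matrix (foreground = `TRUE`).
#' @param connectivity 8 (default, edges + diagonals) or 4.
#' @return A list of `colony_object`s, ordered by label; empty mask gives an
#'   empty list.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask))
    cp_abort("`mask` must be a matrix", "validation")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1)))
      cp_abort("`mask` must be logical or 0/1", "validation")
    mask <- mask > 0
  }
  lab <- cp_label_components(mask, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(list())
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  labs <- lab[idx]
  lapply(seq_len(k), function(l) {
    sel <- labs == l
    new_colony_object(l, rows[sel], cols[sel])
  })
}

#' Shape filters selecting quasi-circular colonies
#'
#' Two rules, applied independently to every labeled object: (i) a minimum
#' area, by default the area of a circle of diameter
#' `min_equiv_circle_diameter_px`; (ii) a bound on deviation from circularity,
#' rejecting objects whose major/minor axis-length ratio exceeds
#' `1 + max_axis_ratio_excess` (merged colonies fail this rule).
#'
#' @param objects List of `colony_object`s from [label_components()].
#' @param min_equiv_circle_diameter_px Diameter (px) of the smallest
#'   acceptable equivalent circle (default 20).
#' @param max_axis_ratio_excess Maximum tolerated excess of the axis ratio
#'   over 1 (default 0.15, i.e. major/minor <= 1.15).
#' @param min_area_mode How to read the area rule: `"diameter"` (default;
#'   minimum area = pi * (d/2)^2), `"radius"` (minimum area = pi * d^2) or
#'   `"literal"` (minimum area = `min_equiv_circle_diameter_px` pixels).
#' @return A list with elements `kept` and `rejected`; every object is
#'   annotated with `passed_filters` and, when rejected, a
#'   `rejection_reason` of `"area"`, `"axis-ratio"` or `"degenerate"`.
#' @export
apply_shape_filters <- function(objects,
                                min_equiv_circle_diameter_px = 20,
                                max_axis_ratio_excess = 0.15,
                                min_area_mode = c("diameter", "radius",
                                                  "literal")) {
  min_area_mode <- match.arg(min_area_mode)
  stopifnot_scalar_pos(min_equiv_circle_diameter_px,
                       "min_equiv_circle_diameter_px")
  stopifnot_scalar_pos(max_axis_ratio_excess, "max_axis_ratio_excess")
  min_area <- switch(min_area_mode,
    diameter = pi * (min_equiv_circle_diameter_px / 2)^2,
    radius   = pi * min_equiv_circle_diameter_px^2,
    literal  = min_equiv_circle_diameter_px)
  annotated <- lapply(objects, function(ob) {
    reason <- NA_character_
    if (ob$area_px < min_area) {
      reason <- "area"
    } else if (ob$minor_axis_px <= 0) {
      reason <- "degenerate"
    } else if (ob$major_axis_px / ob$minor_axis_px - 1 > max_axis_ratio_excess) {
      reason <- "axis-ratio"
    }
    ob$passed_filters <- is.na(reason)
    ob$rejection_reason <- reason
    ob
  })
  keep <- vapply(annotated, function(ob) ob$passed_filters, logical(1))
  list(kept = annotated[keep], rejected = annotated[!keep])
}

#' Summarize colony objects as a data frame
#'
#' @param objects List of `colony_object`s (annotated or not).
#' @return One row per object with label, area, centroid, axis lengths and
#'   filter outcome.
#' @export
colony_table <- function(objects) {
  if (!length(objects))
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      major_axis_px = numeric(), minor_axis_px = numeric(),
                      kept = logical(), rejection_reason = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(objects, function(ob) {
    data.frame(label = ob$label, area_px = ob$area_px,
               centroid_x = ob$centroid_xy[["x"]],
               centroid_y = ob$centroid_xy[["y"]],
               major_axis_px = ob$major_axis_px,
               minor_axis_px = ob$minor_axis_px,
               kept = if (is.na(ob$passed_filters)) NA else ob$passed_filters,
               rejection_reason = ob$rejection_reason,
               stringsAsFactors = FALSE)
  }))
}
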