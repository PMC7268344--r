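#' Per-grid-point replicate statistics
#'
#' Computes, at every grid point and over the replicates valid there, the
#' mean, median, sample standard deviation (n - 1 denominator) and the
#' coefficient of variation `cv = std / mean` (sentinel `NA` where the mean
#' is zero or fewer than two replicates are valid). Points valid in fewer
#' than `min_replicates_flag` replicates are flagged low-n: with small n the
#' dispersion estimates can increase drastically, so they deserve caution.
#'
#' @param stack A `profile_stack` from [stack_profiles()].
#' @param min_replicates_flag Minimum replicate count below which a grid
#'   point is flagged (default 10, a conservative criterion).
#' @return A `profile_stats` object: per plane (`xy`, `xz`) and channel the
#'   matrices `mean`, `median`, `std`, `cv`; count matrices `xy_n`, `xz_n`;
#'   low-n flag matrices; `n_colonies`; `normalization_mode = "raw"`.
#' @export
central_tendency <- function(stack, min_replicates_flag = 10L) {
  if (!inherits(stack, "profile_stack"))
    cp_abort("`stack` must be a profile_stack", "validation")
  one <- function(arr) {
    dims <- dim(arr)[2:3]
    n <- colSums(!is.na(arr), dims = 1)
    s1 <- colSums(arr, dims = 1, na.rm = TRUE)
    s2 <- colSums(arr^2, dims = 1, na.rm = TRUE)
    mn <- ifelse(n >= 1, s1 / n, NA_real_)
    va <- ifelse(n >= 2, pmax(s2 - n * mn^2, 0) / (n - 1), NA_real_)
    sdv <- sqrt(va)
    med <- apply(arr, c(2, 3), median, na.rm = TRUE)
    med[n < 1] <- NA_real_
    cv <- ifelse(!is.na(mn) & mn != 0, sdv / mn, NA_real_)
    list(mean = matrix(mn, dims[1], dims[2]),
         median = med,
         std = matrix(sdv, dims[1], dims[2]),
         cv = matrix(cv, dims[1], dims[2]))
  }
  structure(
    list(xy = lapply(stack$xy, one), xz = lapply(stack$xz, one),
         xy_n = stack$xy_n, xz_n = stack$xz_n,
         xy_low_n = stack$xy_n < min_replicates_flag & stack$xy_n >= 1,
         xz_low_n = stack$xz_n < min_replicates_flag & stack$xz_n >= 1,
         n_colonies = length(stack$colony_ids),
         colony_ids = stack$colony_ids,
         normalization_mode = "raw",
         condition = stack$condition, grid = stack$grid),
    class = "profile_stats"
  )
}

#' @export
print.profile_stats <- function(x, ...) {
  cat(sprintf(
    "<profile_stats> condition '%s': %d colonies, channels %s, mode '%s'\n",
    x$condition, x$n_colonies, paste(names(x$xy), collapse = "/"),
    x$normalization_mode))
  invisible(x)
}

#' Control-based intensity normalization
#'
#' Rescales a sample's intensity array against positive and negative control
#' arrays on the same grid: `(M - Cneg) / (Cpos - Cneg)`, so the negative
#' control maps to 0 and the positive control to 1. Grid points where the
#' controls coincide are sentinel-invalid (`NA`); valid masks are
#' effectively intersected because any `NA` input propagates.
#'
#' @param sample_mean,pos_control_mean,neg_control_mean Numeric arrays of
#'   identical shape (typically per-condition mean profiles).
#' @return The normalized array, `NA` where undefined.
#' @export
normalize_with_controls <- function(sample_mean, pos_control_mean,
                                    neg_control_mean) {
  if (!identical(dim(sample_mean), dim(pos_control_mean)) ||
      !identical(dim(sample_mean), dim(neg_control_mean)))
    cp_abort("sample and control arrays must share the same shape",
             "validation")
  denom <- pos_control_mean - neg_control_mean
  out <- (sample_mean - neg_control_mean) / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  if (!any(is.finite(out)))
    cp_warn("controls coincide everywhere: control normalization is undefined")
  out
}

#' Min-max intensity normalization
#'
#' Affine rescale of a profile by the extreme intensities found in it:
#' `(I - min) / (max - min)` over valid (finite) points, so the output spans
#' exactly `[0, 1]`. Used when microscope settings cannot be standardized
#' across samples and control-based normalization is not applicable.
#'
#' @param profile Numeric array (invalid points `NA`).
#' @return The rescaled array; `NA` points are preserved.
#' @export
normalize_minmax <- function(profile) {
  v <- profile[is.finite(profile)]
  if (length(v) < 2L)
    cp_abort("need at least two valid values for min-max normalization",
             "validation")
  rng <- range(v)
  if (diff(rng) == 0)
    cp_abort("constant profile: min-max normalization undefined",
             "validation")
  (profile - rng[1]) / diff(rng)
}

#' Attach normalized mean profiles to a profile_stats object
#'
#' Applies one of the two intensity-normalization schemes to the
#' replicate-mean arrays of every plane and channel, storing the result in a
#' `normalized` slot and recording the mode.
#'
#' @param stats A `profile_stats` (mode `"raw"`).
#' @param mode `"controls"` or `"minmax"`.
#' @param pos_stats,neg_stats For `mode = "controls"`: `profile_stats` of
#'   the positive and negative control conditions on the same grid.
#' @return The updated `profile_stats` with `normalization_mode` set.
#' @export
normalize_stats <- function(stats, mode = c("controls", "minmax"),
                            pos_stats = NULL, neg_stats = NULL) {
  mode <- match.arg(mode)
  if (!inherits(stats, "profile_stats"))
    cp_abort("`stats` must be a profile_stats object", "validation")
  norm <- list()
  for (plane in c("xy", "xz")) {
    norm[[plane]] <- list()
    for (ch in names(stats[[plane]])) {
      m <- stats[[plane]][[ch]]$mean
      norm[[plane]][[ch]] <- if (mode == "controls") {
        if (is.null(pos_stats) || is.null(neg_stats))
          cp_abort("controls mode needs pos_stats and neg_stats", "validation")
        normalize_with_controls(m, pos_stats[[plane]][[ch]]$mean,
                                neg_stats[[plane]][[ch]]$mean)
      } else {
        normalize_minmax(m)
      }
    }
  }
  stats$normalized <- norm
  stats$normalization_mode <- mode
  stats
}

#' Radial profile of an XY grid image
#'
#' Averages a value matrix on the normalized XY grid over annuli of equal
#' width in normalized radius; used to locate radially symmetric features
#' such as ring-shaped expression patterns.
#'
#' @param values Matrix of shape `(n_y, n_x)` on the normalized XY grid.
#' @param grid The [reference_grid()] the matrix lives on.
#' @param nbins Number of radial bins covering `[0, 1]`.
#' @return Data frame with columns `r` (bin midpoints), `value` (annulus
#'   mean, `NA` where no valid points) and `n` (points per annulus).
#' @export
radial_profile <- function(values, grid, nbins = 64L) {
  if (!inherits(grid, "reference_grid"))
    cp_abort("`grid` must be a reference_grid", "validation")
  r <- sqrt(outer(grid$xy_y^2, grid$xy_x^2, "+"))
  breaks <- seq(0, 1, length.out = nbins + 1L)
  bin <- cut(as.vector(r), breaks, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin) & !is.na(as.vector(values))
  sums <- tabulate(bin[ok], nbins)
  tot <- vapply(split(as.vector(values)[ok], factor(bin[ok], levels = 1:nbins)),
                function(v) if (length(v)) sum(v) else NA_real_, numeric(1))
  data.frame(r = (breaks[-1] + breaks[-(nbins + 1L)]) / 2,
             value = tot / ifelse(sums > 0, sums, NA),
             n = sums)
}
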