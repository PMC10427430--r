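#' RMS contrast of an image channel
#'
#' Sample standard deviation (1/(n-1) divisor) of the masked pixel values,
#' which must already be scaled to `[0, 1]` (retardance, depolarization,
#' hue and saturation channels all are by construction).
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param mask optional logical matrix selecting the pixels to use.
#' @return non-negative scalar.
#' @export
rms_contrast_image <- function(values, mask = NULL) {
  x <- if (is.null(mask)) as.numeric(values) else as.numeric(values[mask])
  if (length(x) < 2L) stop("RMS contrast needs at least two pixels")
  if (any(x < 0 | x > 1)) stop("values must be scaled to [0, 1]")
  stats::sd(x)
}

#' RMS contrast between two category medians
#'
#' Extension of the RMS contrast to compare the median values of two
#' categories: `sqrt((m1 - m)^2 + (m2 - m)^2)` with `m = (m1 + m2)/2`,
#' i.e. `|m1 - m2| / sqrt(2)`.
#'
#' @param m1,m2 category medians in `[0, 1]`.
#' @return non-negative scalar.
#' @export
rms_contrast_medians <- function(m1, m2) {
  if (any(c(m1, m2) < 0 | c(m1, m2) > 1))
    stop("medians must lie in [0, 1]")
  mbar <- (m1 + m2) / 2
  sqrt((m1 - mbar)^2 + (m2 - mbar)^2)
}

#' Grid-unit means of a map over a region
#'
#' Tiles the image into `unit_px` x `unit_px` blocks and returns the mean of
#' every block that lies fully inside the region mask and contains no
#' invalid pixel.  Block means are treated as statistically independent in
#' the downstream tests (the blocks do not overlap).
#'
#' @param values numeric matrix, or a [parameter_map()] (whose validity mask
#'   is then used by default).
#' @param region logical matrix; `NULL` means the whole image.
#' @param valid logical matrix of per-pixel validity; units containing any
#'   invalid pixel are dropped.
#' @param unit_px unit size in pixels (16 for in-vivo style analysis, 30 for
#'   classifier sampling).
#' @return data frame of class `"roi_grid"` with columns `unit_row`,
#'   `unit_col`, `mean`.
#' @export
grid_unit_means <- function(values, region = NULL, valid = NULL,
                            unit_px = 16L) {
  if (inherits(values, "parameter_map")) {
    if (is.null(valid)) valid <- values$valid
    values <- values$values
  }
  stopifnot(unit_px >= 1L)
  H <- nrow(values); W <- ncol(values)
  if (is.null(region)) region <- matrix(TRUE, H, W)
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  nr <- H %/% unit_px; nc <- W %/% unit_px
  out <- vector("list", nr * nc)
  n <- 0L
  for (ur in seq_len(nr)) for (uc in seq_len(nc)) {
    ri <- ((ur - 1L) * unit_px + 1L):(ur * unit_px)
    ci <- ((uc - 1L) * unit_px + 1L):(uc * unit_px)
    if (all(region[ri, ci]) && all(valid[ri, ci])) {
      n <- n + 1L
      out[[n]] <- data.frame(unit_row = ur, unit_col = uc,
                             mean = mean(values[ri, ci]))
    }
  }
  if (n == 0L) stop("no grid unit survives the region/validity filter")
  res <- do.call(rbind, out[seq_len(n)])
  class(res) <- c("roi_grid", class(res))
  res
}

#' Two-sided Mann-Whitney U comparison of two groups of unit means
#'
#' Wraps [stats::wilcox.test()]: exact when both groups have at most 20
#' observations and no ties, otherwise the normal approximation with
#' continuity correction.
#'
#' @param x,y numeric vectors of (grid-unit) means.
#' @return list with `U` (statistic for `x`), `p` (two-sided) and `method`.
#' @export
mannwhitney_compare <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  exact <- length(x) <= 20L && length(y) <= 20L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # all observations tied: no evidence either way
  list(U = unname(wt$statistic), p = p, method = wt$method)
}

#' Hue and saturation channels of an RGB image
#'
#' Standard hexcone HSV conversion (via [grDevices::rgb2hsv()]); hue lives on
#' the `[0, 1]` circle.  Inputs in `[0, 255]` are auto-scaled.
#'
#' @param rgb H x W x 3 numeric array.
#' @return list with matrices `hue` and `saturation`, both in `[0, 1]`.
#' @export
hue_saturation_from_rgb <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (max(rgb) > 1) rgb <- rgb / 255
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                            g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  list(hue = matrix(hsv[1, ], H, W), saturation = matrix(hsv[2, ], H, W))
}

#' Retardance index of a polarization-microscopy colour image
#'
#' Retarding structures (collagen and other birefringent fibres) appear
#' golden to dark green between crossed polarizers; they are segmented by
#' thresholding hue in `[hue_lo, hue_hi]` (endpoints inclusive).  The index
#' is the mean grey level (`0.2989 r + 0.5870 g + 0.1140 b`, on the 0-255
#' scale) over the retarding pixels, or 0 when none are found.
#'
#' @param rgb H x W x 3 RGB image, `[0, 1]` or `[0, 255]` (auto-scaled).
#' @param hue_lo,hue_hi hue window of retarding pixels.
#' @return list with `index`, `n_retarding` and the logical `mask`.
#' @export
retardance_index <- function(rgb, hue_lo = 0.05, hue_hi = 0.45) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (max(rgb) > 1) rgb <- rgb / 255
  hs <- hue_saturation_from_rgb(rgb)
  mask <- hs$hue >= hue_lo & hs$hue <= hue_hi
  n <- sum(mask)
  if (n == 0L) return(list(index = 0, n_retarding = 0L, mask = mask))
  grey <- 255 * (0.2989 * rgb[, , 1] + 0.5870 * rgb[, , 2] +
                   0.1140 * rgb[, , 3])
  list(index = mean(grey[mask]), n_retarding = n, mask = mask)
}
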