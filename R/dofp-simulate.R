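#' Per-pixel Stokes image container
#'
#' A light-weight container for per-pixel Stokes channels.  Full images carry
#' `S0..S3`; partial images (as reconstructed from the snapshot camera) carry
#' the channels of their mode only.
#'
#' @param S0,S1,S2,S3 numeric matrices of identical dimension (partial images
#'   may omit channels by passing `NULL`).
#' @param mode `"full"`, `"retardance"` (S0,S1,S2) or `"depolarization"`
#'   (S0,S3).
#' @return list of class `"stokes_image"`.
#' @export
stokes_image <- function(S0, S1 = NULL, S2 = NULL, S3 = NULL,
                         mode = c("full", "retardance", "depolarization")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(S0))
  for (ch in list(S1, S2, S3)) {
    if (!is.null(ch)) stopifnot(identical(dim(ch), dim(S0)))
  }
  structure(list(S0 = S0, S1 = S1, S2 = S2, S3 = S3, mode = mode),
            class = "stokes_image")
}

#' @export
print.stokes_image <- function(x, ...) {
  cat(sprintf("<stokes_image> %dx%d, mode=%s\n",
              nrow(x$S0), ncol(x$S0), x$mode))
  invisible(x)
}

#' Micro-polarizer super-pixel layout
#'
#' The DoFP sensor carries a 2x2 mosaic of micro linear polarizers repeated
#' over the array.  The default reading-order assignment is 90, 45 (top row),
#' 135, 0 (bottom row) degrees; `phase` shifts the pattern for sensors whose
#' super-pixel is registered differently relative to pixel (1,1).
#'
#' @param angles_deg length-4 vector, reading order (top-left, top-right,
#'   bottom-left, bottom-right), in degrees.
#' @param phase integer length-2 (row, col) offset of the pattern.
#' @return 2x2 numeric matrix of analyzer angles in radians, with attribute
#'   `angles_deg`.
#' @export
dofp_layout <- function(angles_deg = c(90, 45, 135, 0), phase = c(0L, 0L)) {
  stopifnot(length(angles_deg) == 4L, length(phase) == 2L)
  lay <- matrix(angles_deg * pi / 180, 2, 2, byrow = TRUE)
  if (phase[1] %% 2 == 1) lay <- lay[c(2, 1), ]
  if (phase[2] %% 2 == 1) lay <- lay[, c(2, 1)]
  structure(lay, angles_deg = angles_deg, phase = as.integer(phase %% 2))
}

# Full H x W map of micro-polarizer angles (radians) for a layout.
layout_angle_map <- function(layout, H, W) {
  ri <- ((seq_len(H) - 1L) %% 2L) + 1L
  ci <- ((seq_len(W) - 1L) %% 2L) + 1L
  matrix(layout[cbind(rep(ri, times = W), rep(ci, each = H))], H, W)
}

#' Fixed-pattern calibration map
#'
#' Per-pixel multiplicative gain and additive offset of the DoFP sensor.  The
#' gain field models the variable diattenuation of the micro-polarizers (the
#' dominant fixed-pattern noise source); the offset models the dark level.
#'
#' @param gain H x W matrix of positive factors.
#' @param offset H x W matrix of additive counts (default 0).
#' @return list of class `"calibration_map"`.
#' @export
calibration_map <- function(gain, offset = NULL) {
  stopifnot(is.matrix(gain), all(gain > 0))
  if (is.null(offset)) offset <- matrix(0, nrow(gain), ncol(gain))
  stopifnot(identical(dim(offset), dim(gain)))
  structure(list(gain = gain, offset = offset), class = "calibration_map")
}

#' Simulate a raw DoFP mosaic frame
#'
#' Forward model of the snapshot polarization camera.  Each pixel sees the
#' scene through its micro linear polarizer at angle `alpha`, so the
#' noise-free expected count is
#' `gain * exposure_scale * (S0 + S1*cos(2*alpha) + S2*sin(2*alpha))/2 + offset`.
#' In depolarization mode a quarter-wave plate in front of the sensor maps
#' the circular components onto the 0/90 analyzer pair before projection.
#' Shot noise (Poisson on the photo-signal), Gaussian read noise, clipping
#' and quantization to `bitdepth` follow in that order.
#'
#' @param scene a [stokes_image()] (mode `"full"`).
#' @param layout a [dofp_layout()].
#' @param calibration a [calibration_map()], or `NULL` for a unit sensor.
#' @param mode `"retardance"` (no waveplate) or `"depolarization"` (quarter
#'   waveplate at 45 degrees to the super-pixel axes).
#' @param exposure_scale counts per unit of scene `S0` (sets the shot-noise
#'   level; the noise-free count at an unpolarized pixel of `S0 = 1` is
#'   `exposure_scale / 2`).
#' @param noise list with `shot` (logical) and `read_sd` (counts).
#' @param bitdepth bits per output pixel.
#' @param seed integer seed for the noise draws (ignored when noise-free).
#' @param quantize logical; set `FALSE` to return the continuous noise-free
#'   expectation (used by round-trip tests).
#' @return integer (or numeric if `quantize = FALSE`) matrix of class
#'   `"mosaic_frame"` with attributes `bitdepth` and `layout`.
#' @export
simulate_dofp_mosaic <- function(scene, layout = dofp_layout(),
                                 calibration = NULL,
                                 mode = c("retardance", "depolarization"),
                                 exposure_scale = 255,
                                 noise = list(shot = FALSE, read_sd = 0),
                                 bitdepth = 8L, seed = NULL,
                                 quantize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "stokes_image"), scene$mode == "full")
  H <- nrow(scene$S0); W <- ncol(scene$S0)
  if (H %% 2 != 0 || W %% 2 != 0) stop("image dimensions must be even")
  if (exposure_scale < 0) stop("exposure_scale must be non-negative")

  S0 <- scene$S0; S1 <- scene$S1; S2 <- scene$S2; S3 <- scene$S3
  if (mode == "depolarization") {
    # quarter waveplate ahead of the sensor; under the package handedness
    # convention the mount angle that routes the polarization-maintaining
    # circular component to the 0-degree analyzer is -45 degrees.
    Q <- mueller_linear_retarder(pi / 2, -pi / 4)
    s1 <- Q[2, 2] * S1 + Q[2, 3] * S2 + Q[2, 4] * S3
    s2 <- Q[3, 2] * S1 + Q[3, 3] * S2 + Q[3, 4] * S3
    S1 <- s1; S2 <- s2
  }

  alpha <- layout_angle_map(layout, H, W)
  signal <- 0.5 * (S0 + S1 * cos(2 * alpha) + S2 * sin(2 * alpha))
  signal[signal < 0] <- 0        # guard tiny negatives from noisy scenes

  if (is.null(calibration)) {
    gain <- matrix(1, H, W); offset <- matrix(0, H, W)
  } else {
    stopifnot(identical(dim(calibration$gain), c(H, W)))
    gain <- calibration$gain; offset <- calibration$offset
  }

  lambda <- gain * exposure_scale * signal
  counts <- lambda
  shot <- isTRUE(noise$shot)
  read_sd <- if (is.null(noise$read_sd)) 0 else noise$read_sd
  if (shot || read_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    if (shot) counts <- matrix(stats::rpois(H * W, lambda), H, W)
    if (read_sd > 0) counts <- counts + stats::rnorm(H * W, 0, read_sd)
  }
  counts <- counts + offset

  if (quantize) {
    maxv <- 2^bitdepth - 1
    counts <- floor(pmin(pmax(counts, 0), maxv) + 0.5)
  }
  structure(counts, class = c("mosaic_frame", class(counts)),
            bitdepth = as.integer(bitdepth), layout = layout, mode = mode)
}

#' Estimate the fixed-pattern calibration from flat-field frames
#'
#' Uses mosaic frames of spatially uniform, unpolarized illumination: every
#' orientation then expects the same count, so the per-pixel gain is the
#' pixel value divided by the mean over all pixels sharing its orientation.
#' Dark frames, when supplied, estimate the per-pixel offset.
#'
#' @param flats list of flat-field mosaic frames (or a single matrix).
#' @param darks optional list of dark frames for the offset.
#' @param layout a [dofp_layout()].
#' @return a [calibration_map()].
#' @export
estimate_calibration <- function(flats, darks = NULL, layout = dofp_layout()) {
  if (is.matrix(flats)) flats <- list(flats)
  flat <- Reduce(`+`, lapply(flats, unclass)) / length(flats)
  offset <- if (is.null(darks)) {
    matrix(0, nrow(flat), ncol(flat))
  } else {
    if (is.matrix(darks)) darks <- list(darks)
    Reduce(`+`, lapply(darks, unclass)) / length(darks)
  }
  flat <- flat - offset
  alpha <- layout_angle_map(layout, nrow(flat), ncol(flat))
  gain <- flat
  for (a in unique(as.vector(layout))) {
    idx <- abs(alpha - a) < 1e-12
    gain[idx] <- flat[idx] / mean(flat[idx])
  }
  calibration_map(gain, offset)
}

#' Correct fixed-pattern gain and offset of a raw mosaic
#'
#' @param raw mosaic frame (integer counts).
#' @param calibration a [calibration_map()] matching the frame dimensions.
#' @return numeric matrix of corrected counts, floored at zero, preserving
#'   the `mosaic_frame` attributes.
#' @export
correct_fixed_pattern <- function(raw, calibration) {
  if (!identical(dim(calibration$gain), dim(raw)))
    stop("calibration dimensions do not match the frame")
  out <- (unclass(raw) - calibration$offset) / calibration$gain
  out[out < 0] <- 0
  attributes(out) <- attributes(raw)[c("dim", "bitdepth", "layout", "mode")]
  class(out) <- c("mosaic_frame", "matrix", "array")
  out
}
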