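# 1-D linear interpolation operator from sample positions `pos` (increasing)
# onto targets 1..n, with edge replication outside [min(pos), max(pos)].
# Returns an n x length(pos) sparse-pattern dense matrix.
interp_operator <- function(pos, n) {
  m <- length(pos)
  Wm <- matrix(0, n, m)
  j <- findInterval(seq_len(n), pos)          # 0 .. m
  for (i in seq_len(n)) {
    k <- j[i]
    if (k <= 0) {
      Wm[i, 1] <- 1
    } else if (k >= m) {
      Wm[i, m] <- 1
    } else {
      w <- (i - pos[k]) / (pos[k + 1] - pos[k])
      Wm[i, k] <- 1 - w
      Wm[i, k + 1] <- w
    }
  }
  Wm
}

#' Demosaic a corrected DoFP frame by bilinear interpolation
#'
#' Splits the mosaic into its four orientation sub-lattices and interpolates
#' each to full resolution.  At native sites the sub-image equals the mosaic
#' value; elsewhere values are bilinear in the same-orientation neighbours,
#' with edge replication outside the outermost native sites (so a 2-pixel
#' border is approximate and is excluded by the round-trip tests).
#'
#' @param mosaic corrected mosaic frame (from [correct_fixed_pattern()], or
#'   any matrix with even dimensions).
#' @param layout a [dofp_layout()]; taken from the frame attribute when
#'   present.
#' @return list of class `"sub_images"` with full-resolution matrices
#'   `I0`, `I45`, `I90`, `I135`.
#' @export
demosaic_bilinear <- function(mosaic, layout = NULL) {
  if (is.null(layout)) layout <- attr(mosaic, "layout")
  if (is.null(layout)) layout <- dofp_layout()
  x <- unclass(mosaic)
  attributes(x) <- list(dim = dim(x))
  H <- nrow(x); W <- ncol(x)
  if (H %% 2 != 0 || W %% 2 != 0) stop("image dimensions must be even")

  deg <- round(layout * 180 / pi) %% 180
  out <- list()
  for (r0 in 1:2) for (c0 in 1:2) {
    rows <- seq(r0, H, by = 2)
    cols <- seq(c0, W, by = 2)
    D <- x[rows, cols, drop = FALSE]
    full <- interp_operator(rows, H) %*% D %*% t(interp_operator(cols, W))
    out[[paste0("I", deg[r0, c0])]] <- full
  }
  need <- c("I0", "I45", "I90", "I135")
  if (!all(need %in% names(out))) stop("unknown micro-polarizer layout")
  structure(out[need], class = "sub_images")
}

#' Partial-Stokes reconstruction from orientation sub-images
#'
#' `partial_stokes_linear()` implements the retardance-mode reconstruction
#' (no waveplate): `S0 = (I0+I45+I90+I135)/2`, `S1 = I0-I90`,
#' `S2 = I45-I135`.  `partial_stokes_circular()` implements the
#' depolarization mode, where the quarter waveplate makes the 0/90 pair
#' analyze the two circular components: `S0 = I0+I90`, `S3 = I0-I90`.
#'
#' @param sub a [demosaic_bilinear()] result.
#' @return a partial [stokes_image()] in the corresponding mode.
#' @export
partial_stokes_linear <- function(sub) {
  stokes_image(S0 = (sub$I0 + sub$I45 + sub$I90 + sub$I135) / 2,
               S1 = sub$I0 - sub$I90,
               S2 = sub$I45 - sub$I135,
               mode = "retardance")
}

#' @rdname partial_stokes_linear
#' @export
partial_stokes_circular <- function(sub) {
  stokes_image(S0 = sub$I0 + sub$I90,
               S3 = sub$I0 - sub$I90,
               mode = "depolarization")
}

#' Scalar parameter map container
#'
#' @param values H x W matrix in `[0, 1]` (wherever valid).
#' @param valid H x W logical validity mask.
#' @param kind `"A_delta"` (retardance magnitude), `"A_dep"` (circular
#'   depolarization), `"T_dep"` (total depolarization) or `"D"`
#'   (diattenuation).
#' @return list of class `"parameter_map"`.
#' @export
parameter_map <- function(values, valid = NULL,
                          kind = c("A_delta", "A_dep", "T_dep", "D")) {
  kind <- match.arg(kind)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(identical(dim(valid), dim(values)))
  structure(list(values = values, valid = valid, kind = kind),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<parameter_map %s> %dx%d, %.1f%% valid, range [%.3f, %.3f]\n",
              x$kind, nrow(x$values), ncol(x$values),
              100 * mean(x$valid), min(v), max(v)))
  invisible(x)
}

#' Retardance magnitude map from the linear partial-Stokes image
#'
#' Computes the degree of linear polarization of the emergent light,
#' `A_delta = sqrt(S1^2 + S2^2) / S0`, clipped to `[0, 1]`.  Under circular
#' illumination of a pure linear retarder this equals `|sin(delta_L)|`, the
#' magnitude of linear phase retardance.
#'
#' @param ps partial [stokes_image()] in retardance mode.
#' @param valid optional logical mask ANDed into the result (e.g. from
#'   [exposure_mask()]).
#' @return a [parameter_map()] of kind `"A_delta"`; pixels with `S0 <= 0`
#'   are marked invalid.
#' @export
retardance_map <- function(ps, valid = NULL) {
  stopifnot(ps$mode == "retardance")
  ok <- ps$S0 > 0
  v <- matrix(0, nrow(ps$S0), ncol(ps$S0))
  v[ok] <- sqrt(ps$S1[ok]^2 + ps$S2[ok]^2) / ps$S0[ok]
  v <- pmin(pmax(v, 0), 1)
  if (!is.null(valid)) ok <- ok & valid
  parameter_map(v, ok, "A_delta")
}

#' Circular depolarization map from the circular partial-Stokes image
#'
#' Computes `A_dep = 1 - |S3 / S0|`, clipped to `[0, 1]`: the fraction of
#' the backscattered intensity that no longer maintains the circular
#' illumination polarization.  For strongly retarding media this
#' over-estimates depolarization, since retardance converts circular to
#' linear polarization which this mode cannot see (a pure retarder of phase
#' `delta` reads `A_dep = 1 - |cos(delta)|`).
#'
#' @inheritParams retardance_map
#' @param ps partial [stokes_image()] in depolarization mode.
#' @return a [parameter_map()] of kind `"A_dep"`.
#' @export
depolarization_map <- function(ps, valid = NULL) {
  stopifnot(ps$mode == "depolarization")
  ok <- ps$S0 > 0
  v <- matrix(0, nrow(ps$S0), ncol(ps$S0))
  v[ok] <- 1 - abs(ps$S3[ok] / ps$S0[ok])
  v <- pmin(pmax(v, 0), 1)
  if (!is.null(valid)) ok <- ok & valid
  parameter_map(v, ok, "A_dep")
}

#' Exposure validity mask from the intensity reference
#'
#' Flags low-image-quality pixels by thresholding the pre-gamma intensity
#' reference: overexposed where `S0_in / 2 > 0.95 * (2^bitdepth - 1)` (e.g.
#' specular highlights) and underexposed where
#' `S0_in / 2 < 0.03 * (2^bitdepth - 1)` (e.g. blood).  Invalid pixels are
#' excluded from all downstream statistics and rendered green.
#'
#' @param S0_in intensity-reference matrix on the raw (pre-gamma) count
#'   scale of the partial-Stokes reconstruction.
#' @param bitdepth bits per pixel of the raw frames.
#' @param lo,hi threshold fractions of full scale.
#' @return logical matrix, `TRUE` where the pixel is usable.
#' @export
exposure_mask <- function(S0_in, bitdepth = 8L, lo = 0.03, hi = 0.95) {
  maxv <- 2^bitdepth - 1
  half <- S0_in / 2
  half <= hi * maxv & half >= lo * maxv
}

#' Gamma correction of a normalized intensity reference
#'
#' `S0_out = S0_in^gamma` on inputs scaled to `[0, 1]`; monotone with fixed
#' endpoints.  The default `gamma = 1/2` brightens dark peripheral regions.
#'
#' @param S0_in numeric matrix (or vector) in `[0, 1]`.
#' @param gamma positive exponent.
#' @return transformed values, same shape.
#' @export
gamma_correct <- function(S0_in, gamma = 0.5) {
  if (gamma <= 0) stop("gamma must be positive")
  if (any(S0_in < 0 | S0_in > 1, na.rm = TRUE))
    stop("gamma correction expects inputs normalized to [0, 1]")
  S0_in^gamma
}

# Gaussian blur with edge replication, separable, via banded operators.
gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(n) {
    Wm <- matrix(0, n, n)
    for (d in seq(-half, half)) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n)   # replicate edges
      Wm[cbind(seq_len(n), idx)] <- Wm[cbind(seq_len(n), idx)] + k[d + half + 1]
    }
    Wm
  }
  blur1(nrow(img)) %*% img %*% t(blur1(ncol(img)))
}

#' Unsharp masking of an intensity image
#'
#' `out = img + amount * (img - blur(img))` with a Gaussian blur of standard
#' deviation `radius` pixels, clipped back to `[0, 1]`.  Cosmetic only: off
#' by default in every quantitative path.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param radius Gaussian sigma in pixels.
#' @param amount strength of the high-frequency boost.
#' @return sharpened matrix in `[0, 1]`.
#' @export
unsharp_mask <- function(img, radius = 2, amount = 0.8) {
  out <- img + amount * (img - gaussian_blur(img, radius))
  pmin(pmax(out, 0), 1)
}

#' Render a parameter map to RGB
#'
#' Valid pixels are colour-mapped over `[0, 1]`; invalid pixels are rendered
#' pure green so they cannot be mistaken for measurements.  Rendering never
#' modifies the map.
#'
#' @param map a [parameter_map()].
#' @param palette vector of colours spanning value 0 to 1.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
render_map <- function(map, palette = grDevices::hcl.colors(256, "Viridis")) {
  H <- nrow(map$values); W <- ncol(map$values)
  idx <- pmin(pmax(floor(map$values * (length(palette) - 1)) + 1L, 1L),
              length(palette))
  rgbm <- grDevices::col2rgb(palette[idx]) / 255   # 3 x (H*W)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgbm[ch, ], H, W)
  inv <- !map$valid
  if (any(inv)) {
    r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
    r[inv] <- 0; g[inv] <- 1; b[inv] <- 0
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  }
  out
}

#' Intensity reference with optional gamma correction and sharpening
#'
#' Normalizes the pre-gamma reference to `[0, 1]` by full scale
#' (`2^bitdepth`, times 2 for the half-sum scale of the linear mode),
#' applies [gamma_correct()] and optionally [unsharp_mask()].
#'
#' @param S0_in raw-scale intensity reference from the partial-Stokes step.
#' @param bitdepth raw bit depth.
#' @param gamma exponent for [gamma_correct()]; `NULL` skips it.
#' @param sharpen logical; apply [unsharp_mask()] after gamma.
#' @return list with `S0_in`, `S0_out` (in `[0, 1]`) and `gamma`.
#' @export
intensity_reference <- function(S0_in, bitdepth = 8L, gamma = 0.5,
                                sharpen = FALSE) {
  maxv <- 2 * (2^bitdepth - 1)      # S0 of Eqns spans twice the pixel scale
  x <- pmin(pmax(S0_in / maxv, 0), 1)
  if (!is.null(gamma)) x <- gamma_correct(x, gamma)
  if (sharpen) x <- unsharp_mask(x)
  list(S0_in = S0_in, S0_out = x, gamma = if (is.null(gamma)) 1 else gamma)
}
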