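#' Construct a Stokes vector
#'
#' A Stokes vector `(S0, S1, S2, S3)` describes the intensity and polarization
#' state of a light beam: `S0` is the total intensity (arbitrary linear units),
#' `S1` the 0/90 degree linear difference, `S2` the +/-45 degree linear
#' difference and `S3` the circular difference.  The package convention is
#' `S3 > 0` for right-circular light (see `vignette("endopol-methods")`).
#'
#' @param S0,S1,S2,S3 numeric scalars.
#' @return A numeric vector of length 4 with class `"stokes"`.
#' @examples
#' stokes(1, 0, 0, 1)          # right-circular
#' @export
stokes <- function(S0, S1 = 0, S2 = 0, S3 = 0) {
  s <- c(S0, S1, S2, S3)
  stopifnot(is.numeric(s), length(s) == 4L, all(is.finite(s)))
  if (S0 < 0) stop("S0 must be non-negative")
  structure(s, class = "stokes")
}

#' @export
print.stokes <- function(x, ...) {
  cat(sprintf("<stokes> S0=%.4g S1=%.4g S2=%.4g S3=%.4g\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Test physical admissibility of a Stokes vector
#'
#' A Stokes vector is physical when the polarized part does not exceed the
#' total intensity: `sqrt(S1^2 + S2^2 + S3^2) <= S0 * (1 + tol)`.
#'
#' @param S numeric length-4 vector.
#' @param tol relative tolerance; default `1e-9` suits noise-free algebra,
#'   raise it for measured or noisy states.
#' @return logical scalar.
#' @export
is_physical_stokes <- function(S, tol = 1e-9) {
  S <- as.numeric(S)
  S[1] >= 0 && sqrt(sum(S[2:4]^2)) <= S[1] * (1 + tol) + tol
}

#' Degrees of polarization of a Stokes vector
#'
#' Computes the total, linear and circular degrees of polarization:
#' `dop = sqrt(S1^2+S2^2+S3^2)/S0`, `dolp = sqrt(S1^2+S2^2)/S0`,
#' `docp = |S3|/S0`.
#'
#' @param S numeric length-4 Stokes vector with `S0 > 0`.
#' @return named list with elements `dop`, `dolp`, `docp`.
#' @examples
#' polarization_degrees(stokes(1, 0, 0, 1))   # fully circular
#' @export
polarization_degrees <- function(S) {
  S <- as.numeric(S)
  if (S[1] <= 0) stop("degree of polarization undefined for S0 <= 0")
  list(dop  = sqrt(sum(S[2:4]^2)) / S[1],
       dolp = sqrt(S[2]^2 + S[3]^2) / S[1],
       docp = abs(S[4]) / S[1])
}

#' Stokes state of the endoscope illumination
#'
#' The circularly polarizing tip attachment produces nearly ideal circular
#' illumination; the characterized state has a residual linear component
#' (degree of linear polarization about 0.028).  `ideal = TRUE` returns the
#' exact right-circular state used for analytic round-trip work.
#'
#' @param ideal logical; return `(1,0,0,1)` instead of the characterized state.
#' @return a [stokes()] vector.
#' @export
spe_illumination <- function(ideal = TRUE) {
  if (ideal) stokes(1, 0, 0, 1) else stokes(1.000, -0.002, 0.028, 0.999)
}
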