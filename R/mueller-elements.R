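#' Mueller matrices of canonical optical elements
#'
#' Constructors for the ideal polarization elements used throughout the
#' simulator and the decomposition: linear retarder, linear polarizer,
#' diagonal depolarizer and Lu-Chipman diattenuator.  All angles are in
#' radians.  The sign convention is fixed package-wide: `S3 > 0` is
#' right-circular, and the retarder with fast axis `theta` and phase `delta`
#' has elements
#' \deqn{M_R(\delta,\theta) = \begin{pmatrix}
#'   1 & 0 & 0 & 0\\
#'   0 & c^2 + s^2\cos\delta & cs(1-\cos\delta) & -s\sin\delta\\
#'   0 & cs(1-\cos\delta) & s^2 + c^2\cos\delta & c\sin\delta\\
#'   0 & s\sin\delta & -c\sin\delta & \cos\delta
#' \end{pmatrix}}
#' with \eqn{c = \cos 2\theta}, \eqn{s = \sin 2\theta}.
#'
#' @param delta retardance phase in radians (wrapped to `[0, 2*pi)`).
#' @param theta fast-axis (retarder) or transmission-axis (polarizer) angle in
#'   radians (wrapped to `[0, pi)`).
#' @return A 4x4 numeric matrix.
#' @name mueller_elements
NULL

wrap_angle <- function(x, period) {
  x - period * floor(x / period)
}

#' @rdname mueller_elements
#' @examples
#' mueller_linear_retarder(pi / 2, 0)   # quarter-wave plate, fast axis at 0
#' @export
mueller_linear_retarder <- function(delta, theta = 0) {
  delta <- wrap_angle(delta, 2 * pi)
  theta <- wrap_angle(theta, pi)
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  cd <- cos(delta); sd <- sin(delta)
  matrix(c(
    1, 0,                      0,                      0,
    0, c2^2 + s2^2 * cd,       c2 * s2 * (1 - cd),    -s2 * sd,
    0, c2 * s2 * (1 - cd),     s2^2 + c2^2 * cd,       c2 * sd,
    0, s2 * sd,               -c2 * sd,                cd
  ), nrow = 4, byrow = TRUE)
}

#' @rdname mueller_elements
#' @export
mueller_linear_polarizer <- function(theta = 0) {
  theta <- wrap_angle(theta, pi)
  c2 <- cos(2 * theta); s2 <- sin(2 * theta)
  0.5 * matrix(c(
    1,       c2,      s2,      0,
    c2,      c2^2,    c2 * s2, 0,
    s2,      c2 * s2, s2^2,    0,
    0,       0,       0,       0
  ), nrow = 4, byrow = TRUE)
}

#' @rdname mueller_elements
#' @param a,b,c linear (0/90), linear (45/135) and circular depolarization
#'   factors in `[0, 1]`; 1 preserves polarization, 0 fully depolarizes.
#' @export
mueller_depolarizer <- function(a = 1, b = a, c = a) {
  f <- c(a, b, c)
  if (any(f < 0 | f > 1)) stop("depolarizer factors must lie in [0, 1]")
  diag(c(1, f))
}

#' @rdname mueller_elements
#' @param D diattenuation 3-vector with `|D| <= 1`.
#' @export
mueller_diattenuator <- function(D) {
  D <- as.numeric(D)
  stopifnot(length(D) == 3L)
  d <- sqrt(sum(D^2))
  if (d > 1 + 1e-12) stop("|D| must not exceed 1")
  mD <- sqrt(max(0, 1 - d^2)) * diag(3)
  if (d > 0) {
    Dh <- D / d
    mD <- mD + (1 - sqrt(max(0, 1 - d^2))) * tcrossprod(Dh)
  }
  out <- rbind(c(1, D), cbind(D, mD))
  dimnames(out) <- NULL
  out
}

#' Apply a Mueller matrix to a Stokes vector
#'
#' @param M 4x4 Mueller matrix.
#' @param S length-4 Stokes vector.
#' @return the emergent Stokes vector (plain numeric, length 4).
#' @export
apply_mueller <- function(M, S) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  as.numeric(M %*% as.numeric(S))
}
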