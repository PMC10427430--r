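#' Polarization state generator matrix
#'
#' The generator is a 0-degree linear polarizer followed by a quarter
#' waveplate on a rotation stage.  Column `k` of the returned matrix is the
#' Stokes state emitted with the waveplate at `qwp_angles_deg[k]`,
#' renormalized to `S0 = 1`:
#' `(1, cos^2(2t), cos(2t) sin(2t), sin(2t))` for waveplate angle `t`.
#'
#' @param qwp_angles_deg waveplate fast-axis angles in degrees; the default
#'   set is -45, 0, 30, 60.
#' @return 4x4 matrix `W` whose columns are the generator states.
#' @export
build_psg <- function(qwp_angles_deg = c(-45, 0, 30, 60)) {
  th <- unique(qwp_angles_deg)
  if (length(th) != 4L) stop("four distinct waveplate angles are required")
  pol0 <- mueller_linear_polarizer(0)
  W <- vapply(th * pi / 180, function(t) {
    s <- apply_mueller(mueller_linear_retarder(pi / 2, t),
                       apply_mueller(pol0, c(1, 0, 0, 0)))
    s / s[1]
  }, numeric(4))
  if (abs(det(W)) < 1e-8)
    stop("waveplate angle set yields a singular generator matrix")
  W
}

#' Polarization state analyser matrix
#'
#' Six analyser channels: linear polarizers at -45, 0, 45 and 90 degrees and
#' left/right circular polarizers.  Row `j` is the first row of the j-th
#' analyser Mueller matrix, so the measured intensity for input Stokes `S`
#' is `A[j, ] %*% S`.
#'
#' @return 6x4 matrix `A` of analyser vectors (rank 4).
#' @export
build_psa <- function() {
  lin <- t(vapply(c(-45, 0, 45, 90) * pi / 180,
                  function(t) mueller_linear_polarizer(t)[1, ], numeric(4)))
  circ <- 0.5 * rbind(c(1, 0, 0, -1),   # left circular analyser
                      c(1, 0, 0, 1))    # right circular analyser
  rbind(lin, circ)
}

#' Mueller polarimeter instrument model
#'
#' Bundles the generator and analyser matrices and precomputes the 24 x 16
#' forward operator mapping a vectorized Mueller matrix to the 24 measured
#' intensities (rows ordered analyser-fastest: measurement
#' `(j, k)` sits at row `(k - 1) * 6 + j`).
#'
#' @param W 4x4 generator matrix (columns = states), see [build_psg()].
#' @param A 6x4 analyser matrix (rows = analyser vectors), see [build_psa()].
#' @return list of class `"instrument_model"` with `W`, `A`, the forward
#'   operator `B` and its condition number `kappa`.
#' @export
instrument_model <- function(W = build_psg(), A = build_psa()) {
  if (qr(W)$rank < 4L) stop("generator matrix W is singular")
  if (qr(A)$rank < 4L) stop("analyser matrix A is rank deficient")
  # I[j,k] = a_j' M w_k = (w_k' \otimes a_j') vec(M)  (column-major vec)
  B <- matrix(0, 24, 16)
  for (k in 1:4) for (j in 1:6) {
    B[(k - 1) * 6 + j, ] <- kronecker(t(W[, k]), t(A[j, ]))
  }
  sv <- svd(B, nu = 0, nv = 0)$d
  structure(list(W = W, A = A, B = B, kappa = sv[1] / sv[length(sv)]),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf("<instrument_model> 6 analysers x 4 generator states, cond = %.2f\n",
              x$kappa))
  invisible(x)
}

#' Perturbed copy of an instrument model
#'
#' Adds zero-mean Gaussian errors to every element of `W` and `A`, emulating
#' residual calibration error of a real polarimeter.  Useful for studying
#' how instrument-matrix errors propagate into reconstructed Mueller
#' elements.
#'
#' @param inst an [instrument_model()].
#' @param sd elementwise error standard deviation (absolute).
#' @param seed integer seed.
#' @return a new [instrument_model()].
#' @export
perturb_instrument <- function(inst, sd = 0.005, seed = 1L) {
  set.seed(seed)
  instrument_model(inst$W + matrix(stats::rnorm(16, 0, sd), 4, 4),
                   inst$A + matrix(stats::rnorm(24, 0, sd), 6, 4))
}

#' Per-pixel Mueller matrix image
#'
#' @param M array of dimension `c(H, W, 4, 4)` (per-pixel Mueller matrices),
#'   or a single 4x4 matrix which is promoted to a 1x1 image.
#' @param valid optional H x W logical mask (default: `m00 > 0`).
#' @return list of class `"mueller_image"`.
#' @export
mueller_image <- function(M, valid = NULL) {
  if (is.matrix(M) && all(dim(M) == 4L)) M <- array(M, c(1, 1, 4, 4))
  stopifnot(length(dim(M)) == 4L, all(dim(M)[3:4] == 4L))
  if (is.null(valid)) valid <- M[, , 1, 1] > 0
  if (is.null(dim(valid))) valid <- matrix(valid, dim(M)[1], dim(M)[2])
  structure(list(M = M, valid = valid), class = "mueller_image")
}

# 16 x N matrix of column-major vectorized per-pixel Mueller matrices.
vec_mueller <- function(img) {
  d <- dim(img$M)
  matrix(aperm(img$M, c(3, 4, 1, 2)), nrow = 16, ncol = d[1] * d[2])
}

unvec_mueller <- function(V, H, W) {
  aperm(array(V, c(4, 4, H, W)), c(3, 4, 1, 2))
}

#' Simulate a Mueller polarimeter intensity stack
#'
#' Forward model of the acquisition: for every pixel and every combination
#' of generator state `w_k` and analyser `a_j`, the measured intensity is
#' `a_j' M w_k`, optionally with additive Gaussian noise.
#'
#' @param M_img a [mueller_image()].
#' @param instrument an [instrument_model()].
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed for the noise.
#' @return array of dimension `c(H, W, 24)` of class `"intensity_stack"`,
#'   measurement `(j, k)` in slice `(k - 1) * 6 + j`.
#' @export
simulate_stack <- function(M_img, instrument = instrument_model(),
                           noise_sd = 0, seed = NULL) {
  d <- dim(M_img$M)
  I <- instrument$B %*% vec_mueller(M_img)       # 24 x N
  if (min(I) < -1e-9)
    stop("non-physical Mueller image: negative noise-free intensity")
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + matrix(stats::rnorm(length(I), 0, noise_sd), nrow(I), ncol(I))
  }
  structure(array(t(I), c(d[1], d[2], 24)), class = "intensity_stack")
}

#' Least-squares Mueller matrix reconstruction
#'
#' Solves, per pixel, the over-determined 24-equation linear system
#' `I = B vec(M)` in the least-squares sense.  All pixels are solved in one
#' batched QR solve; the result is bit-identical to a per-pixel loop.
#'
#' @param stack an [simulate_stack()] array (or any `c(H, W, 24)` array in
#'   the same measurement order).
#' @param instrument the [instrument_model()] used for the acquisition.
#' @return a [mueller_image()]; pixels with non-positive `m00` are marked
#'   invalid.
#' @export
reconstruct_mueller <- function(stack, instrument = instrument_model()) {
  if (qr(instrument$B)$rank < 16L)
    stop("instrument forward operator is rank deficient")
  d <- dim(stack)
  stopifnot(length(d) == 3L, d[3] == 24L)
  I <- t(matrix(stack, nrow = d[1] * d[2], ncol = 24))   # 24 x N
  V <- qr.solve(instrument$B, I)                         # 16 x N
  mueller_image(unvec_mueller(V, d[1], d[2]))
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors a (normalized) Mueller matrix as `M = M_delta M_R M_D`: a
#' depolarizer, a retarder and a diattenuator, in that order.  The
#' diattenuation vector is read off the first row; the depolarizer block is
#' the symmetric square root of `m' m''` obtained from its eigenvalues with
#' the sign of `det(m')`; the retarder block is what remains.  Scalar
#' summaries follow the standard definitions:
#' total depolarization `T_dep = 1 - (tr(M_delta) - 1)/3`, circular
#' depolarization `A_dep = 1 - |M_delta[4,4]|`, retardance angle
#' `R = acos(tr(M_R)/2 - 1)` on `[0, pi]` and retardance magnitude
#' `A_delta = sin(R)`.
#'
#' @param M 4x4 Mueller matrix with `m00 > 0` (normalized internally).
#' @param tol relative eigenvalue threshold below which the depolarizer
#'   block is treated as singular and an SVD branch is used.
#' @return list of class `"polar_decomposition"` with components `M_delta`,
#'   `M_R`, `M_D`, scalars `T_dep`, `A_dep`, `R`, `A_delta`, `D`, the input
#'   transmittance `m00` and a `degenerate` flag.
#' @export
lu_chipman <- function(M, tol = 1e-12) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  m00 <- M[1, 1]
  if (m00 <= 0) stop("lu_chipman requires m00 > 0")
  M <- M / m00

  Dv <- M[1, 2:4]
  Dmag <- sqrt(sum(Dv^2))
  M_D <- mueller_diattenuator(if (Dmag > 1) Dv / Dmag else Dv)
  Mp <- if (Dmag < 1 - 1e-9) M %*% solve(M_D) else M %*% MASS_ginv(M_D)
  Pd <- Mp[2:4, 1]
  mp <- Mp[2:4, 2:4]

  mm <- mp %*% t(mp)
  ev <- eigen(mm, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  s <- sqrt(lam)
  degenerate <- lam[3] < tol * max(lam[1], 1)

  if (!degenerate) {
    sgn <- if (det(mp) < 0) -1 else 1
    m_delta <- sgn * solve(mm + (s[1] * s[2] + s[2] * s[3] + s[3] * s[1]) * diag(3),
                           (s[1] + s[2] + s[3]) * mm + s[1] * s[2] * s[3] * diag(3))
    m_R <- solve(m_delta, mp)
  } else {
    # fully (or nearly) depolarizing in at least one channel: pseudo-inverse
    # branch via SVD; the retarder is the orthogonal factor of m'.
    sv <- svd(mp)
    sgn <- if (det(sv$u %*% t(sv$v)) < 0) -1 else 1
    m_R <- sv$u %*% diag(c(1, 1, sgn)) %*% t(sv$v)
    m_delta <- mp %*% t(m_R)
  }

  M_delta <- rbind(c(1, 0, 0, 0), cbind(Pd, m_delta))
  M_R <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), m_R))

  R <- acos(pmin(pmax(sum(diag(M_R)) / 2 - 1, -1), 1))
  structure(list(
    M_delta = M_delta, M_R = M_R, M_D = M_D,
    T_dep = as.numeric(1 - (sum(diag(M_delta)) - 1) / 3),
    A_dep = as.numeric(1 - abs(M_delta[4, 4])),
    R = as.numeric(R), A_delta = as.numeric(sin(R)), D = Dmag,
    m00 = m00, degenerate = degenerate
  ), class = "polar_decomposition")
}

# Moore-Penrose pseudo-inverse (small matrices only).
MASS_ginv <- function(X, tol = 1e-12) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
print.polar_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<polar_decomposition> T_dep=%.4f A_dep=%.4f R=%.4f rad ",
                     "A_delta=%.4f D=%.4f%s\n"),
              x$T_dep, x$A_dep, x$R, x$A_delta, x$D,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Scalar maps from a Mueller image via per-pixel decomposition
#'
#' Applies [lu_chipman()] to every valid pixel.  The depolarization map uses
#' the circular term `A_dep = 1 - |M_delta[4,4]|` (matching the snapshot
#' depolarization mode); the total depolarization `T_dep` and diattenuation
#' `D` maps are returned alongside.
#'
#' @param M_img a [mueller_image()].
#' @return list with [parameter_map()]s `retardance`, `depolarization`,
#'   `T_dep`, `D` and a logical matrix `degenerate`.
#' @export
decomposition_maps <- function(M_img) {
  d <- dim(M_img$M)
  H <- d[1]; W <- d[2]
  ret <- dep <- tdep <- dia <- matrix(0, H, W)
  degen <- matrix(FALSE, H, W)
  ok <- M_img$valid
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!ok[i, j]) next
    pd <- lu_chipman(matrix(M_img$M[i, j, , ], 4, 4))
    ret[i, j] <- pd$A_delta
    dep[i, j] <- pd$A_dep
    tdep[i, j] <- pd$T_dep
    dia[i, j] <- pd$D
    degen[i, j] <- pd$degenerate
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  list(retardance     = parameter_map(clip01(ret), ok, "A_delta"),
       depolarization = parameter_map(clip01(dep), ok, "A_dep"),
       T_dep          = parameter_map(clip01(tdep), ok, "T_dep"),
       D              = parameter_map(clip01(dia), ok, "D"),
       degenerate     = degen)
}
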