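# Shared fixture builders for the test suite.

# Uniform ground truth: one retarder/depolarizer over the whole frame.
uniform_truth <- function(H = 32, W = 32, delta = 0, theta = 0,
                          a = 1, b = 1, c = 1, brightness = 0.7) {
  m <- function(v) matrix(v, H, W)
  ground_truth(m(delta), m(theta), m(a), m(b), m(c), m(brightness),
               matrix(1L, H, W), "uniform")
}

# Noise-free snapshot reconstruction of a full Stokes scene in one mode.
reconstruct_noise_free <- function(scene_stokes,
                                   mode = c("retardance", "depolarization"),
                                   exposure_scale = 200) {
  mode <- match.arg(mode)
  mos <- simulate_dofp_mosaic(scene_stokes, mode = mode,
                              exposure_scale = exposure_scale,
                              quantize = FALSE)
  sub <- demosaic_bilinear(mos)
  if (mode == "retardance") {
    retardance_map(partial_stokes_linear(sub))
  } else {
    depolarization_map(partial_stokes_circular(sub))
  }
}

# Random physical Stokes states (uniform over the Poincare ball).
random_stokes <- function(n, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
    s0 <- stats::runif(1, 0.1, 2)
    c(s0, s0 * u)
  }, numeric(4)))
}

# Random composition M_delta(a,b,c) . M_R(delta, theta) . M_D(D)
random_composition <- function(dep_range = c(0.3, 1), dmax = 0.2) {
  abc <- stats::runif(3, dep_range[1], dep_range[2])
  delta <- stats::runif(1, 0, pi)
  theta <- stats::runif(1, 0, pi)
  Dv <- stats::rnorm(3)
  Dv <- Dv / sqrt(sum(Dv^2)) * stats::runif(1, 0, dmax)
  list(abc = abc, delta = delta, theta = theta, Dv = Dv,
       M = mueller_depolarizer(abc[1], abc[2], abc[3]) %*%
         mueller_linear_retarder(delta, theta) %*%
         mueller_diattenuator(Dv))
}
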