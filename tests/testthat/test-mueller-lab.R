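test_that("generator states follow the polarizer + waveplate construction", {
  W <- build_psg()
  # waveplate aligned with the polarizer leaves the linear state unchanged
  expect_equal(W[, 2], c(1, 1, 0, 0))
  # waveplate at -45 degrees produces a fully circular state
  expect_equal(abs(W[4, 1]), 1)
  expect_equal(sqrt(sum(W[2:4, 1]^2)), 1)
  expect_lt(instrument_model()$kappa, 20)
  expect_error(build_psg(c(0, 0, 30, 60)), "distinct")
  # four states whose waveplate angles coincide mod 90 are degenerate
  expect_error(build_psg(c(0, 90, 45, 135)), "singular")
})

test_that("analyser rows are the first rows of the analyser elements", {
  A <- build_psa()
  expect_equal(A[2, ], 0.5 * c(1, 1, 0, 0))       # 0-degree polarizer
  expect_equal(A[1, ], 0.5 * c(1, 0, -1, 0))      # -45-degree polarizer
  expect_equal(A[6, ], 0.5 * c(1, 0, 0, 1))       # right-circular analyser
  expect_equal(qr(A)$rank, 4L)
})

test_that("simulated stacks follow I = a' M w and reconstruct exactly", {
  inst <- instrument_model()
  # identity sample: I[j,k] = a_j . w_k
  st <- simulate_stack(mueller_image(diag(4)), inst)
  for (k in 1:4) for (j in 1:6) {
    expect_equal(st[1, 1, (k - 1) * 6 + j],
                 sum(inst$A[j, ] * inst$W[, k]))
  }
  # ideal depolarizer: every generator state reads the same intensities
  std <- simulate_stack(mueller_image(diag(c(1, 0, 0, 0))), inst)
  I <- matrix(std[1, 1, ], 6, 4)
  expect_equal(I, matrix(inst$A[, 1], 6, 4))

  # retarder . depolarizer sample: exact elementwise recovery
  M <- mueller_linear_retarder(0.7, 20 * pi / 180) %*%
    mueller_depolarizer(0.9, 0.8, 0.85)
  rec <- reconstruct_mueller(simulate_stack(mueller_image(M), inst), inst)
  expect_lt(max(abs(rec$M[1, 1, , ] - M)), 1e-10)
})

test_that("reconstruction error scales linearly with measurement noise", {
  inst <- instrument_model()
  M <- mueller_depolarizer(0.8, 0.7, 0.9) %*% mueller_linear_retarder(1, 0.4)
  img <- mueller_image(array(rep(M, each = 64 * 64),
                             c(64, 64, 4, 4)))
  med_err <- vapply(c(0.002, 0.02), function(sig) {
    st <- simulate_stack(img, inst, noise_sd = sig, seed = 11)
    rec <- reconstruct_mueller(st, inst)
    stats::median(abs(rec$M - img$M))
  }, numeric(1))
  expect_gt(med_err[2] / med_err[1], 6)   # ~10x noise -> ~10x error
  expect_lt(med_err[2] / med_err[1], 14)
})

test_that("Lu-Chipman decomposition reproduces the scalar definitions", {
  pd <- lu_chipman(diag(4))
  expect_equal(c(pd$T_dep, pd$A_dep, pd$R, pd$A_delta, pd$D),
               c(0, 0, 0, 0, 0))
  pd2 <- lu_chipman(diag(c(1, 0.5, 0.5, 0.5)))
  expect_equal(c(pd2$T_dep, pd2$A_dep), c(0.5, 0.5))
  pd3 <- lu_chipman(mueller_linear_retarder(pi / 2, 0.3))
  expect_equal(pd3$R, pi / 2)
  expect_equal(pd3$A_delta, 1)
  # normalization by m00
  pd4 <- lu_chipman(3 * mueller_linear_retarder(0.9, 0.1))
  expect_equal(pd4$R, 0.9)
  expect_equal(pd4$m00, 3)
})

test_that("fully depolarizing input takes the degenerate branch gracefully", {
  pd <- lu_chipman(diag(c(1, 0, 0, 0)))
  expect_true(pd$degenerate)
  expect_equal(pd$T_dep, 1)
  expect_equal(pd$A_dep, 1)
  expect_lt(max(abs(pd$M_delta %*% pd$M_R %*% pd$M_D - diag(c(1, 0, 0, 0)))),
            1e-9)
})

test_that("random compositions are recovered through the full chain", {
  inst <- instrument_model()
  set.seed(2024)
  n <- 200
  worst <- 0
  for (i in seq_len(n)) {
    comp <- random_composition()
    st <- simulate_stack(mueller_image(comp$M), inst)
    rec <- reconstruct_mueller(st, inst)
    pd <- lu_chipman(rec$M[1, 1, , ])
    err <- max(abs(pd$R - comp$delta),
               abs(pd$D - sqrt(sum(comp$Dv^2))),
               abs(pd$A_dep - (1 - comp$abc[3])),
               abs(pd$T_dep - (1 - mean(comp$abc))))
    worst <- max(worst, err)
    expect_lt(max(abs(pd$M_delta %*% pd$M_R %*% pd$M_D -
                        comp$M / comp$M[1, 1])), 1e-9)
  }
  expect_lt(worst, 1e-8)
})

test_that("decomposition maps agree with per-pixel scalars and segment regions", {
  # two-region scene: left retarder, right depolarizer
  H <- 8; W <- 8
  M <- array(0, c(H, W, 4, 4))
  Mr <- mueller_linear_retarder(0.9, 0.2)
  Md <- mueller_depolarizer(0.6, 0.6, 0.6)
  for (i in 1:H) for (j in 1:W) {
    M[i, j, , ] <- if (j <= 4) Mr else Md
  }
  maps <- decomposition_maps(mueller_image(M))
  expect_equal(maps$retardance$values[, 1:4],
               matrix(sin(0.9), H, 4))
  expect_equal(maps$retardance$values[, 5:8], matrix(0, H, 4))
  expect_equal(maps$depolarization$values[, 5:8], matrix(0.4, H, 4))
  expect_equal(maps$depolarization$values[, 1:4], matrix(0, H, 4))
  # consistency with the scalar decomposition on every pixel
  for (i in c(1, 5)) for (j in c(2, 7)) {
    pd <- lu_chipman(M[i, j, , ])
    expect_equal(maps$retardance$values[i, j], pd$A_delta)
    expect_equal(maps$T_dep$values[i, j], max(0, min(1, pd$T_dep)))
  }
  # uniform identity image: all maps zero
  maps0 <- decomposition_maps(mueller_image(array(rep(diag(4), each = 4),
                                                  c(2, 2, 4, 4))))
  expect_equal(max(abs(maps0$retardance$values)), 0)
  expect_equal(max(abs(maps0$depolarization$values)), 0)
})

test_that("a rank-deficient instrument is rejected before pixel work", {
  inst <- instrument_model()
  bad <- inst
  bad$B[, 16] <- 0
  expect_error(reconstruct_mueller(array(0, c(2, 2, 24)), bad),
               "rank deficient")
})

test_that("retardance from the snapshot path equals sin(R) from the decomposition", {
  set.seed(7)
  for (i in 1:25) {
    delta <- runif(1, 0, pi)
    theta <- runif(1, 0, pi)
    cfac <- runif(1, 0.3, 1)
    truth <- uniform_truth(8, 8, delta = delta, theta = theta, c = cfac)
    a_snapshot <- reconstruct_noise_free(scene_to_stokes(truth))$values[4, 4]
    pd <- lu_chipman(scene_to_mueller(truth)$M[4, 4, , ])
    expect_equal(a_snapshot, pd$A_delta, tolerance = 1e-6)
  }
})
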