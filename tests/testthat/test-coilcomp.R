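energy <- function(x) sum(Mod(x)^2)

test_that("SVD compression is energy-optimal", {
  fx <- fixture_frames()
  ksp <- frame_of(fx$sim, 1)
  # full basis preserves energy exactly
  Mfull <- cc_svd(ksp, 8)
  expect_equal(energy(ccapply(ksp, Mfull)), energy(ksp), tolerance = 1e-10)
  expect_error(cc_svd(ksp, 9), "exceeds")
  # rank-r data compresses to r virtual coils without loss
  set.seed(1)
  base <- matrix(rcplx(128 * 13 * 3), 128 * 13, 3)
  mix <- matrix(rcplx(3 * 8), 3, 8)
  kr <- array(base %*% mix, dim = c(128, 13, 8))
  expect_equal(energy(ccapply(kr, cc_svd(kr, 3))), energy(kr),
               tolerance = 1e-10)
  # SVD captures at least as much energy as any random projection
  M4 <- cc_svd(ksp, 4)
  e_svd <- energy(ccapply(ksp, M4))
  set.seed(2)
  worse <- vapply(1:100, function(i) {
    Q <- qr.Q(qr(matrix(rcplx(8 * 4), 8, 4)))
    energy(ccapply(ksp, Q)) <= e_svd + 1e-8
  }, logical(1))
  expect_true(all(worse))
})

test_that("ccapply is a projection with the expected algebra", {
  fx <- fixture_frames()
  ksp <- frame_of(fx$sim, 1)
  expect_equal(ccapply(ksp, diag(8) + 0i), ksp, tolerance = 1e-12)
  M4 <- cc_svd(ksp, 4)
  expect_lte(energy(ccapply(ksp, M4)), energy(ksp))
  # compress + expand reproduces the truncated-SVD approximation
  D <- matrix(ksp, 128 * 13, 8)
  sv <- svd(D)
  approx4 <- sv$u[, 1:4] %*% diag(sv$d[1:4]) %*% Conj(t(sv$v[, 1:4]))
  back <- matrix(ccapply(ksp, M4), 128 * 13, 4) %*% Conj(t(M4))
  expect_equal(back, approx4, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(ccapply(ksp, M4[1:5, ]), "coils")
})

test_that("Procrustes alignment removes unitary ambiguity causally", {
  set.seed(3)
  M1 <- qr.Q(qr(matrix(rcplx(8 * 4), 8, 4)))
  expect_equal(align_matrices(list(M1, M1))[[2]], M1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rcplx(16), 4, 4)))
  al <- align_matrices(list(M1, M1 %*% Q))
  expect_lt(max(Mod(al[[2]] - M1)), 1e-6)
  # alignment never increases the frame-to-frame Frobenius distance
  for (trial in 1:20) {
    mats <- list(M1)
    for (f in 2:6) {
      pert <- mats[[f - 1]] + 0.1 * matrix(rcplx(32), 8, 4)
      Qr <- qr.Q(qr(matrix(rcplx(16), 4, 4)))
      mats[[f]] <- qr.Q(qr(pert)) %*% Qr
    }
    before <- profile_jumps(mats)
    after <- profile_jumps(align_matrices(mats))
    expect_true(all(after <= before + 1e-8))
  }
})

test_that("alignment preserves the column space", {
  set.seed(4)
  mats <- lapply(1:4, function(i) qr.Q(qr(matrix(rcplx(8 * 4), 8, 4))))
  al <- align_matrices(mats)
  for (f in 1:4) {
    # principal angles between before/after spans are all zero
    s <- svd(Conj(t(mats[[f]])) %*% al[[f]])$d
    expect_equal(s, rep(1, 4), tolerance = 1e-10)
  }
})

test_that("compression mode contrasts match the real-time motivation", {
  fx <- cached("cc_repo", {
    params <- test_params()
    scene <- phantom_scene(params, n_coils = 8, reposition_frames = 10)
    trj <- traj_turn_based(params, 20)
    sim <- simulate_kspace(scene, trj, noise_sigma = 0.02, seed = 5)
    lapply(1:20, function(f) frame_of(sim, f))
  })
  aligned <- cc_stream(fx, 4, "dynamic-aligned")
  unaligned <- cc_stream(fx, 4, "dynamic-unaligned")
  expect_lt(mean(profile_jumps(aligned$matrices)),
            mean(profile_jumps(unaligned$matrices)))
  # on a smoothly varying series (object motion, no reposition) no aligned
  # frame jumps more than 3x the median jump
  smooth_frames <- cached("cc_smooth", {
    params <- test_params()
    scene <- phantom_scene(params, n_coils = 8, motion_amplitude = 3,
                           motion_period = 15)
    trj <- traj_turn_based(params, 15)
    sim <- simulate_kspace(scene, trj, noise_sigma = 0.02, seed = 6)
    lapply(1:15, function(f) frame_of(sim, f))
  })
  sm <- cc_stream(smooth_frames, 4, "dynamic-aligned")
  ja <- profile_jumps(sm$matrices)
  expect_true(all(ja <= 3 * stats::median(ja) + 1e-6))
  # on stationary data, static and aligned dynamic compression agree
  statq <- cc_stream(fx[1:5], 4, "static")
  alq <- cc_stream(fx[1:5], 4, "dynamic-aligned")
  dist <- mean(vapply(1:5, function(f)
    mean(Mod(statq$frames[[f]] - alq$frames[[f]])^2), numeric(1)))
  expect_lt(dist, 1e-3 * mean(vapply(statq$frames, function(f)
    mean(Mod(f)^2), numeric(1))))
})

test_that("lossless compression leaves the reconstruction unchanged", {
  # coil maps of exact rank 4: compressing 8 -> 4 costs nothing
  params <- test_params(spokes = 101, turns = 1)
  scene <- phantom_scene(params, n_coils = 8)
  set.seed(6)
  base <- scene$coil_maps[, , 1:4]
  mix <- matrix(rcplx(4 * 8), 4, 8)
  cm <- array(0 + 0i, dim = c(64, 64, 8))
  for (j in 1:8) {
    for (r in 1:4) cm[, , j] <- cm[, , j] + base[, , r] * mix[r, j]
  }
  scene$coil_maps <- cm
  trj <- traj_turn_based(params, 1)
  sim <- simulate_kspace(scene, trj, seed = 7)
  ksp <- frame_of(sim, 1)
  e_raw <- nrmse(grid_recon(ksp, trj), sim$truth[, , 1, 1])
  kc <- ccapply(ksp, cc_svd(ksp, 4))
  e_cc <- nrmse(grid_recon(kc, trj), sim$truth[, , 1, 1])
  expect_lt(abs(e_cc - e_raw), 1e-3)
})
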