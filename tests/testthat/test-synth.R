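test_that("the turn-based pattern tiles the half circle across turns", {
  params <- test_params()
  trj <- traj_turn_based(params, 10)
  ang <- lapply(1:10, function(f) traj_angles(trj, f))
  # within one frame: uniform spacing pi/13
  expect_equal(diff(sort(ang[[1]])), rep(pi / 13, 12), tolerance = 1e-10)
  # 5 turns x 13 spokes: union of 65 distinct angles at spacing pi/65
  u <- sort(unique(round(unlist(ang[1:5]), 10)))
  expect_equal(length(u), 65)
  expect_equal(diff(u), rep(pi / 65, 64), tolerance = 1e-8)
  # frames one full cycle apart repeat their angles
  expect_equal(ang[[1]], ang[[6]], tolerance = 1e-12)
  # turns = 1 has identical angles every frame
  t1 <- traj_turn_based(test_params(turns = 1), 3)
  expect_equal(traj_angles(t1, 1), traj_angles(t1, 3), tolerance = 1e-12)
})

test_that("rational golden-angle spokes have constant increment and period", {
  params <- test_params(spokes = 1)
  trj <- traj_golden_rational(params, fib_index = 7, n_frames = 16)
  raw <- vapply(1:16, function(f) {
    d <- traj_dirs(trj, f)
    atan2(d[2, 1], d[1, 1])
  }, numeric(1))
  inc <- diff(raw) %% (2 * pi)
  expect_equal(inc, rep(inc[1], 15), tolerance = 1e-10)
  expect_equal(inc[1] %% (2 * pi), (pi * 5 / 13) %% (2 * pi), tolerance = 1e-10)
  # periodic with period F = 13 (mod pi)
  expect_equal((raw[14] - raw[1]) %% pi, 0, tolerance = 1e-9)
  expect_error(traj_golden_rational(params, fib_index = 2), "fib_index")
})

test_that("frame time is spokes times TR", {
  expect_equal(frame_time(seq_params()), 27.3)
  expect_equal(frame_time(seq_params(spokes_per_frame = 1)), 2.1)
  expect_error(seq_params(spokes_per_frame = 0), "spokes_per_frame")
})

test_that("a Cartesian trajectory reproduces the plain DFT exactly", {
  N <- 16
  params <- test_params(matrix = N)
  scene <- phantom_scene(params, n_coils = 2)
  xs <- seq_len(N) - 1 - N / 2
  trj <- array(0 + 0i, dim = c(3, N, N, 1))
  for (s in seq_len(N)) {
    trj[1, , s, 1] <- xs
    trj[2, , s, 1] <- xs[s]
  }
  sim <- simulate_kspace(scene, trj, seed = 1)
  coil1 <- mdstream:::rasterize_ellipses(N, scene$ellipses) *
    scene$coil_maps[, , 1]
  ref <- fft_md(coil1, 3) * N  # unitary -> unnormalized sum
  expect_equal(sim$ksp[, , 1, 1], ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the generator is deterministic in its seed", {
  fx <- fixture_frames()
  sim2 <- simulate_kspace(fx$scene, fx$trj, seed = 3)
  expect_identical(sim2$ksp, fx$sim$ksp)
  sim3 <- simulate_kspace(fx$scene, fx$trj, noise_sigma = 0.05, seed = 4)
  sim4 <- simulate_kspace(fx$scene, fx$trj, noise_sigma = 0.05, seed = 4)
  expect_identical(sim3$ksp, sim4$ksp)
})

test_that("reposition events change the coil maps, not the phantom", {
  params <- test_params()
  scene <- phantom_scene(params, n_coils = 4, reposition_frames = 10)
  before <- mdstream:::scene_coil_maps(scene, 9)
  after <- mdstream:::scene_coil_maps(scene, 10)
  expect_gt(max(Mod(before - after)), 0.1)
  expect_equal(mdstream:::rasterize_ellipses(64, scene$ellipses),
               mdstream:::rasterize_ellipses(64, scene$ellipses))
})

test_that("sampling and gridding adjoint form an adjoint pair", {
  # <F x, y> = <x, F^H y> for the exact-DFT sampling operator
  N <- 16
  params <- test_params(matrix = N, spokes = 5, turns = 1)
  trj <- traj_turn_based(params, 1)
  co <- traj_coords(trj)
  set.seed(2)
  x <- matrix(rcplx(N * N), N * N, 1)
  y <- rcplx(length(co$kx))
  Fx <- mdstream:::radial_dft_forward(x, co$kx, co$ky, N)
  Fhy <- mdstream:::radial_dft_adjoint(y, co$kx, co$ky, N)
  lhs <- sum(Conj(as.vector(Fx)) * y)
  rhs <- sum(Conj(as.vector(x)) * as.vector(Fhy))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})

test_that("view sharing a static phantom equals reconstructing the union", {
  fx <- fixture_frames()
  # union of the 5 turns
  uk <- do.call(mdstream:::abind2, lapply(1:5, function(f) frame_of(fx$sim, f)))
  ut <- do.call(mdstream:::abind2_trj, lapply(1:5, function(f) trj_of(fx$sim, f)))
  e_union <- grid_recon(uk, ut)
  cfg <- pipeline_config(recon = "grid", view_sharing = TRUE)
  out <- run_pipeline(build_pipeline(cfg, grid = 64, turns = 5),
                      fx$sim$ksp, fx$sim$trj)
  expect_equal(out$images[, , 1, 5], e_union, tolerance = 1e-8)
})
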