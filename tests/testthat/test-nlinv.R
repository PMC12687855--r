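disk_fixture <- function() cached("nlinv_disk", {
  params <- test_params(spokes = 101, turns = 1)
  scene <- phantom_scene(params, n_coils = 1,
    ellipses = list(list(cx = 0, cy = 0, ax = 18, ay = 18, angle = 0,
                         intensity = 1)))
  scene$coil_maps <- array(1 + 0i, dim = c(64, 64, 1))
  trj <- traj_turn_based(params, 1)
  sim <- simulate_kspace(scene, trj, seed = 1)
  list(trj = trj, sim = sim, ksp = frame_of(sim, 1))
})

test_that("a fully sampled single-coil phantom is recovered accurately", {
  fx <- disk_fixture()
  res <- nlinv_frame(fx$ksp, fx$trj, grid = 64)
  expect_lt(nrmse(Mod(res$image), fx$sim$truth[, , 1, 1]), 0.05)
})

test_that("zero data reconstructs to a zero image", {
  fx <- disk_fixture()
  res <- nlinv_frame(fx$ksp * 0, fx$trj, grid = 64)
  expect_lt(max(Mod(res$image)), 1e-8)
})

test_that("the reconstruction scales linearly with the data", {
  fx <- disk_fixture()
  r1 <- nlinv_frame(fx$ksp, fx$trj, grid = 64)
  r2 <- nlinv_frame(fx$ksp * 3.7, fx$trj, grid = 64)
  expect_equal(Mod(r2$image), 3.7 * Mod(r1$image), tolerance = 0.01)
})

test_that("more Gauss-Newton iterations do not hurt on noiseless data", {
  fx <- disk_fixture()
  e6 <- nrmse(Mod(nlinv_frame(fx$ksp, fx$trj, 64,
                              nlinv_config(iterations = 6))$image),
              fx$sim$truth[, , 1, 1])
  e8 <- nrmse(Mod(nlinv_frame(fx$ksp, fx$trj, 64,
                              nlinv_config(iterations = 8))$image),
              fx$sim$truth[, , 1, 1])
  expect_lte(e8, e6 + 1e-3)
})

test_that("the Gauss-Newton residual decreases over the iterations", {
  # monotone surrogate residual; divergence would raise an error instead
  fx <- disk_fixture()
  expect_no_error(nlinv_frame(fx$ksp, fx$trj, grid = 64,
                              nlinv_config(iterations = 10)))
})

stream_fixture <- function() cached("nlinv_stream", {
  params <- test_params()
  scene <- phantom_scene(params, n_coils = 4)
  trj <- traj_turn_based(params, 6)
  sim <- simulate_kspace(scene, trj, seed = 9)
  list(trj = trj, sim = sim)
})

test_that("warm-started streaming converges over the first frames", {
  fx <- stream_fixture()
  imgs <- nlinv_stream(fx$sim$ksp, fx$trj, grid = 64)
  d <- vapply(2:5, function(f)
    sqrt(mean(Mod(imgs[, , 1, f] - imgs[, , 1, f - 1])^2)), numeric(1))
  # frame-to-frame change decreases as the state warms up
  expect_lt(d[4], d[1])
  expect_lt(nrmse(Mod(imgs[, , 1, 6]), fx$sim$truth[, , 1, 6]), 0.1)
})

test_that("temporal damping zero decouples the frames", {
  fx <- stream_fixture()
  cfg <- nlinv_config(temporal_damping = 0, iterations = 4)
  imgs <- nlinv_stream(fx$sim$ksp[, , , 1:2, drop = FALSE], fx$trj, 64, cfg)
  solo <- nlinv_frame(frame_of(fx$sim, 2), fx$trj, 64, cfg, frame = 2)
  expect_equal(imgs[, , 1, 2], solo$image, tolerance = 1e-12)
})

test_that("the stream is causal: truncation leaves earlier frames bitwise", {
  fx <- stream_fixture()
  full <- nlinv_stream(fx$sim$ksp[, , , 1:4, drop = FALSE], fx$trj, 64)
  cut <- nlinv_stream(fx$sim$ksp[, , , 1:2, drop = FALSE], fx$trj, 64)
  expect_identical(full[, , , 1:2], cut[, , , 1:2])
})

test_that("a moving object is tracked with at most one frame of lag", {
  fx <- cached("nlinv_moving", {
    params <- test_params()
    scene <- phantom_scene(params, n_coils = 4, motion_amplitude = 4,
                           motion_period = 8)
    trj <- traj_turn_based(params, 8)
    sim <- simulate_kspace(scene, trj, seed = 13)
    list(scene = scene, trj = trj, sim = sim)
  })
  imgs <- nlinv_stream(fx$sim$ksp, fx$trj, grid = 64)
  centroid <- function(img) {
    w <- img^2
    xs <- seq_len(64) - 1 - 32
    sum(outer(xs, rep(1, 64)) * w) / sum(w)
  }
  cx_rec <- vapply(3:8, function(f) centroid(Mod(imgs[, , 1, f])), numeric(1))
  cx_true <- vapply(3:8, function(f)
    centroid(fx$sim$truth[, , 1, f]), numeric(1))
  cx_prev <- vapply(2:7, function(f)
    centroid(fx$sim$truth[, , 1, f]), numeric(1))
  err_now <- mean(abs(cx_rec - cx_true))
  err_lag2 <- mean(abs(cx_rec - cx_prev))
  # the track follows the truth to within the inter-frame displacement
  expect_lt(err_now, max(abs(diff(cx_true))) + 0.5)
  expect_lt(err_now, err_lag2 + 0.5)
})
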