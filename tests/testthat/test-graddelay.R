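est_entries <- function(S) c(S$s_xx, S$s_yy, S$s_xy)

test_that("the delay estimator recovers injected symmetric matrices", {
  fx <- fixture_frames()
  cases <- list(NULL,
                delay_matrix(0.5, 0.5, 0),
                delay_matrix(0.8, 0.3, 0.1))
  want <- list(c(0, 0, 0), c(0.5, 0.5, 0), c(0.8, 0.3, 0.1))
  for (i in seq_along(cases)) {
    sim <- simulate_kspace(fx$scene, fx$trj, delay = cases[[i]], seed = 3)
    Sh <- estimate_delay(frame_of(sim, 1), fx$trj)
    tol <- if (i == 1) 0.05 else 0.1
    expect_true(all(abs(est_entries(Sh) - want[[i]]) < tol),
                label = paste("case", i, ":",
                              paste(round(est_entries(Sh), 3), collapse = " ")))
  }
})

test_that("fewer than 3 distinct spoke angles is a rank error", {
  params <- test_params(spokes = 2, turns = 1)
  trj <- traj_turn_based(params, 1)
  ksp <- rand_md(c(128, 2, 4), seed = 1)
  expect_error(estimate_delay(ksp, trj), "rank deficiency")
})

test_that("estimation is equivariant under in-plane rotation", {
  fx <- fixture_frames()
  Sin <- delay_matrix(0.6, 0.2, 0.15)
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # rotate the trajectory; the apparatus delay S is fixed in the lab frame
  trj_rot <- fx$trj
  trj_rot[1, , , ] <- cos(th) * fx$trj[1, , , ] - sin(th) * fx$trj[2, , , ]
  trj_rot[2, , , ] <- sin(th) * fx$trj[1, , , ] + cos(th) * fx$trj[2, , , ]
  sim <- simulate_kspace(fx$scene, trj_rot, delay = Sin, seed = 3)
  Sh <- estimate_delay(frame_of(sim, 1), trj_rot)
  expect_lt(max(abs(as.matrix(Sh) - as.matrix(Sin))), 0.1)
})

test_that("estimator error shrinks as the matrix grows", {
  Sin <- delay_matrix(0.4, 0.25, 0.1)
  errs <- vapply(c(64, 128), function(N) {
    params <- test_params(matrix = N)
    scene <- phantom_scene(params, n_coils = 8)
    trj <- traj_turn_based(params, 1)
    sim <- simulate_kspace(scene, trj, delay = Sin, seed = 3)
    Sh <- estimate_delay(frame_of(sim, 1), trj)
    max(abs(est_entries(Sh) - c(0.4, 0.25, 0.1)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("trajectory correction closes the loop on reconstruction quality", {
  fx <- fixture_frames()
  expect_equal(correct_trajectory(fx$trj, delay_matrix(0, 0, 0)), fx$trj)
  Sin <- delay_matrix(0.5, 0.5, 0)
  sim0 <- fx$sim
  simd <- simulate_kspace(fx$scene, fx$trj, delay = Sin, seed = 3)
  truth <- sim0$truth[, , 1, 1]
  t1 <- trj_of(sim0, 1)
  Sh <- estimate_delay(frame_of(simd, 1), t1)
  e_free <- nrmse(grid_recon(frame_of(sim0, 1), t1), truth)
  e_corr <- nrmse(grid_recon(frame_of(simd, 1), correct_trajectory(t1, Sh)),
                  truth)
  e_stale <- nrmse(grid_recon(frame_of(simd, 1),
                              correct_trajectory(t1, delay_matrix(-0.3, 0.2, 0.4))),
                   truth)
  expect_lt(e_corr / e_free, 1.1)
  expect_lt(e_corr, e_stale)
})

test_that("the ellipse decomposition reflects strength and orientation", {
  e1 <- delay_ellipse(delay_matrix(1, 1, 0))
  expect_equal(e1$axis_lengths, c(1, 1))
  e2 <- delay_ellipse(delay_matrix(2, 1, 0))
  expect_equal(e2$axis_lengths, c(2, 1))
  expect_equal(e2$orientation, 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M <- R %*% diag(c(2, 1)) %*% t(R)
  er <- delay_ellipse(delay_matrix(M[1, 1], M[2, 2], M[1, 2]))
  expect_equal(er$axis_lengths, c(2, 1), tolerance = 1e-10)
  expect_equal(er$orientation %% pi, th %% pi, tolerance = 1e-10)
})

test_that("exponential smoothing stabilizes a streamed delay estimate", {
  fx <- fixture_frames()
  Sin <- delay_matrix(0.4, 0.4, 0)
  sim <- simulate_kspace(fx$scene, fx$trj, delay = Sin, seed = 3)
  frames <- lapply(1:3, function(f) frame_of(sim, f))
  ests <- estimate_delay_stream(frames, fx$trj, decay = 0.5)
  expect_equal(length(ests), 3)
  expect_lt(max(abs(est_entries(ests[[3]]) - c(0.4, 0.4, 0))), 0.1)
  # decay 0 reproduces per-frame estimation
  e0 <- estimate_delay_stream(frames, fx$trj, decay = 0)
  expect_equal(est_entries(e0[[2]]),
               est_entries(estimate_delay(frames[[2]], fx$trj, frame = 2)))
})
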