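# Shared fixtures, built in code at test time.

rcplx <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}

rand_md <- function(dims, seed = 1) {
  set.seed(seed)
  array(rcplx(prod(dims)), dim = dims)
}

# test-scale sequence: matrix 64, 2x readout oversampling, 13 spokes/frame
test_params <- function(matrix = 64, spokes = 13, turns = 5) {
  seq_params(matrix = matrix, adc_samples = 2 * matrix,
             spokes_per_frame = spokes, turns = turns)
}

# memoised standard simulations (shared across tests within a file run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# fully sampled single frame, 8 coils
fixture_full <- function() cached("full", {
  params <- test_params(spokes = 101, turns = 1)
  scene <- phantom_scene(params, n_coils = 8)
  trj <- traj_turn_based(params, 1)
  sim <- simulate_kspace(scene, trj, seed = 3)
  list(params = params, scene = scene, trj = trj, sim = sim,
       ksp = array(sim$ksp[, , , 1], dim = dim(sim$ksp)[1:3]))
})

# 13-spoke frames, 8 coils, noiseless
fixture_frames <- function() cached("frames", {
  params <- test_params()
  scene <- phantom_scene(params, n_coils = 8)
  trj <- traj_turn_based(params, 5)
  sim <- simulate_kspace(scene, trj, seed = 3)
  list(params = params, scene = scene, trj = trj, sim = sim)
})

frame_of <- function(sim, f) array(sim$ksp[, , , f], dim = dim(sim$ksp)[1:3])
trj_of <- function(sim, f) array(sim$trj[, , , f], dim = dim(sim$trj)[1:3])

grid_recon <- function(ksp, trj, N = 64) {
  w <- ramlak_filter(ksp, trj)
  Mod(resize_center(rss_combine(nufft_adjoint(w, trj * 2, 2 * N), 2),
                    c(N, N))[, , 1])
}
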