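test_that("the centered FFT matches a brute-force DFT and is unitary", {
  N <- 8
  x <- rand_md(c(N, N), seed = 1)
  xs <- seq_len(N) - 1 - N / 2
  W <- outer(xs, xs, function(k, p) exp(-2i * pi * k * p / N)) / sqrt(N)
  expect_lt(max(Mod(fft_md(x, 3) - W %*% x %*% t(W))), 1e-12)
  expect_lt(max(Mod(fft_md(fft_md(x, 3), 3, inverse = TRUE) - x)), 1e-12)
  # impulse at the centered origin transforms to a constant
  d <- array(0 + 0i, dim = c(N, N)); d[N / 2 + 1, N / 2 + 1] <- 1
  expect_lt(stats::sd(Re(fft_md(d, 3))), 1e-12)
  expect_error(fft_md(x, 0), "empty")
})

test_that("Ram-Lak weights ramp linearly with radius and ignore direction", {
  fx <- fixture_full()
  ksp1 <- array(1 + 0i, dim = dim(fx$ksp))
  w <- ramlak_filter(ksp1, fx$trj)
  co <- traj_coords(fx$trj)
  r <- sqrt(co$kx^2 + co$ky^2)
  # linearity: weight ratio 2 between radius r and 2r samples
  i1 <- which(abs(r - 8) < 1e-9)[1]
  i2 <- which(abs(r - 16) < 1e-9)[1]
  expect_equal(Re(w[, , 1][i2]) / Re(w[, , 1][i1]), 2, tolerance = 1e-12)
  # symmetric under spoke reversal (depends on |k| only)
  expect_equal(Re(w[1, 1, 1]), Re(w[1, 2, 1]), tolerance = 1e-12)
  expect_error(ramlak_filter(array(1 + 0i, c(10, 3, 1)), fx$trj),
               "shape mismatch")
})

test_that("gridding matches the exact adjoint on arbitrary radial data", {
  set.seed(2)
  params <- test_params(matrix = 32, spokes = 8, turns = 1)
  trj <- traj_turn_based(params, 1)
  co <- traj_coords(trj)
  dat <- rcplx(length(co$kx))
  g <- nufft_adjoint(array(dat, dim = c(64, 8, 1)), trj, 32)
  xs <- seq_len(32) - 1 - 16
  direct <- matrix(0 + 0i, 32, 32)
  for (m in seq_along(dat))
    direct <- direct + dat[m] * exp(2i * pi *
      (co$kx[m] * outer(xs, rep(1, 32)) + co$ky[m] * outer(rep(1, 32), xs)) / 32)
  expect_lt(sqrt(sum(Mod(g[, , 1] - direct)^2) / sum(Mod(direct)^2)), 1e-2)
  # zero data gives a zero image
  expect_equal(max(Mod(nufft_adjoint(array(0i, c(64, 8, 1)), trj, 32))), 0)
  # out-of-band samples are rejected
  expect_error(nufft_adjoint(array(dat, c(64, 8, 1)), trj * 3, 32),
               "outside the band")
})

test_that("gridding a Cartesian trajectory reduces to a centered inverse FFT", {
  N <- 16
  set.seed(3)
  img_k <- rand_md(c(N, N), seed = 3)
  xs <- seq_len(N) - 1 - N / 2
  trj <- array(0 + 0i, dim = c(3, N, N))
  for (s in seq_len(N)) {
    trj[1, , s] <- xs
    trj[2, , s] <- xs[s]
  }
  g <- nufft_adjoint(array(img_k, dim = c(N, N, 1)), trj, N)[, , 1]
  ref <- fft_md(img_k, 3, inverse = TRUE)
  scale <- g[N / 2 + 1, N / 2 + 1] / ref[N / 2 + 1, N / 2 + 1]
  expect_equal(g / scale, ref, tolerance = 1e-2)
})

test_that("Ram-Lak + adjoint NUFFT reconstructs a fully sampled phantom", {
  fx <- fixture_full()
  img <- grid_recon(fx$ksp, fx$trj)
  expect_lt(nrmse(img, fx$sim$truth[, , 1, 1]), 0.1)
})

test_that("root sum-of-squares combines coils as expected", {
  x <- rand_md(c(6, 6, 1), seed = 4)
  expect_equal(Re(rss_combine(x, 2)), Mod(x), tolerance = 1e-12)
  two <- array(c(x, x), dim = c(6, 6, 2))
  expect_equal(as.vector(Re(rss_combine(two, 2))),
               as.vector(sqrt(2) * Mod(x)), tolerance = 1e-12)
  perm <- rand_md(c(4, 4, 3), seed = 5)
  expect_equal(rss_combine(perm, 2), rss_combine(perm[, , c(3, 1, 2)], 2),
               tolerance = 1e-12)
})

test_that("centered resize crops, pads and round-trips", {
  x <- rand_md(c(8, 8), seed = 6)
  p <- resize_center(x, c(12, 12))
  expect_identical(resize_center(p, c(8, 8)), x)
  cr <- resize_center(x, c(4, 4))
  expect_identical(cr, x[3:6, 3:6])
  expect_lte(sum(Mod(cr)^2), sum(Mod(x)^2))
  # 384 -> 192 keeps the central 192 samples
  v <- array(seq_len(384) + 0i, dim = 384)
  expect_equal(Re(resize_center(v, 192)[1]), 97)
})

test_that("the causal temporal median filter behaves as specified", {
  nf <- 12
  x <- array(1 + 0i, dim = c(3, 3, 1, nf))
  expect_equal(median_filter_temporal(x, 5), x)  # constant series unchanged
  # single-frame impulse is rejected in steady state
  xi <- x; xi[, , 1, 6] <- 10
  out <- median_filter_temporal(xi, 5)
  expect_equal(Re(out[1, 1, 1, 8:12]), rep(1, 5))
  # a step appears floor(L/2) frames late
  xs <- x; xs[, , 1, 7:nf] <- 5
  outs <- Re(median_filter_temporal(xs, 5)[1, 1, 1, ])
  expect_equal(which(outs == 5)[1], 7 + 2)
  expect_error(median_filter_temporal(x, 4), "odd")
})

test_that("non-local means denoises without touching clean structure", {
  expect_equal(nlm_filter(matrix(3, 16, 16)), matrix(3, 16, 16))
  set.seed(7)
  noisy <- matrix(5 + stats::rnorm(48 * 48, sd = 0.5), 48, 48)
  vr <- vapply(1:5, function(i) {
    set.seed(i)
    n2 <- matrix(5 + stats::rnorm(48 * 48, sd = 0.5), 48, 48)
    stats::var(as.vector(nlm_filter(n2))) < stats::var(as.vector(n2))
  }, logical(1))
  expect_true(all(vr))
  smooth <- outer(1:24, 1:24, `+`) / 10
  expect_lt(max(abs(nlm_filter(smooth, h = 1e-9) - smooth)), 1e-8)
})
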