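test_that("bi-tensor forward model matches independent scalar evaluation", {
  sc <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  p <- bitensor_params(0.5, diag(0.7e-3, 3), d_iso = 3.0e-3, s0 = 1)
  s <- bitensor_signal(p, sc)
  expect_equal(s[1], 1)                                   # b = 0 returns S0
  expect_equal(s[2], 0.5 * exp(-0.7) + 0.5 * exp(-3), tolerance = 1e-12)

  # pure free water is direction independent
  sc3 <- fx_scheme3(15L)
  pfw <- bitensor_params(1, diag(0.7e-3, 3), s0 = 2)
  sfw <- bitensor_signal(pfw, sc3)
  expect_equal(sfw[-sc3$b0_indices],
               2 * exp(-sc3$bvals[-sc3$b0_indices] * 3.0e-3), tolerance = 1e-12)

  expect_error(bitensor_params(0.5, diag(c(1, 1, -1) * 1e-3)), "positive semi-definite")
  expect_error(bitensor_params(1.2, diag(1e-3, 3)), "\\[0, 1\\]")
})

test_that("Rician noise has the right distribution and is reproducible", {
  x <- rep(0, 1e5)
  n <- add_rician_noise(x, snr = 20, s0 = 1, seed = 5)
  expect_equal(mean(n), (1 / 20) * sqrt(pi / 2), tolerance = 0.01)  # Rayleigh mean
  n2 <- add_rician_noise(x, snr = 20, s0 = 1, seed = 5)
  expect_identical(n, n2)
  # effectively infinite SNR leaves the signal unchanged
  s <- runif(100, 0.5, 1)
  expect_equal(add_rician_noise(s, snr = 1e12, seed = 1), s, tolerance = 1e-9)
  expect_error(add_rician_noise(s, snr = -1), "positive")
})

test_that("noiseless phantom signals equal the forward model of their truth", {
  ph <- fx_phantom_noiseless()
  V <- prod(dim(ph$signal)[1:3])
  sig <- matrix(ph$signal, V, dim(ph$signal)[4])
  for (v in c(1L, 57L, 200L)) {
    p <- bitensor_params(ph$truth_f[v], d6_to_mat(ph$truth_d6[v, ]),
                         d_iso = ph$d_iso, s0 = ph$s0)
    expect_equal(sig[v, ], bitensor_signal(p, ph$scheme), tolerance = 1e-12)
  }
  # b0 equals S0 exactly
  expect_equal(max(abs(sig[, ph$scheme$b0_indices] - ph$s0)), 0)
})

test_that("phantom geometry and determinism contracts hold", {
  ph <- generate_phantom(shape = c(5, 5, 5), dirs_per_shell = 30, n_b0 = 3,
                         shells = c(1000, 2000, 3000), seed = 77)
  expect_equal(dim(ph$signal)[4], 3 + 3 * 30)
  ph2 <- generate_phantom(shape = c(5, 5, 5), dirs_per_shell = 30, n_b0 = 3,
                          shells = c(1000, 2000, 3000), seed = 77)
  expect_identical(ph$signal, ph2$signal)
  expect_true(all(ph$truth_f >= 0 & ph$truth_f <= 1))
  expect_error(generate_phantom(dirs_per_shell = 4), ">= 6")
})

test_that("repulsion direction sets are well spread", {
  set.seed(21)
  d <- repulsion_directions(90)
  g <- abs(d %*% t(d)); diag(g) <- 0
  min_angle <- acos(min(1, max(g))) * 180 / pi
  expect_gt(min_angle, 5)
})

test_that("directional mean signal increases with f when free water decays slower", {
  sc <- fx_scheme3(45L)
  idx1000 <- sc$shells[["1000"]]
  set.seed(31)
  for (i in 1:5) {
    D <- fwsphere:::tensor_from_md_fa(runif(1, 0.6e-3, 0.9e-3),
                                      runif(1, 0.2, 0.9), rnorm(3))
    means <- vapply(seq(0, 1, by = 0.1), function(f) {
      mean(bitensor_signal(bitensor_params(f, D), sc)[idx1000])
    }, numeric(1))
    g <- sc$bvecs[idx1000, ]
    tissue_mean <- mean(exp(-1000 * rowSums((g %*% D) * g)))
    if (exp(-1000 * 3.0e-3) > tissue_mean) {
      expect_true(all(diff(means) > 0))
    } else {
      expect_true(all(diff(means) < 0))
    }
  }
})
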