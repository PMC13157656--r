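test_that("SH fits are exact for band-limited signals", {
  set.seed(51)
  dirs <- repulsion_directions(90)
  # constant signal is pure degree 0
  c0 <- 0.37
  cf <- sh_fit(rep(c0, 90), dirs, max_degree = 8)
  B <- sh_basis(dirs, 8)
  expect_lt(max(abs(drop(B %*% cf) - c0)), 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)

  # synthesized degree-4 signal: coefficients recovered exactly
  B4 <- sh_basis(dirs, 4)
  truth <- rnorm(ncol(B4))
  y <- drop(B4 %*% truth)
  rec <- sh_fit(y, dirs, max_degree = 4)
  expect_lt(max(abs(rec - truth)), 1e-8)

  # antipodal symmetry of the basis
  expect_lt(max(abs(sh_basis(dirs, 8) - sh_basis(-dirs, 8))), 1e-12)

  # degenerate set refused
  expect_error(sh_fit(rep(1, 10), matrix(rep(c(1, 0, 0), 10), ncol = 3,
                                         byrow = TRUE), 4), "degenerate")
})

test_that("rotation acts on SH fits without changing per-degree power", {
  set.seed(52)
  dirs <- repulsion_directions(90)
  B4 <- sh_basis(dirs, 4)
  truth <- rnorm(ncol(B4))
  R <- rotation_matrix(0.9, -0.5, 0.3)
  # rotated signal sampled at rotated directions has identical coefficients;
  # sampled at the ORIGINAL directions it has Wigner-rotated coefficients,
  # whose per-degree power is invariant
  y <- drop(B4 %*% truth)
  rec_rot <- sh_fit(y, dirs %*% t(R), max_degree = 4)
  l <- attr(sh_basis(dirs, 4), "l")
  for (dg in c(0, 2, 4)) {
    expect_equal(sum(rec_rot[l == dg]^2), sum(truth[l == dg]^2),
                 tolerance = 1e-10)
  }
})

test_that("feature blocks honor the shell code and dropout consistency", {
  ph <- fx_phantom_noiseless()
  V <- prod(dim(ph$signal)[1:3])
  sig <- matrix(ph$signal, V, dim(ph$signal)[4])
  ns <- normalize_signal(sig, ph$scheme)
  fs <- build_feature_set(ns$normalized, ph$scheme)
  expect_equal(dim(fs$coeffs), c(V, 45L, 3L))

  # zeroing absent shells never changes present blocks
  fz <- apply_shell_code(fs, shell_code(c(1, 0, 0)))
  expect_identical(fz$coeffs[, , 1], fs$coeffs[, , 1])
  expect_true(all(fz$coeffs[, , 2:3] == 0))

  # features from genuinely single-shell data match the zeroed full set
  keep <- sort(c(ph$scheme$b0_indices, ph$scheme$shells[["1000"]]))
  sc1 <- gradient_scheme(ph$scheme$bvals[keep], ph$scheme$bvecs[keep, ])
  ns1 <- normalize_signal(sig[, keep], sc1)
  f1 <- build_feature_set(ns1$normalized, sc1, code = shell_code(c(1, 0, 0)))
  expect_lt(max(abs(f1$coeffs - fz$coeffs)), 1e-8)

  expect_error(build_feature_set(ns1$normalized, sc1,
                                 code = shell_code(c(1, 1, 0))),
               "configuration error")
})

test_that("SHORE basis has 50 coefficients and reconstructs smooth signals", {
  sc <- fx_scheme3(45L)
  siso <- exp(-sc$bvals * 0.9e-3)
  sf <- shore_fit(siso, sc, md = 0.9e-3)
  expect_length(sf$coeffs, 50L)
  rec <- shore_reconstruct(sf, sc)
  expect_lt(max(abs(rec - siso)), 0.01)           # < 1% of S0 = 1

  # zeta formula: doubling tau halves zeta; value matches the definition
  sf2 <- shore_fit(siso, sc, tau = 2 * sf$tau, md = 0.9e-3)
  expect_equal(sf2$zeta, sf$zeta / 2)
  expect_equal(sf$zeta, 1 / (8 * pi^2 * sf$tau * 0.9e-3))

  expect_warning(shore_fit(siso, sc, md = -1), "falling back")
})

test_that("per-voxel SHORE field fits reconstruct anisotropic voxels", {
  ph <- fx_phantom_noiseless()
  sig <- matrix(ph$signal, prod(dim(ph$signal)[1:3]), dim(ph$signal)[4])[1:10, ]
  ns <- normalize_signal(sig, ph$scheme)
  sf <- shore_fit_field(ns$normalized, ph$scheme)
  expect_equal(dim(sf$coeffs), c(10L, 50L))
  v <- 3
  feats <- structure(list(coeffs = sf$coeffs[v, ], zeta = sf$zeta[v],
                          tau = sf$tau, radial_order = 6L),
                     class = "shore_features")
  rec <- shore_reconstruct(feats, ph$scheme)
  expect_lt(max(abs(rec - ns$normalized[v, ])), 0.05)
})
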