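test_that("DTI fit recovers isotropic and anisotropic tensors exactly", {
  sc <- fx_scheme3(30L)
  iso <- bitensor_signal(bitensor_params(0, diag(0.7e-3, 3), s0 = 100), sc)
  m <- fit_dti(iso, sc)
  expect_lt(m$fa, 1e-8)
  expect_equal(m$md, 0.7e-3, tolerance = 1e-10 / 0.7e-3)

  D <- diag(c(1.7, 0.2, 0.2) * 1e-3)
  s <- bitensor_signal(bitensor_params(0, D, s0 = 50), sc)
  m2 <- fit_dti(s, sc)
  # closed-form eigenvalue metrics evaluated independently
  lam <- c(1.7, 0.2, 0.2) * 1e-3
  md_ref <- mean(lam)
  fa_ref <- sqrt(1.5 * sum((lam - md_ref)^2) / sum(lam^2))
  expect_equal(m2$md, md_ref, tolerance = 1e-8)
  expect_equal(m2$fa, fa_ref, tolerance = 1e-8)
  expect_equal(m2$tensor, D, tolerance = 1e-6)

  # no decay: tensor ~ 0
  flat <- rep(10, length(sc$bvals))
  m3 <- fit_dti(flat, sc)
  expect_lt(abs(m3$md), 1e-12)
})

test_that("DTI fit validates its design requirements", {
  sc <- fx_scheme3(30L)
  expect_error(fit_dti(rep(1, 5), sc), "mismatch")
  # coplanar directions give a rank-deficient design
  n <- 10
  ang <- seq(0, pi, length.out = n + 1)[-1]
  dirs <- cbind(cos(ang), sin(ang), 0)
  scp <- gradient_scheme(c(0, rep(1000, n)), rbind(c(0, 0, 0), dirs))
  expect_error(fit_dti(rep(1, n + 1), scp), "rank-deficient")
})

test_that("FA/MD agree with spectral formulas on noiseless fields", {
  ph <- fx_phantom_noiseless()
  V <- prod(dim(ph$signal)[1:3])
  sig <- matrix(ph$signal, V, dim(ph$signal)[4])
  # pure-tissue voxels only (f = 0 surrogate: rebuild signals without free water)
  sig0 <- fwsphere:::bitensor_signal_field(rep(0, V), ph$truth_d6, ph$s0,
                                           ph$scheme, ph$d_iso)
  fit <- fit_dti_field(sig0[1:64, ], ph$scheme)
  ref <- t(apply(ph$truth_d6[1:64, ], 1, function(d) {
    ev <- eigen(d6_to_mat(d), symmetric = TRUE, only.values = TRUE)$values
    md <- mean(ev)
    c(sqrt(1.5 * sum((ev - md)^2) / sum(ev^2)), md)
  }))
  expect_lt(max(abs(fit$fa - ref[, 1])), 1e-8)
  expect_lt(max(abs(fit$md - ref[, 2])), 1e-11)
})

test_that("multi-shell free-water fit recovers the true fraction", {
  ph <- fx_phantom_noiseless()
  V <- prod(dim(ph$signal)[1:3])
  sig <- matrix(ph$signal, V, dim(ph$signal)[4])
  # two-shell subset (1000, 2000) is already well posed
  keep <- sort(c(ph$scheme$b0_indices, ph$scheme$shells[["1000"]],
                 ph$scheme$shells[["2000"]]))
  sc2 <- gradient_scheme(ph$scheme$bvals[keep], ph$scheme$bvecs[keep, ])
  sub <- which(abs(ph$truth_f - 0.30) < 0.15)[1:25]
  fw <- fit_fwdti(sig[sub, keep], sc2)
  expect_lt(max(abs(fw$f - ph$truth_f[sub])), 1e-3)

  # f = 0 voxel: tissue tensor recovered to high relative accuracy
  sig0 <- fwsphere:::bitensor_signal_field(rep(0, 4), ph$truth_d6[1:4, ],
                                           ph$s0, ph$scheme, ph$d_iso)
  fw0 <- fit_fwdti(sig0, ph$scheme)
  expect_lt(max(fw0$f), 0.01)
  expect_lt(max(abs(fw0$tissue_d6 - ph$truth_d6[1:4, ])) /
              max(abs(ph$truth_d6[1:4, ])), 1e-6)

  # pure free water is thresholded to f = 1 with zeroed tissue tensor
  sigfw <- fwsphere:::bitensor_signal_field(rep(1, 2), ph$truth_d6[1:2, ],
                                            ph$s0, ph$scheme, ph$d_iso)
  fw1 <- fit_fwdti(sigfw, ph$scheme)
  expect_equal(fw1$f, c(1, 1))
  expect_equal(unname(fw1$exit_flags), c(2L, 2L))
  expect_true(all(fw1$tissue_d6 == 0))
})

test_that("single-shell input is refused as ill-posed", {
  sc <- fx_scheme3(30L)
  keep <- sort(c(sc$b0_indices, sc$shells[["1000"]]))
  sc1 <- gradient_scheme(sc$bvals[keep], sc$bvecs[keep, ])
  expect_error(fit_fwdti(matrix(1, 2, length(keep)), sc1), "ill-posed")
})

test_that("MD threshold marks pure free water and is a no-op at infinity", {
  ph <- fx_phantom_noiseless()
  sig <- matrix(ph$signal, prod(dim(ph$signal)[1:3]), dim(ph$signal)[4])[1:8, ]
  fw <- fit_fwdti(sig, ph$scheme)
  md <- c(2.8e-3, 2.6e-3, rep(1e-3, 6))
  out <- apply_md_threshold(fw, md = md, threshold = 2.7e-3)
  expect_equal(out$f[1], 1)
  expect_true(all(out$tissue_d6[1, ] == 0))
  expect_equal(out$exit_flags[1], 2L)
  expect_equal(out$f[-1], fw$f[-1])
  out2 <- apply_md_threshold(fw, md = md, threshold = Inf)
  expect_equal(out2$f, fw$f)
  expect_error(apply_md_threshold(fw, md = md, threshold = -1), "positive")
})

test_that("free-water fit is invariant under joint rotation", {
  ph <- fx_phantom_noiseless()
  n <- 12
  sig <- matrix(ph$signal, prod(dim(ph$signal)[1:3]), dim(ph$signal)[4])[1:n, ]
  fw <- fit_fwdti(sig, ph$scheme)
  R <- rotation_matrix(0.7, 0.4, 1.1)
  scr <- ph$scheme; scr$bvecs <- ph$scheme$bvecs %*% t(R)
  d6r <- t(apply(ph$truth_d6[1:n, ], 1, function(d) {
    mat_to_d6(R %*% d6_to_mat(d) %*% t(R))
  }))
  sigr <- fwsphere:::bitensor_signal_field(ph$truth_f[1:n], d6r, ph$s0,
                                           scr, ph$d_iso)
  expect_lt(max(abs(sigr - sig)), 1e-10)   # same signal by construction
  fwr <- fit_fwdti(sigr, scr)
  expect_lt(max(abs(fwr$f - fw$f)), 1e-6)
})
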