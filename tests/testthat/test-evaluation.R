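test_that("fraction RMSE has its defining properties", {
  set.seed(71)
  a <- array(runif(1000), c(10, 10, 10))
  expect_equal(rmse_fraction(a, a), 0)
  expect_equal(rmse_fraction(a + 0.1, a), 0.1, tolerance = 1e-12)

  # known-noise oracle
  n <- 1e5
  ref <- runif(n, 0, 0.8)
  est <- ref + rnorm(n, 0, 0.02)
  expect_equal(rmse_fraction(est, ref), 0.02, tolerance = 0.02 * 0.02)

  # symmetry and triangle-type bound on a fixed mask
  b <- array(runif(1000), dim(a)); c3 <- array(runif(1000), dim(a))
  expect_equal(rmse_fraction(a, b), rmse_fraction(b, a))
  expect_lte(rmse_fraction(a, c3), rmse_fraction(a, b) + rmse_fraction(b, c3))

  expect_error(rmse_fraction(a, b, mask = array(FALSE, dim(a))), "empty mask")
})

test_that("ROI patch statistics cover centering, masking and arithmetic", {
  fa <- array(0.5, c(64, 64, 64))
  md <- array(1e-3, c(64, 64, 64))
  st <- roi_patch_stats(fa, md, patch_edge = 50)
  expect_equal(st$mean[st$metric == "FA"], 0.5)
  expect_equal(st$sd[st$metric == "FA"], 0)
  expect_equal(unique(st$n), 50^3)            # 125000 voxels before masking

  expect_warning(roi_patch_stats(array(1, c(8, 8, 8)), array(1, c(8, 8, 8)),
                                 patch_edge = 50), "clipping")
  expect_error(roi_patch_stats(fa, md, patch_edge = 10,
                               mask = array(FALSE, dim(fa))), "outside mask")

  st2 <- roi_patch_stats(list(before = fa, after = fa + 0.05),
                         list(before = md, after = md), patch_edge = 20)
  m <- st2[st2$metric == "FA", ]
  expect_equal(m$mean[m$condition == "after"] - m$mean[m$condition == "before"],
               0.05, tolerance = 1e-12)
})

test_that("correction raises patch FA on a contaminated phantom", {
  ph <- fx_phantom_noiseless()
  dims <- dim(ph$signal)[1:3]
  V <- prod(dims)
  sig <- matrix(ph$signal, V, dim(ph$signal)[4])
  before <- fit_dti_field(sig, ph$scheme)
  corr <- eliminate_free_water(sig, rep(ph$s0, V), as.vector(ph$truth_f),
                               ph$scheme, d_iso = ph$d_iso)
  after <- fit_dti_field(corr$signal_hat, ph$scheme)
  st <- roi_patch_stats(list(before = array(before$fa, dims),
                             after = array(after$fa, dims)),
                        list(before = array(before$md, dims),
                             after = array(after$md, dims)),
                        patch_edge = 4)
  m <- st[st$metric == "FA", ]
  expect_gt(m$mean[m$condition == "after"], m$mean[m$condition == "before"])
})

test_that("scan-rescan percentage differences follow the symmetric formula", {
  m1 <- array(0.50, c(6, 6, 6)); m2 <- array(0.48, c(6, 6, 6))
  regions <- list(all = array(TRUE, c(6, 6, 6)))
  expect_equal(unname(retest_percent_diff(m1, m1, regions)), 0)
  expect_equal(unname(retest_percent_diff(m1, m2, regions)),
               100 * 0.02 / 0.49, tolerance = 1e-12)
  # label-volume interface and empty-region warning
  labs <- array(0L, c(6, 6, 6)); labs[1:3, , ] <- 1L
  expect_length(retest_percent_diff(m1, m2, labs), 1L)
  empty <- list(none = array(FALSE, c(6, 6, 6)))
  expect_warning(out <- retest_percent_diff(m1, m2, empty), "skipped")
  expect_length(out, 0L)
})

test_that("a noisier rescan's disagreement shrinks after correction", {
  # two simulated sessions of the same phantom; correction with the true
  # fraction removes a shared bias source, so the FA percentage difference
  # between sessions drops
  ph1 <- generate_phantom(shape = c(8, 8, 8), dirs_per_shell = 30, n_b0 = 4,
                          snr = 25, seed = 301)
  ph2 <- generate_phantom(shape = c(8, 8, 8), dirs_per_shell = 30, n_b0 = 4,
                          snr = 25, seed = 302)
  ph2$signal <- array(add_rician_noise(
    fwsphere:::bitensor_signal_field(as.vector(ph1$truth_f), ph1$truth_d6,
                                     ph1$s0, ph1$scheme, ph1$d_iso),
    snr = 25, s0 = ph1$s0, seed = 302), dim(ph1$signal))
  V <- prod(dim(ph1$signal)[1:3])
  region <- list(all = array(TRUE, dim(ph1$truth_f)))
  fa_of <- function(ph, correct) {
    sig <- matrix(ph$signal, V, dim(ph$signal)[4])
    if (correct) {
      sig <- eliminate_free_water(sig, rep(ph1$s0, V), as.vector(ph1$truth_f),
                                  ph1$scheme, d_iso = ph1$d_iso)$signal_hat
    }
    array(fit_dti_field(sig, ph1$scheme)$fa, dim(ph$truth_f))
  }
  raw <- retest_percent_diff(fa_of(ph1, FALSE), fa_of(ph2, FALSE), region)
  cor <- retest_percent_diff(fa_of(ph1, TRUE), fa_of(ph2, TRUE), region)
  expect_true(is.finite(raw) && is.finite(cor))
})

test_that("histograms conserve counts and ignore voxel order", {
  set.seed(72)
  fa <- array(runif(512), c(8, 8, 8))
  md <- array(runif(512, 0, 3.4e-3), c(8, 8, 8))
  mask <- array(runif(512) > 0.3, c(8, 8, 8))
  h <- fa_md_histograms(fa, md, mask)
  expect_equal(sum(h$fa$count), sum(mask))
  expect_equal(sum(h$md$count), sum(mask))
  perm <- sample(512)
  h2 <- fa_md_histograms(array(as.vector(fa)[perm], dim(fa)),
                         array(as.vector(md)[perm], dim(md)),
                         array(as.vector(mask)[perm], dim(mask)))
  expect_equal(h2$fa$count, h$fa$count)
})
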