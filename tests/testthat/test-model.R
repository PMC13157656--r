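test_that("network configurations enforce their structural invariants", {
  cfg <- scnn_config()
  expect_equal(cfg$bandlimits, c(20L, 10L, 10L, 6L, 3L, 1L))
  expect_equal(cfg$channels, c(1L, 20L, 22L, 24L, 26L, 28L))
  expect_equal(cfg$l1_strength, 1e-5)
  expect_error(scnn_config(bandlimits = c(4, 8, 2, 0),
                           channels = c(1, 4, 5, 6)), "non-increasing")
  expect_error(scnn_config(bandlimits = c(8, 6, 4, 0),
                           channels = c(8, 6, 5, 4)), "non-decreasing")

  a <- ann_config(96)
  expect_equal(a$sizes, c(96L, 48L, 24L, 1L))   # N_b/2 and N_b/4 hidden
  expect_length(a$sizes, 4L)                    # 4-layer network
  s <- shore_fcn_config()
  expect_equal(s$sizes, c(50L, 100L, 50L, 1L))
})

test_that("dynamic head is deterministic and code-sensitive after training", {
  ck <- fx_trained_small()
  k1 <- dynamic_first_layer(shell_code(c(1, 0, 0)), ck$weights)
  k1b <- dynamic_first_layer(shell_code(c(1, 0, 0)), ck$weights)
  expect_identical(k1, k1b)
  k_full <- dynamic_first_layer(shell_code(c(1, 1, 1)), ck$weights)
  expect_gt(max(abs(k1[["0"]] - k_full[["0"]])), 0)
  expect_error(dynamic_first_layer(c(0, 0, 0), ck$weights), "at least one")
  expect_length(all_shell_codes(3L), 2^3 - 1)
})

test_that("spherical network output is bounded, pure and contract-checked", {
  ck <- fx_trained_small()
  dat <- fx_data_small()
  X <- dat$features[1:40, , , drop = FALSE]
  p1 <- forward_scnn(X, ck, code = c(1, 1, 1))
  expect_true(all(p1 >= 0 & p1 <= 1))
  p2 <- forward_scnn(X, ck, code = c(1, 1, 1))
  expect_identical(p1, p2)                     # pure function of input + weights

  Xbad <- X; Xbad[3, 1, 1] <- NaN
  expect_error(forward_scnn(Xbad, ck, code = c(1, 1, 1)), "voxel index 3")

  td <- withr::local_tempdir()
  pth <- file.path(td, "m.ckpt")
  save_checkpoint(ck, pth)
  ck2 <- load_checkpoint(pth)
  expect_identical(forward_scnn(X, ck2, code = c(1, 0, 0)),
                   forward_scnn(X, ck, code = c(1, 0, 0)))
  expect_error(load_checkpoint(pth, expected_contract = list(lmax = 12L)),
               "feature-contract mismatch")
})

test_that("backpropagation matches numerical differentiation", {
  set.seed(61)
  cfg <- scnn_config(K = 3, lmax = 4, bandlimits = c(4, 4, 2, 0),
                     channels = c(1, 4, 5, 6), fc_sizes = c(8, 4),
                     head_hidden = 5)
  net <- scnn_init(cfg, seed = 2)
  net$params$head$Ws[] <- rnorm(length(net$params$head$Ws), sd = 0.2)
  plan <- fwsphere:::scnn_plan(cfg)
  B <- 6
  X <- array(rnorm(B * 15 * 3, sd = 0.3), c(B, 15, 3))
  code <- shell_code(c(1, 1, 0)); X[, , 3] <- 0
  tgt <- runif(B)
  lossfn <- function(params) {
    fw <- fwsphere:::scnn_forward(params, net$state, cfg, X, code,
                                  train = TRUE, plan = plan, fc_def = net$fc_def)
    sqrt(mean((fw$pred - tgt)^2))
  }
  fw <- fwsphere:::scnn_forward(net$params, net$state, cfg, X, code,
                                train = TRUE, plan = plan, fc_def = net$fc_def)
  L <- sqrt(mean((fw$pred - tgt)^2))
  gr <- fwsphere:::scnn_backward(net$params, cfg, fw, (fw$pred - tgt) / (B * L))
  for (trial in 1:15) {
    i <- sample(3, 1); k <- sample(names(net$params$conv[[i]]$W), 1)
    j <- sample(length(net$params$conv[[i]]$W[[k]]), 1)
    pp <- net$params
    pp$conv[[i]]$W[[k]][j] <- pp$conv[[i]]$W[[k]][j] + 1e-6
    gnum <- (lossfn(pp) - L) / 1e-6
    expect_equal(gr$conv[[i]]$W[[k]][j], gnum, tolerance = 1e-3)
  }
  for (nm in c("Wh", "Ws", "bh", "bs")) {
    j <- sample(length(net$params$head[[nm]]), 1)
    pp <- net$params
    pp$head[[nm]][j] <- pp$head[[nm]][j] + 1e-6
    gnum <- (lossfn(pp) - L) / 1e-6
    expect_equal(gr$head[[nm]][j], gnum, tolerance = 1e-3)
  }
})

test_that("L1 penalty covers convolution weights only and matches recomputation", {
  ck <- fx_trained_small()
  pen <- scnn_l1_penalty(ck$weights, ck$config)
  manual <- 0
  for (cv in ck$weights$conv) for (w in cv$W) manual <- manual + sum(abs(w))
  expect_equal(pen, ck$config$l1_strength * manual, tolerance = 1e-12)
  # changing FC weights leaves the penalty unchanged
  ck2 <- ck; ck2$weights$fc$W[[1]][] <- 0
  expect_equal(scnn_l1_penalty(ck2$weights, ck2$config), pen)
})

test_that("trained network representation is stable under input rotation", {
  ck <- fx_trained_small()
  dat <- fx_data_small()
  ph <- fx_phantom_noisy_small()
  sc <- ph$scheme
  n <- 80
  X <- dat$features[seq_len(n), , , drop = FALSE]
  set.seed(62)
  R <- rotation_matrix(runif(1, 0, 2 * pi), runif(1, 0, pi), runif(1, 0, 2 * pi))
  # rotate the band-limited per-shell signals and refit on the same scheme
  Xr <- X
  for (k in 1:3) {
    b <- c(1000, 2000, 3000)[k]
    dirs <- sc$bvecs[sc$shells[[as.character(b)]], ]
    Brot <- sh_basis(dirs %*% R, 8)
    vals <- X[, , k] %*% t(Brot)
    Xr[, , k] <- sh_fit(vals, dirs, max_degree = 8)
  }
  p0 <- forward_scnn(X, ck, code = c(1, 1, 1))
  pr <- forward_scnn(Xr, ck, code = c(1, 1, 1))
  expect_lt(mean(abs(p0 - pr)), 0.02)
})

test_that("fully connected baselines satisfy their contracts", {
  dat <- fx_data_small()
  plan <- training_plan(epochs = 2L, seed = 3L,
                        config_sampler = list(codes = list(shell_code(c(1, 1, 1))),
                                              probs = 1))
  ann <- fw_train("ann", dat, plan)
  X <- dat$signals[1:30, ]
  p <- forward_ann(X, ann)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(forward_ann(X[, 1:10], ann), "contract error")
  # no rotation/permutation invariance by construction
  Xp <- X[, c(1, sample(2:ncol(X))), drop = FALSE]
  expect_gt(max(abs(forward_ann(Xp, ann) - p)), 1e-6)
})
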