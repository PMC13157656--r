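test_that("shells form by nearest-center clustering and b0s are split off", {
  sc <- gradient_scheme(c(0, 1000, 1000),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(sc$b0_indices, 1L)
  expect_equal(sc$shells[["1000"]], c(2L, 3L))

  # jittered b-values assign to the nearest nominal center (checked against
  # brute-force assignment)
  bv <- c(0, 995, 2005, 3000)
  gv <- rbind(c(0, 0, 0), diag(3))
  sc2 <- gradient_scheme(bv, gv, shell_tolerance = 100)
  nominal <- sc2$nominal_bvals
  brute <- vapply(bv[-1], function(b) nominal[which.min(abs(nominal - b))],
                  numeric(1))
  got <- vapply(2:4, function(i) {
    as.numeric(names(which(vapply(sc2$shells, function(s) i %in% s, logical(1)))))
  }, numeric(1))
  expect_equal(got, brute)
  expect_equal(unname(lengths(sc2$shells)), c(1L, 1L, 1L))

  # partition: every index in exactly one of b0/shells
  all_idx <- sort(unname(c(sc2$b0_indices, unlist(sc2$shells))))
  expect_equal(all_idx, seq_along(bv))
})

test_that("degenerate and inconsistent gradient inputs are refused", {
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero direction")
  expect_error(gradient_scheme(c(0, 1000, 2000),
                               rbind(c(0, 0, 0), c(1, 0, 0))),
               "format error")
  # a b-value within tolerance of two nominal shells is ambiguous
  expect_error(gradient_scheme(c(0, 1000, 1150, 1300),
                               rbind(c(0, 0, 0), diag(3)),
                               shell_tolerance = 160),
               "ambigu")
})

test_that("FSL files round-trip within tolerance and auto-detect layout", {
  set.seed(11)
  sc <- fx_scheme3(20L)
  td <- withr::local_tempdir()
  bvalp <- file.path(td, "x.bval"); bvecp <- file.path(td, "x.bvec")
  write_gradients(sc, bvalp, bvecp)
  sc2 <- read_gradients(bvalp, bvecp)
  expect_lt(max(abs(sc2$bvals - sc$bvals)), 0.5)
  expect_lt(max(abs(sc2$bvecs - sc$bvecs)), 1e-6)
  expect_equal(names(sc2$shells), names(sc$shells))

  # N x 3 layout read back identically
  writeLines(apply(sc$bvecs, 1, paste, collapse = " "), bvecp)
  sc3 <- read_gradients(bvalp, bvecp)
  expect_lt(max(abs(sc3$bvecs - sc$bvecs)), 1e-6)

  expect_error(read_gradients(file.path(td, "missing.bval"), bvecp),
               "not found")
})

test_that("shell partition is invariant to measurement permutation", {
  set.seed(12)
  sc <- fx_scheme3(15L)
  perm <- sample(length(sc$bvals))
  sc2 <- gradient_scheme(sc$bvals[perm], sc$bvecs[perm, ])
  expect_equal(sc2$nominal_bvals, sc$nominal_bvals)
  for (nm in names(sc$shells)) {
    expect_equal(sort(perm[sc2$shells[[nm]]]), sort(sc$shells[[nm]]))
  }
})

test_that("shell codes encode availability against the training scheme", {
  sc <- fx_scheme3(15L)
  expect_equal(as.integer(shell_code_for(sc, c(1000, 2000, 3000))), c(1L, 1L, 1L))

  sc1 <- gradient_scheme(c(0, rep(1000, 15)),
                         rbind(c(0, 0, 0), fx_scheme3(15L)$bvecs[3:17, ]))
  expect_equal(as.integer(shell_code_for(sc1, c(1000, 2000, 3000))), c(1L, 0L, 0L))

  sc4 <- gradient_scheme(c(0, rep(4000, 15)),
                         rbind(c(0, 0, 0), fx_scheme3(15L)$bvecs[3:17, ]))
  expect_error(shell_code_for(sc4, c(1000, 2000, 3000)), "unusable")

  expect_error(shell_code(c(0, 0, 0)), "at least one")
  expect_error(shell_code(c(1, 2, 0)), "0 or 1")
  expect_length(all_shell_codes(3L), 7L)
})
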