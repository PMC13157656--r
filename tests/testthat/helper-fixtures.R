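# Shared fixtures, built lazily in code and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# three-shell scheme with n directions per shell and 2 b0s
fx_scheme3 <- function(n = 45L, seed = 101L) {
  fx_cached(paste0("scheme3_", n, "_", seed), function() {
    set.seed(seed)
    dirs <- repulsion_directions(n)
    gradient_scheme(c(0, 0, rep(c(1000, 2000, 3000), each = n)),
                    rbind(matrix(0, 2, 3), dirs, dirs, dirs))
  })
}

# small noiseless three-shell phantom
fx_phantom_noiseless <- function() {
  fx_cached("ph_noiseless", function() {
    generate_phantom(shape = c(6L, 6L, 6L), dirs_per_shell = 45L, n_b0 = 4L,
                     f_field = "uniform", snr = Inf, seed = 103L)
  })
}

# small noisy phantom for quick learning tests
fx_phantom_noisy_small <- function() {
  fx_cached("ph_noisy_small", function() {
    generate_phantom(shape = c(12L, 12L, 12L), dirs_per_shell = 45L,
                     n_b0 = 6L, snr = 30, f_field = "uniform", seed = 104L)
  })
}

fx_data_small <- function() {
  fx_cached("data_small", function() {
    prepare_training_data(fx_phantom_noisy_small())
  })
}

# compact network configuration used for desk-scale training
fx_scnn_config <- function() {
  scnn_config(K = 3L, lmax = 8L, bandlimits = c(8L, 6L, 4L, 2L, 0L),
              channels = c(1L, 12L, 14L, 16L, 16L),
              fc_sizes = c(64L, 32L), head_hidden = 16L)
}

# a briefly trained compact model on the small noisy phantom
fx_trained_small <- function() {
  fx_cached("trained_small", function() {
    plan <- training_plan(epochs = 10L, seed = 9L, patience = 12L,
                          batch_size = 64L)
    fw_train("scnn", fx_data_small(), plan, config = fx_scnn_config())
  })
}

rotation_matrix <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[2], d6[4],
           d6[2], d6[3], d6[5],
           d6[4], d6[5], d6[6]), 3, 3)
}

mat_to_d6 <- function(D) c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
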