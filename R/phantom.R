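#' Bi-tensor voxel parameters
#'
#' Generative/fit parameters of the two-compartment free-water model:
#' a free-water volume fraction `f` in \[0, 1\], a symmetric positive
#' semi-definite tissue tensor (mm^2/s), the isotropic free-water
#' diffusivity `d_iso` (mm^2/s) and the non-weighted signal `s0`.
#'
#' @param f free-water volume fraction.
#' @param d_tissue 3 x 3 symmetric PSD tensor (mm^2/s).
#' @param d_iso free-water diffusivity (default 3.0e-3 mm^2/s, the
#'   body-temperature value).
#' @param s0 non-diffusion-weighted signal.
#' @export
bitensor_params <- function(f, d_tissue, d_iso = 3.0e-3, s0 = 1) {
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (d_iso <= 0 || s0 <= 0) stop("d_iso and s0 must be positive")
  d_tissue <- (d_tissue + t(d_tissue)) / 2
  ev <- eigen(d_tissue, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1e-30)) {
    stop("domain error: tissue tensor is not positive semi-definite")
  }
  structure(list(f = f, d_tissue = d_tissue, d_iso = d_iso, s0 = s0),
            class = "bitensor_params")
}

#' Two-compartment (bi-tensor) forward signal
#'
#' Per measurement `i`,
#' \deqn{S_i = S_0 [(1-f) \exp(-b_i g_i^T D g_i) + f \exp(-b_i D_{iso})].}
#' b0 measurements return `s0` exactly.
#'
#' @param params a [bitensor_params()] object.
#' @param scheme a [gradient_scheme()].
#' @return numeric vector, one signal per measurement.
#' @export
bitensor_signal <- function(params, scheme) {
  stopifnot(inherits(params, "bitensor_params"))
  g <- scheme$bvecs
  b <- scheme$bvals
  quad <- rowSums((g %*% params$d_tissue) * g)
  s <- params$s0 * ((1 - params$f) * exp(-b * quad) +
                      params$f * exp(-b * params$d_iso))
  s[scheme$b0_indices] <- params$s0
  s
}

# Vectorized forward model over voxels. d6: V x 6 lower-triangular tensors
# (dxx, dxy, dyy, dxz, dyz, dzz); f, s0: length-V. Returns V x N signals.
#' @keywords internal
bitensor_signal_field <- function(f, d6, s0, scheme, d_iso = 3.0e-3) {
  g <- scheme$bvecs
  b <- scheme$bvals
  Gq <- rbind(g[, 1]^2, 2 * g[, 1] * g[, 2], g[, 2]^2,
              2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3], g[, 3]^2)  # 6 x N
  quad <- d6 %*% Gq                                   # V x N
  att <- exp(-sweep(quad, 2L, b, `*`))
  fw <- matrix(exp(-b * d_iso), nrow = nrow(quad), ncol = length(b),
               byrow = TRUE)
  s <- s0 * ((1 - f) * att + f * fw)
  s[, scheme$b0_indices] <- s0
  s
}

#' Add Rician noise to magnitude signals
#'
#' Each value `S` is replaced by `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `s0 / snr` — the
#' magnitude-MR noise model. Reproducible given `seed`.
#'
#' @param signal numeric vector/matrix/array of signals.
#' @param snr signal-to-noise ratio relative to `s0`.
#' @param s0 reference signal defining the noise scale (default 1).
#' @param seed integer seed (optional; if `NULL` the current RNG stream is
#'   used).
#' @export
add_rician_noise <- function(signal, snr, s0 = 1, seed = NULL) {
  if (snr <= 0) stop("snr must be positive")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  sigma <- s0 / snr
  n <- length(signal)
  noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
  attributes(noisy) <- attributes(signal)
  noisy
}

#' @keywords internal
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Quasi-uniform directions by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of antipodal point pairs on the sphere by
#' projected gradient descent, the standard construction for HARDI
#' direction tables. Deterministic given the RNG state.
#'
#' @param n number of directions.
#' @param n_iter descent iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsion_directions <- function(n, n_iter = 200L) {
  if (n < 6L) stop("need at least 6 directions")
  x <- matrix(stats::rnorm(3 * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  step <- 0.1 / n
  for (it in seq_len(n_iter)) {
    grad <- matrix(0, n, 3)
    for (s in c(1, -1)) {
      # force from x_j and its antipode -x_j
      for (j in seq_len(n)) {
        d <- sweep(x, 2L, s * x[j, ], `-`)
        r2 <- rowSums(d^2)
        r2[j] <- Inf
        r2[r2 < 1e-12] <- 1e-12
        grad <- grad + d / r2^1.5
      }
    }
    x <- x + step * grad
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' @keywords internal
min_pairwise_angle <- function(dirs) {
  g <- abs(dirs %*% t(dirs))
  diag(g) <- 0
  acos(pmin(1, max(g))) * 180 / pi
}

# Axially symmetric tensor with given mean diffusivity, fractional
# anisotropy and principal axis. FA = sqrt(3) d / sqrt(1 + 2 d^2) with
# lambda_1 = MD (1 + 2 d), lambda_perp = MD (1 - d); solving gives
# d = FA / sqrt(3 - 2 FA^2).
#' @keywords internal
tensor_from_md_fa <- function(md, fa, axis) {
  d <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * d)
  lp <- md * (1 - d)
  a <- axis / sqrt(sum(axis^2))
  D <- lp * diag(3) + (l1 - lp) * tcrossprod(a)
  D
}

#' @keywords internal
tensor_to_d6 <- function(D) c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])

#' @keywords internal
d6_to_tensor <- function(d6) {
  matrix(c(d6[1], d6[2], d6[4],
           d6[2], d6[3], d6[5],
           d6[4], d6[5], d6[6]), 3, 3)
}

# Simple separable 3D box-smoothing used to create spatially smooth truth
# fields (partial-volume interface band).
#' @keywords internal
smooth3d <- function(a, w = 3L) {
  k <- rep(1 / w, w)
  sm1 <- function(v) as.numeric(stats::filter(c(rep(v[1], w), v, rep(v[length(v)], w)),
                                              k, sides = 2L))[(w + 1):(w + length(v))]
  for (d in 1:3) {
    a <- apply(a, setdiff(1:3, d), sm1)
    a <- aperm(array(a, dim(a)), order(c(d, setdiff(1:3, d))))
  }
  a
}

#' Generate a bi-tensor free-water phantom
#'
#' Builds a synthetic multi-shell HARDI acquisition from the bi-tensor
#' forward model with known ground truth, emulating an HCP-style protocol
#' (default: shells at b = 1000, 2000, 3000 s/mm^2, 90 directions each,
#' plus interleaved b0 volumes). The truth fraction field is a smooth
#' spatial ramp 0 to 1 across a CSF-interface band along the third axis,
#' on top of a uniform tissue background f in \[0, 0.2\]. Tissue tensors
#' have FA drawn uniformly in \[0.2, 0.9\], mean diffusivity in
#' \[0.6e-3, 0.9e-3\] mm^2/s (parenchyma-like), and random principal
#' directions.
#'
#' @param shape integer 3-vector of volume extents.
#' @param shells nominal shell b-values (s/mm^2).
#' @param dirs_per_shell directions per shell (>= 6).
#' @param n_b0 number of b0 volumes.
#' @param f_field `"ramp"` (default, interface band + background),
#'   `"uniform"` (f ~ U(0, 0.9) i.i.d. then smoothed), or a numeric array
#'   of the requested shape.
#' @param snr Rician SNR relative to `s0`; `Inf` for noiseless.
#' @param seed integer seed; the phantom is bit-reproducible given it.
#' @param s0 non-weighted signal level.
#' @param d_iso free-water diffusivity (mm^2/s).
#' @param md_range,fa_range tissue tensor sampling ranges.
#' @return object of class `phantom_volume`: `signal` (4D array),
#'   `truth_f`, `truth_d6` (V x 6 with voxels in array order),
#'   `scheme`, `mask`, `snr`, `seed`, `s0`, `d_iso`.
#' @export
generate_phantom <- function(shape = c(16L, 16L, 16L),
                             shells = c(1000, 2000, 3000),
                             dirs_per_shell = 90L,
                             n_b0 = 18L,
                             f_field = "ramp",
                             snr = Inf,
                             seed = 1L,
                             s0 = 500,
                             d_iso = 3.0e-3,
                             md_range = c(0.6e-3, 0.9e-3),
                             fa_range = c(0.2, 0.9)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  if (dirs_per_shell < 6L) stop("parameter error: need >= 6 directions per shell")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  # acquisition: b0 block then shells, each with its own repulsion set
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, n_b0, 3)
  for (b in sort(shells)) {
    dirs <- repulsion_directions(dirs_per_shell)
    bvals <- c(bvals, rep(b, dirs_per_shell))
    bvecs <- rbind(bvecs, dirs)
  }
  scheme <- gradient_scheme(bvals, bvecs)

  V <- prod(shape)
  # truth fraction field
  if (is.character(f_field) && f_field == "ramp") {
    z <- (slice_index(shape, 3L) - 1) / max(1L, shape[3L] - 1L)
    ramp <- pmin(1, pmax(0, (z - 0.6) / 0.3))        # 0 -> 1 band at the top
    bg <- array(stats::runif(V, 0, 0.2), shape)
    f <- array(pmin(1, smooth3d(ramp + bg, 3L)), shape)
  } else if (is.character(f_field) && f_field == "uniform") {
    f <- array(stats::runif(V, 0, 0.9), shape)
    f <- array(pmin(0.9, pmax(0, smooth3d(f, 3L))), shape)
  } else if (is.numeric(f_field)) {
    f <- array(f_field, shape)
    if (any(f < 0 | f > 1)) stop("parameter error: supplied f field outside [0, 1]")
  } else stop("parameter error: unknown f_field spec")

  md <- stats::runif(V, md_range[1], md_range[2])
  fa <- stats::runif(V, fa_range[1], fa_range[2])
  ax <- matrix(stats::rnorm(3 * V), V, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  d6 <- matrix(0, V, 6)
  dlt <- fa / sqrt(3 - 2 * fa^2)
  l1 <- md * (1 + 2 * dlt); lp <- md * (1 - dlt)
  # D = lp I + (l1 - lp) a a^T, assembled componentwise
  dl <- l1 - lp
  d6[, 1] <- lp + dl * ax[, 1]^2
  d6[, 2] <- dl * ax[, 1] * ax[, 2]
  d6[, 3] <- lp + dl * ax[, 2]^2
  d6[, 4] <- dl * ax[, 1] * ax[, 3]
  d6[, 5] <- dl * ax[, 2] * ax[, 3]
  d6[, 6] <- lp + dl * ax[, 3]^2

  sig <- bitensor_signal_field(as.vector(f), d6, s0, scheme, d_iso)
  if (is.finite(snr)) sig <- add_rician_noise(sig, snr, s0 = s0)

  structure(
    list(signal = array(sig, c(shape, length(scheme$bvals))),
         truth_f = f,
         truth_d6 = d6,
         scheme = scheme,
         mask = array(TRUE, shape),
         snr = snr, seed = as.integer(seed), s0 = s0, d_iso = d_iso),
    class = "phantom_volume")
}

#' @keywords internal
slice_index <- function(shape, axis) {
  idx <- array(0, shape)
  perm <- c(axis, setdiff(1:3, axis))
  tmp <- array(rep(seq_len(shape[axis]),
                   times = prod(shape[setdiff(1:3, axis)])),
               shape[perm])
  aperm(tmp, order(perm))
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("phantom_volume:", paste(dim(x$signal)[1:3], collapse = " x "),
      "voxels,", dim(x$signal)[4], "measurements, SNR",
      if (is.finite(x$snr)) x$snr else "Inf", "\n")
  invisible(x)
}

#' Write a phantom to disk as NIfTI + FSL gradients
#'
#' @param phantom a `phantom_volume`.
#' @param prefix output path prefix; writes `<prefix>_dwi.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`, `<prefix>_truthf.nii.gz`,
#'   `<prefix>_mask.nii.gz`.
#' @export
write_phantom <- function(phantom, prefix) {
  RNifti::writeNifti(RNifti::asNifti(phantom$signal),
                     paste0(prefix, "_dwi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$truth_f),
                     paste0(prefix, "_truthf.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$mask + 0),
                     paste0(prefix, "_mask.nii.gz"))
  write_gradients(phantom$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}
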