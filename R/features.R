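#' Per-shell spherical-harmonic feature blocks
#'
#' Expands the normalized signal of each available shell in a real,
#' even-degree SH basis up to degree 8 (45 coefficients per shell). Blocks
#' of shells flagged absent in the shell code are zero-filled, so features
#' computed from full data under a reduced code are identical to features
#' computed from a genuinely reduced acquisition — the dropout-consistency
#' contract that lets one network serve every shell configuration.
#'
#' @param volume normalized signal: V x N matrix or 4D array (use
#'   [normalize_signal()] first).
#' @param scheme a [gradient_scheme()].
#' @param code a [shell_code()]; defaults to the code derived from the
#'   scheme itself.
#' @param training_shells nominal training shell b-values (defines block
#'   order and K).
#' @param max_degree maximum even SH degree (default 8).
#' @param reg Laplace-Beltrami weight used when a shell has fewer
#'   directions than coefficients (default 6e-3; 0 otherwise).
#' @return object of class `shell_feature_set`: `coeffs` (V x C x K
#'   array), `code`, `training_shells`, `max_degree`.
#' @export
build_feature_set <- function(volume, scheme, code = NULL,
                              training_shells = c(1000, 2000, 3000),
                              max_degree = 8L, reg = 6e-3) {
  dims <- NULL
  if (length(dim(volume)) == 4L) {
    dims <- dim(volume)[1:3]
    volume <- matrix(volume, prod(dims), dim(volume)[4L])
  }
  volume <- as.matrix(volume)
  K <- length(training_shells)
  if (is.null(code)) code <- shell_code_for(scheme, training_shells)
  if (length(code) != K) stop("configuration error: code length != K")
  C <- sh_ncoef(max_degree)
  V <- nrow(volume)
  coeffs <- array(0, c(V, C, K))
  tol <- scheme$shell_tolerance
  for (k in seq_len(K)) {
    if (code[k] == 0L) next
    hit <- which(abs(scheme$nominal_bvals - training_shells[k]) <= tol)
    if (!length(hit)) {
      stop("configuration error: code flags shell ", training_shells[k],
           " s/mm^2 present but the scheme has no matching shell")
    }
    idx <- scheme$shells[[hit[1L]]]
    dirs <- scheme$bvecs[idx, , drop = FALSE]
    use_reg <- if (length(idx) < C) reg else 0
    op <- sh_fit_operator(dirs, max_degree, use_reg)
    coeffs[, , k] <- volume[, idx, drop = FALSE] %*% op$pinv
  }
  structure(list(coeffs = coeffs, code = code,
                 training_shells = training_shells,
                 max_degree = as.integer(max_degree), dims = dims),
            class = "shell_feature_set")
}

#' Zero the feature blocks of absent shells
#'
#' @param features a `shell_feature_set`.
#' @param code the [shell_code()] to impose.
#' @return the feature set with absent blocks zeroed and `code` replaced.
#' @export
apply_shell_code <- function(features, code) {
  stopifnot(inherits(features, "shell_feature_set"))
  if (length(code) != dim(features$coeffs)[3L]) {
    stop("configuration error: code length != K")
  }
  for (k in which(code == 0L)) features$coeffs[, , k] <- 0
  features$code <- shell_code(code)
  features
}

# ---- SHORE (simple harmonic oscillator based reconstruction) ----------------

#' @keywords internal
shore_index_table <- function(radial_order = 6L) {
  n <- integer(0); l <- integer(0); m <- integer(0)
  for (deg in seq(0L, radial_order, by = 2L)) {
    for (nn in deg:((radial_order + deg) %/% 2L)) {
      n <- c(n, rep.int(nn, 2L * deg + 1L))
      l <- c(l, rep.int(deg, 2L * deg + 1L))
      m <- c(m, seq(-deg, deg))
    }
  }
  list(n = n, l = l, m = m)
}

# Generalized Laguerre polynomial L_k^alpha(x), by recurrence.
#' @keywords internal
genlaguerre <- function(k, alpha, x) {
  if (k == 0L) return(rep(1, length(x)))
  lm1 <- rep(1, length(x))
  lcur <- 1 + alpha - x
  if (k == 1L) return(lcur)
  for (j in 2:k) {
    lnew <- ((2 * j - 1 + alpha - x) * lcur - (j - 1 + alpha) * lm1) / j
    lm1 <- lcur; lcur <- lnew
  }
  lcur
}

#' @keywords internal
shore_basis_matrix <- function(scheme, zeta, tau, radial_order = 6L) {
  qsq <- scheme$bvals / (4 * pi^2 * tau)          # q^2 (mm^-2)
  x <- qsq / zeta
  tab <- shore_index_table(radial_order)
  # angular part: full (even) SH up to radial_order at the gradient dirs;
  # b0 rows get the l = 0 constant only (direction undefined at q = 0)
  dirs <- scheme$bvecs
  safe <- rowSums(dirs^2) > 0.5
  dirs[!safe, ] <- rep(c(0, 0, 1), each = sum(!safe))
  Y <- sh_basis(dirs, radial_order)
  lY <- attr(Y, "l"); mY <- attr(Y, "m")
  B <- matrix(0, length(x), length(tab$n))
  radial_cache <- list()
  for (j in seq_along(tab$n)) {
    nn <- tab$n[j]; ll <- tab$l[j]; mm <- tab$m[j]
    key <- paste0(nn, "_", ll)
    if (is.null(radial_cache[[key]])) {
      kap <- sqrt(2 * factorial(nn - ll) / (zeta^1.5 * gamma(nn + 1.5)))
      rad <- kap * x^(ll / 2) * exp(-x / 2) * genlaguerre(nn - ll, ll + 0.5, x)
      rad[!safe & ll > 0L] <- 0
      radial_cache[[key]] <- rad
    }
    ycol <- Y[, which(lY == ll & mY == mm)]
    if (ll > 0L) ycol[!safe] <- 0
    B[, j] <- radial_cache[[key]] * ycol
  }
  attr(B, "n") <- tab$n; attr(B, "l") <- tab$l; attr(B, "m") <- tab$m
  B
}

#' Fit SHORE coefficients to one voxel
#'
#' Regularized least squares in the simple-harmonic-oscillator basis at
#' radial order 6 (50 coefficients). The scale is
#' \eqn{\zeta = 1 / (8 \pi^2 \tau \, MD)} with the mean diffusivity taken
#' from the voxel's DTI fit; nonpositive MD falls back to 0.7e-3 mm^2/s
#' with a warning. Regularization penalizes radial and angular roughness
#' with weight `lambda_reg` (default 1e-8) each.
#'
#' @param values per-measurement signal vector.
#' @param scheme a [gradient_scheme()].
#' @param tau effective diffusion time (s); default 0.025 s (used when
#'   acquisition timing is unknown; it only scales zeta and is recorded).
#' @param lambda_reg regularization constant.
#' @param md voxel mean diffusivity (mm^2/s); if `NULL`, computed from a
#'   DTI fit of `values`.
#' @param radial_order SHORE radial order (default 6).
#' @return object of class `shore_features`: `coeffs` (50 at order 6),
#'   `zeta` (mm^-2), `tau`, `lambda_reg`, `md`, index attributes `n`, `l`,
#'   `m`.
#' @export
shore_fit <- function(values, scheme, tau = 0.025, lambda_reg = 1e-8,
                      md = NULL, radial_order = 6L) {
  if (is.null(md)) md <- fit_dti(values, scheme)$md
  if (!is.finite(md) || md <= 0) {
    warning("nonpositive MD; falling back to 0.7e-3 mm^2/s for the SHORE scale")
    md <- 0.7e-3
  }
  zeta <- 1 / (8 * pi^2 * tau * md)
  B <- shore_basis_matrix(scheme, zeta, tau, radial_order)
  n <- attr(B, "n"); l <- attr(B, "l")
  P <- diag(lambda_reg * (l^2 * (l + 1)^2 + n^2 * (n + 1)^2), ncol(B))
  coeffs <- drop(solve(crossprod(B) + P, crossprod(B, values)))
  structure(list(coeffs = coeffs, zeta = zeta, tau = tau,
                 lambda_reg = lambda_reg, md = md,
                 radial_order = as.integer(radial_order),
                 n = attr(B, "n"), l = attr(B, "l"), m = attr(B, "m")),
            class = "shore_features")
}

#' Evaluate a SHORE fit at the acquisition's sample points
#' @param features a `shore_features` object.
#' @param scheme the acquisition scheme to evaluate at.
#' @export
shore_reconstruct <- function(features, scheme) {
  B <- shore_basis_matrix(scheme, features$zeta, features$tau,
                          features$radial_order)
  drop(B %*% features$coeffs)
}

#' Fit SHORE coefficients to many voxels
#'
#' Per-voxel scale from the voxel's DTI MD; the basis is rebuilt per voxel
#' (the scale enters nonlinearly), with cached angular terms.
#'
#' @param signal V x N matrix.
#' @param scheme a [gradient_scheme()].
#' @param md per-voxel MD (length V); computed by [fit_dti_field()] when
#'   `NULL`.
#' @inheritParams shore_fit
#' @return list with `coeffs` (V x 50), `zeta` (length V), `tau`.
#' @export
shore_fit_field <- function(signal, scheme, tau = 0.025, lambda_reg = 1e-8,
                            md = NULL, radial_order = 6L) {
  signal <- as.matrix(signal)
  if (is.null(md)) md <- fit_dti_field(signal, scheme)$md
  bad <- !is.finite(md) | md <= 0
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with nonpositive MD; SHORE scale fallback 0.7e-3")
    md[bad] <- 0.7e-3
  }
  zeta <- 1 / (8 * pi^2 * tau * md)
  tab <- shore_index_table(radial_order)
  nc <- length(tab$n)
  out <- matrix(0, nrow(signal), nc)
  P <- diag(lambda_reg * (tab$l^2 * (tab$l + 1)^2 + tab$n^2 * (tab$n + 1)^2), nc)
  for (v in seq_len(nrow(signal))) {
    B <- shore_basis_matrix(scheme, zeta[v], tau, radial_order)
    out[v, ] <- solve(crossprod(B) + P, crossprod(B, signal[v, ]))
  }
  list(coeffs = out, zeta = zeta, tau = tau, md = md,
       n = tab$n, l = tab$l, m = tab$m)
}
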