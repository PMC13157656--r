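#' @keywords internal
dti_design <- function(scheme) {
  g <- scheme$bvecs; b <- scheme$bvals
  cbind(1,
        -b * g[, 1]^2, -2 * b * g[, 1] * g[, 2], -b * g[, 2]^2,
        -2 * b * g[, 1] * g[, 3], -2 * b * g[, 2] * g[, 3], -b * g[, 3]^2)
}

# Eigenvalues of symmetric 3x3 tensors, vectorized over rows of d6
# (dxx, dxy, dyy, dxz, dyz, dzz); analytic trigonometric solution.
# Returns V x 3 sorted descending.
#' @keywords internal
eigvals_sym3 <- function(d6) {
  d6 <- rbind(d6)
  a <- d6[, 1]; b <- d6[, 3]; c <- d6[, 6]
  d <- d6[, 2]; e <- d6[, 5]; f <- d6[, 4]
  p1 <- d^2 + e^2 + f^2
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ev <- matrix(q, nrow = length(q), ncol = 3)
  nz <- p > 0
  if (any(nz)) {
    pn <- p[nz]; qn <- q[nz]
    an <- (a[nz] - qn) / pn; bn <- (b[nz] - qn) / pn; cn <- (c[nz] - qn) / pn
    dn <- d[nz] / pn; en <- e[nz] / pn; fn <- f[nz] / pn
    # det of (A - qI)/p
    detB <- an * (bn * cn - en^2) - dn * (dn * cn - en * fn) +
      fn * (dn * en - bn * fn)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    l1 <- qn + 2 * pn * cos(phi)
    l3 <- qn + 2 * pn * cos(phi + 2 * pi / 3)
    l2 <- 3 * qn - l1 - l3
    ev[nz, ] <- cbind(l1, l2, l3)
  }
  ev
}

# FA/MD from eigenvalue rows; eigenvalues clamped at 0 before the metric
# computation so noise-driven negative eigenvalues cannot push FA past 1.
#' @keywords internal
fa_md_from_eigvals <- function(ev) {
  ev <- pmax(rbind(ev), 0)
  md <- rowMeans(ev)
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  list(fa = unname(pmin(1, fa)), md = unname(md))
}

#' Fit the single diffusion tensor to one voxel
#'
#' Two-pass weighted least squares on the log-signal: an ordinary LS pass
#' provides predicted signals whose squares serve as WLS weights (the
#' standard correction for log-transformed Rician-mean noise). Nonpositive
#' signals are floored at `1e-6 * S0` before the log.
#'
#' @param signal per-measurement signal vector.
#' @param scheme a [gradient_scheme()].
#' @return object of class `dti_metrics`: `tensor` (3 x 3, mm^2/s),
#'   `eigenvalues` (sorted descending), `fa`, `md`, `s0`.
#' @export
fit_dti <- function(signal, scheme) {
  fit <- fit_dti_field(matrix(signal, nrow = 1L), scheme)
  D <- d6_to_tensor(fit$d6[1L, ])
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  met <- fa_md_from_eigvals(ev)
  structure(list(tensor = D, eigenvalues = ev, fa = met$fa, md = met$md,
                 s0 = fit$s0[1L]),
            class = "dti_metrics")
}

#' Fit diffusion tensors to many voxels at once
#'
#' @param signal V x N matrix (rows = voxels) of signals.
#' @param scheme a [gradient_scheme()].
#' @param method `"wls"` (two-pass weighted LS, default) or `"ols"`.
#' @return list with `d6` (V x 6 lower-triangular tensors), `fa`, `md`,
#'   `s0`, `eigenvalues` (V x 3).
#' @export
fit_dti_field <- function(signal, scheme, method = c("wls", "ols")) {
  method <- match.arg(method)
  signal <- as.matrix(signal)
  if (ncol(signal) != length(scheme$bvals)) stop("signal/scheme length mismatch")
  ndir <- length(scheme$bvals) - length(scheme$b0_indices)
  if (ndir < 6L || length(scheme$b0_indices) < 1L) {
    stop("fit error: need >= 6 diffusion-weighted directions and >= 1 b0")
  }
  X <- dti_design(scheme)
  if (qr(X)$rank < 7L) stop("fit error: rank-deficient design (coplanar directions?)")
  s0 <- rowMeans(signal[, scheme$b0_indices, drop = FALSE])
  floorv <- pmax(1e-6 * s0, 1e-300)
  y <- log(pmax(signal, floorv))
  XtXinv <- solve(crossprod(X))
  beta <- y %*% X %*% XtXinv                       # V x 7, OLS
  if (method == "wls") {
    w <- exp(2 * tcrossprod(beta, X))              # predicted signal squared
    pairs <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
    XX <- X[, pairs[, 1]] * X[, pairs[, 2]]        # N x 28
    A <- w %*% XX                                  # V x 28
    Rhs <- (w * y) %*% X                           # V x 7
    M <- matrix(0, 7, 7)
    for (v in seq_len(nrow(signal))) {
      M[cbind(pairs[, 1], pairs[, 2])] <- A[v, ]
      M[cbind(pairs[, 2], pairs[, 1])] <- A[v, ]
      bet <- tryCatch(solve(M, Rhs[v, ]), error = function(e) beta[v, ])
      beta[v, ] <- bet
    }
  }
  d6 <- beta[, 2:7, drop = FALSE]
  ev <- eigvals_sym3(d6)
  met <- fa_md_from_eigvals(ev)
  list(d6 = d6, fa = met$fa, md = met$md, s0 = exp(beta[, 1]),
       eigenvalues = ev)
}

#' Fit the two-compartment free-water tensor model (multi-shell)
#'
#' Per-voxel nonlinear least squares of the bi-tensor model over
#' `(f, D_tissue)` with the free-water diffusivity fixed. `f` is
#' box-constrained to \[0, 1\] and the tissue tensor kept positive
#' semi-definite through a Cholesky factor parameterization. Initialization
#' comes from a plain DTI fit, with the initial fraction interpolated
#' linearly between a tissue reference MD and the free-water diffusivity
#' (clipped to \[0.05, 0.95\]). Afterwards the mean-diffusivity threshold
#' (default 2.7e-3 mm^2/s) marks voxels whose signal is taken to be pure
#' free water: `f = 1`, tissue tensor zeroed. This multi-shell fit is
#' what produces silver-standard fraction maps for training.
#'
#' @param signal 4D array (x, y, z, measurement) or V x N matrix.
#' @param scheme a [gradient_scheme()] with at least two distinct nonzero
#'   shells (the well-posed regime; single-shell input is refused with a
#'   pointer to the learned estimator).
#' @param mask logical 3D array (or length-V vector); voxels outside are
#'   skipped with `f = 0`.
#' @param d_iso fixed free-water diffusivity (mm^2/s).
#' @param md_threshold mean-diffusivity threshold above which a voxel is
#'   declared pure free water.
#' @param md_tissue_ref tissue reference MD for fraction initialization.
#' @return object of class `free_water_map`: `f` (array/vector in \[0,1\]),
#'   `tissue_d6` (V x 6), `exit_flags` (integer: 0 skipped, 1 converged,
#'   2 thresholded-to-1, 3 failed), `md_dti` (plain DTI MD), `d_iso`.
#' @export
fit_fwdti <- function(signal, scheme, mask = NULL, d_iso = 3.0e-3,
                      md_threshold = 2.7e-3, md_tissue_ref = 0.6e-3) {
  dims <- NULL
  if (length(dim(signal)) == 4L) {
    dims <- dim(signal)[1:3]
    signal <- matrix(signal, prod(dims), dim(signal)[4L])
  }
  signal <- as.matrix(signal)
  if (length(scheme$shells) < 2L) {
    stop("ill-posed: the free-water tensor fit needs >= 2 distinct nonzero ",
         "shells; use the learned estimator (predict_fw) for single-shell data")
  }
  V <- nrow(signal)
  mask <- if (is.null(mask)) rep(TRUE, V) else as.logical(mask)
  if (length(mask) != V) stop("mask/signal shape mismatch")

  dti <- fit_dti_field(signal[mask, , drop = FALSE], scheme)
  f0 <- pmin(0.95, pmax(0.05, (dti$md - md_tissue_ref) / (d_iso - md_tissue_ref)))
  # S0 from the b0 average, not the log-linear intercept: the bi-exponential
  # decay biases the extrapolated intercept upward.
  s0_b0 <- rowMeans(signal[mask, scheme$b0_indices, drop = FALSE])

  g <- scheme$bvecs; b <- scheme$bvals
  eiso <- exp(-b * d_iso)
  n_m <- sum(mask)
  fhat <- numeric(n_m); d6hat <- matrix(0, n_m, 6); flag <- integer(n_m)
  midx <- which(mask)
  for (v in seq_len(n_m)) {
    y <- signal[midx[v], ]
    s0 <- s0_b0[v]
    D0 <- d6_to_tensor(dti$d6[v, ])
    ed <- eigen(D0, symmetric = TRUE)
    lam <- pmax(ed$values, 1e-6 * d_iso)
    R0 <- ed$vectors %*% diag(sqrt(lam))           # D0 = R0 R0^T (PSD projected)
    theta0 <- c(f0[v], as.vector(R0))
    objgrad <- local({
      gl <- g; bl <- b; yl <- y; s0l <- s0; eisol <- eiso
      list(
        fn = function(th) {
          Rm <- matrix(th[-1], 3, 3)
          quad <- rowSums((gl %*% Rm)^2)
          s <- s0l * ((1 - th[1]) * exp(-bl * quad) + th[1] * eisol)
          sum((s - yl)^2)
        },
        gr = function(th) {
          Rm <- matrix(th[-1], 3, 3)
          A <- gl %*% Rm
          quad <- rowSums(A^2)
          et <- exp(-bl * quad)
          s <- s0l * ((1 - th[1]) * et + th[1] * eisol)
          r <- s - yl
          gf <- 2 * sum(r * s0l * (eisol - et))
          cvec <- -2 * r * s0l * (1 - th[1]) * et * bl
          gR <- 2 * t(gl) %*% (cvec * A)
          c(gf, as.vector(gR))
        })
    })
    fit <- stats::optim(theta0, objgrad$fn, objgrad$gr, method = "L-BFGS-B",
                        lower = c(0, rep(-Inf, 9)), upper = c(1, rep(Inf, 9)),
                        control = list(maxit = 200L, factr = 1e4))
    if (fit$convergence == 0L) {
      Rm <- matrix(fit$par[-1], 3, 3)
      fhat[v] <- fit$par[1]
      d6hat[v, ] <- tensor_to_d6(Rm %*% t(Rm))
      flag[v] <- 1L
    } else {
      fhat[v] <- f0[v]
      d6hat[v, ] <- dti$d6[v, ]
      flag[v] <- 3L
    }
  }

  f_full <- numeric(V); d6_full <- matrix(0, V, 6)
  flag_full <- integer(V); md_full <- rep(NA_real_, V)
  f_full[mask] <- fhat; d6_full[mask, ] <- d6hat
  flag_full[mask] <- flag; md_full[mask] <- dti$md

  out <- structure(
    list(f = if (is.null(dims)) f_full else array(f_full, dims),
         tissue_d6 = d6_full,
         exit_flags = if (is.null(dims)) flag_full else array(flag_full, dims),
         md_dti = if (is.null(dims)) md_full else array(md_full, dims),
         mask = if (is.null(dims)) mask else array(mask, dims),
         d_iso = d_iso),
    class = "free_water_map")
  apply_md_threshold(out, md = out$md_dti, threshold = md_threshold)
}

#' Mean-diffusivity regularization threshold
#'
#' Voxels whose (plain DTI) mean diffusivity exceeds the threshold —
#' default 2.7e-3 mm^2/s, approximately the free-water diffusivity — are
#' assumed to contain pure free water: their fraction is set to 1, the
#' tissue tensor entries to exactly 0, and the exit flag to
#' thresholded-to-1. All other voxels are unchanged.
#'
#' @param map a `free_water_map`.
#' @param md per-voxel mean diffusivity (defaults to the DTI MD stored in
#'   the map).
#' @param threshold mm^2/s; `Inf` makes this a no-op.
#' @return the updated `free_water_map`.
#' @export
apply_md_threshold <- function(map, md = map$md_dti, threshold = 2.7e-3) {
  if (threshold <= 0) stop("threshold must be positive")
  hit <- !is.na(md) & md > threshold & as.vector(map$mask)
  if (any(hit)) {
    map$f[hit] <- 1
    map$tissue_d6[as.vector(hit), ] <- 0
    map$exit_flags[hit] <- 2L
  }
  map
}

#' @export
print.free_water_map <- function(x, ...) {
  fl <- table(factor(as.vector(x$exit_flags), levels = 0:3,
                     labels = c("skipped", "converged", "thresholded-to-1", "failed")))
  cat("free_water_map:", length(x$f), "voxels; flags:",
      paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a free-water map as NIfTI volumes
#'
#' Writes the fraction map, the exit-flag map, and the tissue tensor field
#' (6 components, lower-triangular order dxx, dxy, dyy, dxz, dyz, dzz).
#'
#' @param map a `free_water_map` with array-shaped fields.
#' @param prefix output path prefix.
#' @export
write_free_water_map <- function(map, prefix) {
  if (is.null(dim(map$f))) stop("map has no spatial shape to write")
  RNifti::writeNifti(RNifti::asNifti(map$f), paste0(prefix, "_fw.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(map$exit_flags + 0),
                     paste0(prefix, "_flags.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(map$tissue_d6, c(dim(map$f), 6L))),
                     paste0(prefix, "_tensor.nii.gz"))
  invisible(prefix)
}
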