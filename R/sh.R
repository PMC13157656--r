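#' Real symmetric spherical-harmonic basis
#'
#' Diffusion signals are antipodally symmetric, so only even-degree
#' harmonics are used. The basis is real and orthonormal on the sphere:
#' for degree `l` and order `m`,
#' \deqn{Y_{lm} = \sqrt{2} N_l^{|m|} P_l^{|m|}(\cos\theta)\sin(|m|\phi)}
#' for `m < 0`, \eqn{N_l^0 P_l^0(\cos\theta)} for `m = 0`, and
#' \eqn{\sqrt{2} N_l^m P_l^m(\cos\theta)\cos(m\phi)} for `m > 0`, with
#' \eqn{N_l^m = \sqrt{(2l+1)/(4\pi)\,(l-m)!/(l+m)!}} and associated
#' Legendre functions without the Condon-Shortley phase. Coefficients are
#' ordered by even degree ascending, and within a degree by order
#' `m = -l, ..., l`. Degree 8 gives 45 coefficients.
#'
#' @param dirs N x 3 matrix of unit direction vectors.
#' @param lmax maximum (even) harmonic degree.
#' @return N x C basis matrix with attributes `l` and `m` (integer vectors
#'   giving the degree/order of each column).
#' @export
sh_basis <- function(dirs, lmax = 8L) {
  dirs <- as_direction_matrix(dirs)
  lmax <- as.integer(lmax)
  if (lmax %% 2L != 0L || lmax < 0L) stop("lmax must be an even, non-negative degree")
  ct <- pmin(pmax(dirs[, 3L], -1), 1)            # cos(theta)
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  P <- assoc_legendre_all(ct, lmax)              # list P[[l+1]][, m+1]
  ord <- sh_ordering(lmax)
  B <- matrix(0, nrow = nrow(dirs), ncol = length(ord$l))
  for (j in seq_along(ord$l)) {
    l <- ord$l[j]; m <- ord$m[j]; am <- abs(m)
    nlm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    leg <- P[[l + 1L]][, am + 1L]
    B[, j] <- if (m == 0L) nlm * leg
      else if (m > 0L) sqrt(2) * nlm * leg * cos(m * phi)
      else sqrt(2) * nlm * leg * sin(am * phi)
  }
  attr(B, "l") <- ord$l
  attr(B, "m") <- ord$m
  B
}

#' @keywords internal
sh_ordering <- function(lmax) {
  l <- integer(0); m <- integer(0)
  for (deg in seq(0L, lmax, by = 2L)) {
    l <- c(l, rep.int(deg, 2L * deg + 1L))
    m <- c(m, seq(-deg, deg))
  }
  list(l = l, m = m)
}

#' Number of even-degree SH coefficients up to `lmax`
#' @keywords internal
sh_ncoef <- function(lmax) as.integer((lmax / 2 + 1) * (lmax + 1))

# Associated Legendre P_l^m(x) for all l <= lmax, 0 <= m <= l, without the
# Condon-Shortley phase. Standard stable recurrences; degrees here stay
# small (<= 8) so unnormalized values are safe.
#' @keywords internal
assoc_legendre_all <- function(x, lmax) {
  n <- length(x)
  sx <- sqrt(pmax(0, 1 - x^2))                   # sin(theta)
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- matrix(0, n, l + 1L)
  P[[1L]][, 1L] <- 1
  if (lmax >= 1L) {
    # diagonal terms P_m^m and first off-diagonal P_{m+1}^m
    for (m in 1:lmax) {
      dfact <- prod(seq(1, 2 * m - 1, by = 2))   # (2m-1)!!
      P[[m + 1L]][, m + 1L] <- dfact * sx^m
    }
    for (m in 0:(lmax - 1L)) {
      P[[m + 2L]][, m + 1L] <- (2 * m + 1) * x * P[[m + 1L]][, m + 1L]
    }
    for (m in 0:lmax) {
      if (m + 2L > lmax) next
      for (l in (m + 2L):lmax) {
        P[[l + 1L]][, m + 1L] <-
          ((2 * l - 1) * x * P[[l]][, m + 1L] -
             (l + m - 1) * P[[l - 1L]][, m + 1L]) / (l - m)
      }
    }
  }
  P
}

#' Spherical quadrature grid
#'
#' Gauss-Legendre nodes in colatitude crossed with a uniform longitude
#' grid. The rule integrates spherical polynomials up to combined degree
#' `2*n_theta - 1` in `cos(theta)` exactly, which is what the band-limited
#' product projections in the network activations require.
#'
#' @param n_theta number of Gauss-Legendre colatitude nodes.
#' @param n_phi number of equally spaced longitudes.
#' @return list with `dirs` (N x 3) and quadrature `weights` (sum = 4*pi).
#' @export
sphere_quadrature <- function(n_theta, n_phi) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  dirs <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = n_phi)
  )
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  list(dirs = dirs, weights = w)
}

#' Fit real symmetric spherical harmonics to directional samples
#'
#' Least squares in the even-degree real SH basis, optionally with
#' Laplace-Beltrami regularization (penalty `l^2 (l+1)^2` per degree),
#' which conditions fits on direction sets smaller than the coefficient
#' count.
#'
#' @param values numeric vector (one sample per direction) or V x N matrix
#'   of per-voxel rows.
#' @param directions N x 3 unit vectors.
#' @param max_degree maximum even degree (default 8).
#' @param reg Laplace-Beltrami regularization weight (default 0; use
#'   ~6e-3 for direction sets below the coefficient count).
#' @param cond_cap largest acceptable condition number of the
#'   (regularized) normal matrix before the direction set is declared
#'   degenerate.
#' @return coefficient vector (or V x C matrix) carrying attributes `l`
#'   and `m`.
#' @export
sh_fit <- function(values, directions, max_degree = 8L, reg = 0,
                   cond_cap = 1e8) {
  op <- sh_fit_operator(directions, max_degree, reg, cond_cap)
  single <- is.null(dim(values))
  V <- if (single) matrix(values, nrow = 1L) else as.matrix(values)
  if (ncol(V) != nrow(op$basis)) stop("number of values does not match number of directions")
  C <- V %*% op$pinv
  attr(C, "l") <- attr(op$basis, "l")
  attr(C, "m") <- attr(op$basis, "m")
  if (single) {
    cvec <- drop(C)
    attr(cvec, "l") <- attr(op$basis, "l")
    attr(cvec, "m") <- attr(op$basis, "m")
    cvec
  } else C
}

# Precomputed fitting operator: pinv is N x C so that coeffs = values %*% pinv.
#' @keywords internal
sh_fit_operator <- function(directions, max_degree = 8L, reg = 0,
                            cond_cap = 1e8) {
  B <- sh_basis(directions, max_degree)
  l <- attr(B, "l")
  M <- crossprod(B) + diag(reg * l^2 * (l + 1)^2, ncol(B))
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > cond_cap) {
    stop("degenerate direction set: normal-matrix condition number ",
         format(kap, digits = 3), " exceeds cap")
  }
  list(basis = B, pinv = t(solve(M, t(B))))
}

#' @keywords internal
as_direction_matrix <- function(dirs) {
  dirs <- as.matrix(dirs)
  if (ncol(dirs) != 3L) {
    if (nrow(dirs) == 3L) dirs <- t(dirs) else stop("directions must be N x 3")
  }
  storage.mode(dirs) <- "double"
  dirs
}
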