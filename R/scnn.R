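#' Configuration of the shell-adaptive spherical network
#'
#' The regressor is a rotation-invariant spherical convolutional network.
#' Per-shell SH coefficient blocks enter as channels of one spherical
#' signal; a dynamic head conditioned on the shell-availability code
#' generates a multiplicative scaling of the first convolution kernel; a
#' cascade of spectral spherical convolutions (learned per-degree
#' filters, scale-only fragment gains) and channel-wise tensor-product
#' activations — pointwise squaring on an exact quadrature grid,
#' projected back to the stage bandlimit and normalized by the sample's
#' fragment norm — descends to degree 0. The rotation-invariant features
#' (final degree-0 coefficients concatenated with the per-stage fragment
#' norms, which are invariant by Parseval) are passed through fully
#' connected layers to the fraction in \[0, 1\].
#'
#' `bandlimits` follow the reference architecture (L0..L5) =
#' (20, 10, 10, 6, 3, 1) with channel widths (1, 20, 22, 24, 26, 28);
#' `channels[1]` counts channels per shell, so the true input width is
#' `K * channels[1]`. Degrees are capped at `lmax` (the SH expansion
#' degree of the input, 8) and floored to even parity, since the
#' antipodally symmetric basis carries even degrees only. Activations sit
#' after every convolution except the first and last (three of them in
#' the 5-convolution reference layout).
#'
#' @param K number of training shells.
#' @param lmax input SH degree.
#' @param bandlimits per-stage bandlimits, length = number of convolutions
#'   plus one (the first entry is the input resolution).
#' @param channels widths, same length as `bandlimits`.
#' @param l1_strength L1 penalty on convolution weights.
#' @param fc_sizes hidden widths of the fully connected head.
#' @param head_hidden hidden width of the dynamic head.
#' @export
scnn_config <- function(K = 3L, lmax = 8L,
                        bandlimits = c(20L, 10L, 10L, 6L, 3L, 1L),
                        channels = c(1L, 20L, 22L, 24L, 26L, 28L),
                        l1_strength = 1e-5,
                        fc_sizes = c(64L, 32L),
                        head_hidden = 16L) {
  if (length(bandlimits) != length(channels)) {
    stop("bandlimits and channels must have equal length")
  }
  if (is.unsorted(rev(bandlimits))) stop("bandlimits must be non-increasing")
  if (is.unsorted(channels)) stop("channels must be non-decreasing")
  structure(list(K = as.integer(K), lmax = as.integer(lmax),
                 bandlimits = as.integer(bandlimits),
                 channels = as.integer(channels),
                 l1_strength = l1_strength,
                 fc_sizes = as.integer(fc_sizes),
                 head_hidden = as.integer(head_hidden)),
            class = "scnn_config")
}

#' @keywords internal
even_cap <- function(band, lmax) {
  l <- min(band, lmax)
  as.integer(l - l %% 2L)
}

# Build the static execution plan: per-conv degree caps, activation
# placement, invariant-feature layout, and precomputed quadrature/basis
# matrices for the tensor-product activations.
#' @keywords internal
scnn_plan <- function(config) {
  nb <- length(config$bandlimits)
  n_conv <- nb - 1L
  caps <- vapply(seq_len(n_conv) + 1L,
                 function(i) even_cap(config$bandlimits[i], config$lmax),
                 integer(1))
  L_in <- c(even_cap(config$bandlimits[1L], config$lmax), caps[-n_conv])
  cin <- c(config$K * config$channels[1L], config$channels[2:n_conv])
  cout <- config$channels[-1L]
  acts <- if (n_conv > 2L) seq(2L, n_conv - 1L) else integer(0)
  stages <- vector("list", n_conv)
  lmax_in <- even_cap(config$bandlimits[1L], config$lmax)
  ndeg_in <- length(seq(0L, config$lmax, by = 2L))   # skip norms use the full input
  # invariants: final degree-0 coefficients, per-activation fragment norms,
  # plus a skip connection carrying the input's per-shell fragment norms
  n_inv <- cout[n_conv] + config$K * ndeg_in
  for (i in seq_len(n_conv)) {
    st <- list(C_in = cin[i], C_out = cout[i],
               L_in = L_in[i], L_out = caps[i],
               dynamic = (i == 1L), act = i %in% acts)
    if (st$act) {
      L <- st$L_out
      # quadrature exact for (squared signal of degree L) * (basis of degree L)
      deg <- 3L * L
      nth <- as.integer(ceiling((deg + 1) / 2))
      nph <- as.integer(deg + 1L)
      q <- sphere_quadrature(max(nth, 2L), max(nph, 4L))
      Bg <- sh_basis(q$dirs, L)
      st$act_B <- t(Bg)                              # ncoef x npts
      st$act_P <- q$weights * Bg                     # npts x ncoef
      st$n_deg <- length(seq(0L, L, by = 2L))
      n_inv <- n_inv + st$n_deg * st$C_out           # concatenated norms
    }
    stages[[i]] <- st
  }
  list(stages = stages, n_conv = n_conv, L_input = lmax_in,
       L_final = caps[n_conv], n_fin = cout[n_conv], n_inv = n_inv)
}

#' @keywords internal
degree_indices <- function(L) {
  out <- list()
  off <- 0L
  for (l in seq(0L, L, by = 2L)) {
    out[[as.character(l)]] <- off + seq_len(2L * l + 1L)
    off <- off + 2L * l + 1L
  }
  out
}

#' Initialize spherical-network parameters
#'
#' @param config an [scnn_config()].
#' @param seed integer RNG seed for the weight draw.
#' @return list with `params` (weights, including the fixed invariant
#'   standardization `inv_scale`), `state` (unused; retained for
#'   checkpoint layout), `config`, `fc_def`.
#' @export
scnn_init <- function(config, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  plan <- scnn_plan(config)
  conv <- vector("list", plan$n_conv)
  gain <- vector("list", plan$n_conv)
  for (i in seq_len(plan$n_conv)) {
    st <- plan$stages[[i]]
    degs <- seq(0L, min(st$L_in, st$L_out), by = 2L)
    W <- lapply(degs, function(l) {
      matrix(stats::rnorm(st$C_in * st$C_out, sd = sqrt(2 / st$C_in)),
             st$C_in, st$C_out)
    })
    names(W) <- as.character(degs)
    conv[[i]] <- list(W = W, b0 = numeric(st$C_out))
    gain[[i]] <- matrix(1, length(seq(0L, st$L_out, by = 2L)), st$C_out)
  }
  st1 <- plan$stages[[1L]]
  head <- list(
    Wh = matrix(stats::rnorm(config$K * config$head_hidden, sd = 0.5),
                config$K, config$head_hidden),
    bh = numeric(config$head_hidden),
    Ws = matrix(0, config$head_hidden, st1$C_in * st1$C_out),
    bs = numeric(st1$C_in * st1$C_out))
  fc <- mlp_init(c(plan$n_inv, config$fc_sizes, 1L))
  params <- list(conv = conv, bn_gain = gain, head = head,
                 inv_scale = rep(1, plan$n_inv), fc = fc$params)
  list(params = params, state = list(), config = config,
       fc_def = fc[c("sizes", "use_bn", "dropout")])
}

#' @keywords internal
head_scaling <- function(head, code) {
  h <- tanh(drop(as.numeric(code) %*% head$Wh) + head$bh)
  s <- drop(h %*% head$Ws) + head$bs
  list(scale = 1 + s, h = h)
}

#' Generate the first-layer kernel from a shell code
#'
#' The dynamic head maps the K-bit shell-availability code through a
#' two-layer perceptron to a multiplicative scaling matrix applied to the
#' learned base kernel of the first spherical convolution. The mapping is
#' deterministic: identical codes give identical kernels.
#'
#' @param code a [shell_code()].
#' @param params SCNN parameter tree (from [scnn_init()] or a checkpoint).
#' @return list of per-degree first-layer kernels.
#' @export
dynamic_first_layer <- function(code, params) {
  code <- shell_code(code)
  hs <- head_scaling(params$head, code)
  W1 <- params$conv[[1L]]$W
  S <- matrix(hs$scale, nrow(W1[[1L]]), ncol(W1[[1L]]))
  lapply(W1, function(w) w * S)
}

# Forward pass. X: (B, ncoef(lmax), K*channels_per_shell) array of SH
# feature blocks (already shell-code zeroed). Every operation is a pure
# function of (weights, input, code): there are no running statistics, so
# repeated evaluation is bit-identical. Returns prediction in [0,1] plus
# caches for backprop when train = TRUE.
#' @keywords internal
scnn_forward <- function(params, state, config, X, code, train = FALSE,
                         plan = NULL, fc_def = NULL, ...) {
  if (is.null(plan)) plan <- scnn_plan(config)
  if (is.null(fc_def)) {
    fc_def <- list(sizes = c(plan$n_inv, config$fc_sizes, 1L),
                   use_bn = FALSE, dropout = 0)
  }
  if (any(!is.finite(X))) {
    bad <- which(apply(!is.finite(X), 1L, any))[1L]
    stop("non-finite features at voxel index ", bad)
  }
  B <- dim(X)[1L]
  hs <- head_scaling(params$head, code)
  caches <- vector("list", plan$n_conv)
  inv_norms <- list()
  A <- X
  for (i in seq_len(plan$n_conv)) {
    st <- plan$stages[[i]]
    degs <- seq(0L, min(st$L_in, st$L_out), by = 2L)
    idx_in <- degree_indices(st$L_in)
    idx_out <- degree_indices(st$L_out)
    S <- if (st$dynamic) matrix(hs$scale, st$C_in, st$C_out) else NULL
    Y <- array(0, c(B, sh_ncoef(st$L_out), st$C_out))
    conv_cache <- list(Xl = list(), Keff = list())
    for (l in degs) {
      k <- as.character(l)
      Keff <- if (st$dynamic) params$conv[[i]]$W[[k]] * S else params$conv[[i]]$W[[k]]
      Xl <- matrix(A[, idx_in[[k]], , drop = FALSE], ncol = st$C_in)
      Yl <- Xl %*% Keff
      if (l == 0L) Yl <- sweep(Yl, 2L, params$conv[[i]]$b0, `+`)
      Y[, idx_out[[k]], ] <- array(Yl, c(B, 2L * l + 1L, st$C_out))
      conv_cache$Xl[[k]] <- Xl
      conv_cache$Keff[[k]] <- Keff
    }
    # restricted normalization: fragments scaled (never translated) by
    # learnable per-degree, per-channel gains
    degs_out <- seq(0L, st$L_out, by = 2L)
    conv_cache$Y_raw <- Y
    for (di in seq_along(degs_out)) {
      ii <- idx_out[[as.character(degs_out[di])]]
      Y[, ii, ] <- sweep(Y[, ii, , drop = FALSE], 3L,
                         params$bn_gain[[i]][di, ], `*`)
    }
    A <- Y
    if (st$act) {
      # channel-wise tensor-product activation: pointwise square on an
      # exact quadrature grid, projected back and divided by the sample's
      # fragment norm, so the map is homogeneous of degree 1
      # (scale-stable), exactly band-limited and exactly equivariant
      M <- matrix(aperm(A, c(1L, 3L, 2L)), ncol = dim(A)[2L])  # (B*C) x ncoef
      G <- M %*% st$act_B
      H <- G * G
      cnorm <- sqrt(rowSums(M^2) + 1e-8)
      Aout <- (H %*% st$act_P) / cnorm
      conv_cache$act <- list(M = M, G = G, cnorm = cnorm, Yact = Aout)
      A <- aperm(array(Aout, c(B, st$C_out, ncol(Aout))), c(1L, 3L, 2L))
      # invariant features: per-fragment norms of the activation output
      # (rows of Aout are (voxel, channel) pairs, voxel fastest)
      nrm <- matrix(0, B, st$n_deg * st$C_out)
      nrm_bc <- matrix(0, nrow(Aout), st$n_deg)
      for (di in seq_along(degs_out)) {
        ii <- idx_out[[as.character(degs_out[di])]]
        nv <- sqrt(rowSums(Aout[, ii, drop = FALSE]^2) + 1e-8)
        nrm_bc[, di] <- nv
        nrm[, (di - 1L) * st$C_out + seq_len(st$C_out)] <- nv
      }
      conv_cache$inv_nrm_bc <- nrm_bc
      inv_norms[[length(inv_norms) + 1L]] <- nrm
    }
    caches[[i]] <- conv_cache
  }
  # skip connection: fragment norms of the raw input, per shell and degree
  ndeg_in <- (dim(X)[2L] > 0) * length(seq(0L, config$lmax, by = 2L))
  idx_full <- degree_indices(config$lmax)
  Xm <- matrix(aperm(X, c(1L, 3L, 2L)), ncol = dim(X)[2L])
  in_nrm <- matrix(0, nrow(Xm), ndeg_in)
  for (di in seq_len(ndeg_in)) {
    ii <- idx_full[[di]]
    in_nrm[, di] <- sqrt(rowSums(Xm[, ii, drop = FALSE]^2) + 1e-8)
  }
  in_nrm <- matrix(aperm(array(in_nrm, c(B, dim(X)[3L], ndeg_in)),
                         c(1L, 3L, 2L)), nrow = B)
  inv_raw <- cbind(matrix(A[, 1L, ], B, plan$n_fin),
                   do.call(cbind, c(inv_norms, list(matrix(0, B, 0)))),
                   in_nrm)
  inv <- sweep(inv_raw, 2L, params$inv_scale, `*`)
  fcres <- mlp_forward(fc_def, params$fc, inv, train = train)
  z <- drop(fcres$out)
  y <- squash01(z)
  list(pred = as.numeric(y), z = z, inv = inv, inv_raw = inv_raw,
       state = state,
       cache = if (train) list(conv = caches, fc = fcres$cache,
                               head = hs, X = X, dydz = attr(y, "dydz"),
                               plan = plan, fc_def = fc_def, code = code)
          else NULL)
}

#' @keywords internal
scnn_backward <- function(params, config, fwd, dpred) {
  cache <- fwd$cache
  plan <- cache$plan
  B <- length(dpred)
  dz <- dpred * cache$dydz
  fcb <- mlp_backward(cache$fc_def, params$fc, cache$fc, matrix(dz, B, 1L))
  dinv <- sweep(fcb$dX, 2L, params$inv_scale, `*`)   # back through standardization
  grads <- list(conv = vector("list", plan$n_conv),
                bn_gain = vector("list", plan$n_conv),
                head = tree_zeros_like(params$head),
                inv_scale = numeric(plan$n_inv),     # fixed calibration, no update
                fc = fcb$grads)
  # split the invariant gradient: final degree-0 block, then per-act norms
  dA <- array(0, c(B, sh_ncoef(plan$L_final), plan$n_fin))
  dA[, 1L, ] <- dinv[, seq_len(plan$n_fin), drop = FALSE]
  off <- plan$n_fin
  dnorm_by_stage <- vector("list", plan$n_conv)
  for (i in seq_len(plan$n_conv)) {
    st <- plan$stages[[i]]
    if (st$act) {
      w <- st$n_deg * st$C_out
      dnorm_by_stage[[i]] <- dinv[, off + seq_len(w), drop = FALSE]
      off <- off + w
    }
  }
  for (i in rev(seq_len(plan$n_conv))) {
    st <- plan$stages[[i]]
    cc <- cache$conv[[i]]
    idx_out <- degree_indices(st$L_out)
    degs_out <- seq(0L, st$L_out, by = 2L)
    if (st$act) {
      ncoef_out <- dim(dA)[2L]
      dOutM <- matrix(aperm(dA, c(1L, 3L, 2L)), ncol = ncoef_out)
      # gradient of the invariant norms taken from this stage's output;
      # rows of the activation matrices are (voxel, channel) pairs
      dn <- dnorm_by_stage[[i]]
      for (di in seq_along(degs_out)) {
        ii <- idx_out[[as.character(degs_out[di])]]
        cols <- (di - 1L) * st$C_out + seq_len(st$C_out)
        ratio <- as.vector(dn[, cols, drop = FALSE]) / cc$inv_nrm_bc[, di]
        dOutM[, ii] <- dOutM[, ii, drop = FALSE] +
          ratio * cc$act$Yact[, ii, drop = FALSE]
      }
      # back through the normalized squaring activation
      cn <- cc$act$cnorm
      dG <- 2 * cc$act$G * ((dOutM / cn) %*% t(st$act_P))
      dM <- dG %*% t(st$act_B)
      dLd_c <- -rowSums(dOutM * cc$act$Yact) / cn
      dM <- dM + (dLd_c / cn) * cc$act$M
      dA <- aperm(array(dM, c(B, st$C_out, ncol(dM))), c(1L, 3L, 2L))
    }
    # back through the fragment gains
    dgain <- matrix(0, length(degs_out), st$C_out)
    dY <- dA
    for (di in seq_along(degs_out)) {
      ii <- idx_out[[as.character(degs_out[di])]]
      dfrag <- dA[, ii, , drop = FALSE]
      yraw <- cc$Y_raw[, ii, , drop = FALSE]
      dgain[di, ] <- apply(dfrag * yraw, 3L, sum)
      dY[, ii, ] <- sweep(dfrag, 3L, params$bn_gain[[i]][di, ], `*`)
    }
    grads$bn_gain[[i]] <- dgain
    # back through the per-degree convolution
    degs <- seq(0L, min(st$L_in, st$L_out), by = 2L)
    idx_in <- degree_indices(st$L_in)
    dX <- array(0, c(B, sh_ncoef(st$L_in), st$C_in))
    db0 <- numeric(st$C_out)
    dKeff <- list()
    for (l in degs) {
      k <- as.character(l)
      dYl <- matrix(dY[, idx_out[[k]], , drop = FALSE], ncol = st$C_out)
      dKeff[[k]] <- crossprod(cc$Xl[[k]], dYl)
      dXl <- tcrossprod(dYl, cc$Keff[[k]])
      dX[, idx_in[[k]], ] <- array(dXl, c(B, 2L * l + 1L, st$C_in))
      if (l == 0L) db0 <- colSums(dYl)
    }
    if (st$dynamic) {
      S <- matrix(cache$head$scale, st$C_in, st$C_out)
      gW <- lapply(names(dKeff), function(k) dKeff[[k]] * S)
      names(gW) <- names(dKeff)
      dS <- Reduce(`+`, lapply(names(dKeff), function(k) {
        dKeff[[k]] * params$conv[[i]]$W[[k]]
      }))
      dsvec <- as.numeric(dS)
      h <- cache$head$h
      grads$head$bs <- dsvec
      grads$head$Ws <- outer(h, dsvec)
      dh <- drop(params$head$Ws %*% dsvec) * (1 - h^2)
      grads$head$bh <- dh
      grads$head$Wh <- outer(as.numeric(cache$code), dh)
    } else {
      gW <- dKeff
    }
    grads$conv[[i]] <- list(W = gW, b0 = db0)
    dA <- dX
  }
  grads
}

#' L1 penalty over convolution weights
#'
#' The regularization term is `l1_strength * sum(|w|)` over spherical
#' convolution weights only — the fully connected head and the dynamic
#' head are excluded.
#'
#' @param params SCNN parameter tree.
#' @param config the [scnn_config()].
#' @export
scnn_l1_penalty <- function(params, config) {
  config$l1_strength *
    sum(vapply(params$conv,
               function(cv) tree_sum(function(w) sum(abs(w)), cv$W),
               numeric(1)))
}

#' @keywords internal
scnn_add_l1_grad <- function(grads, params, config) {
  for (i in seq_along(params$conv)) {
    for (k in names(params$conv[[i]]$W)) {
      grads$conv[[i]]$W[[k]] <- grads$conv[[i]]$W[[k]] +
        config$l1_strength * sign(params$conv[[i]]$W[[k]])
    }
  }
  grads
}
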