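# Small hand-rolled neural-network core: parameter trees (nested lists of
# numeric arrays), Adam, and a dense multilayer perceptron with exact
# backpropagation. Kept deliberately minimal — the models in this package
# are small enough that explicit gradients are simpler and more auditable
# than an autodiff dependency.

#' @keywords internal
tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

#' @keywords internal
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

#' @keywords internal
tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

#' @keywords internal
tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) tree_sum(f, x), numeric(1))) else f(a)
}

#' @keywords internal
adam_state <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# One Adam step. `mask` (same tree shape, 0/1) freezes parameters where 0.
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, mask = NULL) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  if (!is.null(mask)) upd <- tree_map2(`*`, upd, mask)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# FNV-1a hash of a parameter subtree (used to verify frozen-parameter
# contracts during fine-tuning).
#' @keywords internal
param_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  prime <- 16777619
  for (b in raw) {
    # xor only touches the low byte (b < 256); the 32-bit modular multiply
    # is split so every intermediate stays below 2^53 (exact in doubles)
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * prime + ((h1 * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ---- dense multilayer perceptron --------------------------------------------

# sizes: full layer widths including input and output, e.g. c(96, 48, 24, 1).
# Hidden layers use ReLU, optionally batch normalization (exact backward)
# and dropout; the output layer is linear (squashing applied by callers).
#' @keywords internal
mlp_init <- function(sizes, use_bn = FALSE, dropout = 0) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    # the output layer starts at zero so the initial prediction is a
    # constant — optimization then grows feature dependence in, which is
    # markedly more stable than starting from random input-dependent output
    sd_i <- if (i == L) 0 else sqrt(2 / sizes[i])
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], sd = sd_i),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  params <- list(W = W, b = b)
  if (use_bn) {
    params$gamma <- lapply(sizes[2:L], function(n) rep(1, n))
    params$beta <- lapply(sizes[2:L], function(n) numeric(n))
  }
  state <- if (use_bn) {
    list(mean = lapply(sizes[2:L], function(n) numeric(n)),
         var = lapply(sizes[2:L], function(n) rep(1, n)))
  } else NULL
  list(params = params, state = state, sizes = sizes,
       use_bn = use_bn, dropout = dropout)
}

#' @keywords internal
mlp_forward <- function(mlp, params, X, train = FALSE, state = NULL,
                        momentum = 0.9, bn_eps = 1e-5) {
  L <- length(params$W)
  cache <- list(inputs = vector("list", L), bn = vector("list", L),
                drop = vector("list", L), relu = vector("list", L))
  A <- X
  for (i in seq_len(L)) {
    cache$inputs[[i]] <- A
    Z <- sweep(A %*% params$W[[i]], 2L, params$b[[i]], `+`)
    if (i < L) {
      if (mlp$use_bn) {
        if (train) {
          mu <- colMeans(Z)
          zc <- sweep(Z, 2L, mu)
          va <- colMeans(zc^2)
          state$mean[[i]] <- momentum * state$mean[[i]] + (1 - momentum) * mu
          state$var[[i]] <- momentum * state$var[[i]] + (1 - momentum) * va
        } else {
          mu <- state$mean[[i]]; va <- state$var[[i]]
          zc <- sweep(Z, 2L, mu)
        }
        inv <- 1 / sqrt(va + bn_eps)
        Zh <- sweep(zc, 2L, inv, `*`)
        cache$bn[[i]] <- list(zc = zc, inv = inv, zh = Zh, train = train)
        Z <- sweep(sweep(Zh, 2L, params$gamma[[i]], `*`), 2L,
                   params$beta[[i]], `+`)
      }
      cache$relu[[i]] <- Z > 0
      A <- Z * cache$relu[[i]]
      if (train && mlp$dropout > 0) {
        mask <- (matrix(stats::runif(length(A)), nrow(A)) >= mlp$dropout) /
          (1 - mlp$dropout)
        cache$drop[[i]] <- mask
        A <- A * mask
      }
    } else {
      A <- Z
    }
  }
  list(out = A, cache = cache, state = state)
}

#' @keywords internal
mlp_backward <- function(mlp, params, cache, dOut) {
  L <- length(params$W)
  g <- list(W = vector("list", L), b = vector("list", L))
  if (mlp$use_bn) {
    g$gamma <- vector("list", L - 1L); g$beta <- vector("list", L - 1L)
  }
  dA <- dOut
  for (i in rev(seq_len(L))) {
    if (i < L) {
      if (!is.null(cache$drop[[i]])) dA <- dA * cache$drop[[i]]
      dZ <- dA * cache$relu[[i]]
      if (mlp$use_bn) {
        bn <- cache$bn[[i]]
        g$gamma[[i]] <- colSums(dZ * bn$zh)
        g$beta[[i]] <- colSums(dZ)
        dZh <- sweep(dZ, 2L, params$gamma[[i]], `*`)
        if (bn$train) {
          n <- nrow(dZh)
          # exact batch-norm backward through batch mean and variance
          dvar <- colSums(dZh * bn$zc) * (-0.5) * bn$inv^3
          dmu <- -bn$inv * colSums(dZh) + dvar * (-2 / n) * colSums(bn$zc)
          dZ <- sweep(dZh, 2L, bn$inv, `*`) +
            sweep(bn$zc, 2L, 2 * dvar / n, `*`) +
            matrix(dmu / n, nrow = n, ncol = length(dmu), byrow = TRUE)
        } else {
          dZ <- sweep(dZh, 2L, bn$inv, `*`)
        }
      }
    } else {
      dZ <- dA
    }
    A <- cache$inputs[[i]]
    g$W[[i]] <- crossprod(A, dZ)
    g$b[[i]] <- colSums(dZ)
    dA <- tcrossprod(dZ, params$W[[i]])
  }
  list(grads = g, dX = dA)
}

# Output squashing to [0, 1]: a slightly over-ranged logistic clipped at the
# box, so exact 0 and 1 are attainable.
#' @keywords internal
squash01 <- function(z) {
  s <- 1 / (1 + exp(-z))
  y <- pmin(1, pmax(0, 1.05 * s - 0.025))
  attr(y, "dydz") <- ifelse(y > 0 & y < 1, 1.05 * s * (1 - s), 0)
  y
}
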