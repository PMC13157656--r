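#' Configuration of the fully connected ANN baseline
#'
#' A 4-layer fully connected network (input, two hidden layers of sizes
#' `N_b/2` and `N_b/4`, one output unit) with batch normalization and
#' dropout, taking the normalized per-measurement signal vector directly.
#' It has no rotation invariance and no shell-adaptivity by construction;
#' it serves as the reference learned baseline.
#'
#' @param N_b input vector length (96 for a 90-direction single-shell
#'   acquisition with its b0 reference; for the phantom's three-shell
#'   layout the mean-b0 entry plus 3 x 90 directions give 271).
#' @param dropout dropout probability on hidden layers.
#' @export
ann_config <- function(N_b, dropout = 0.1) {
  N_b <- as.integer(N_b)
  structure(list(N_b = N_b,
                 sizes = c(N_b, N_b %/% 2L, N_b %/% 4L, 1L),
                 dropout = dropout, use_bn = TRUE),
            class = "ann_config")
}

#' Configuration of the SHORE-coefficient regressor (Deep SHORE baseline)
#'
#' A 4-layer fully connected network over the 50 SHORE coefficients
#' (radial order 6), hidden sizes 100 and 50.
#'
#' @param dropout dropout probability.
#' @export
shore_fcn_config <- function(dropout = 0.1) {
  structure(list(N_b = 50L, sizes = c(50L, 100L, 50L, 1L),
                 dropout = dropout, use_bn = TRUE),
            class = "shore_fcn_config")
}

#' @keywords internal
code_id <- function(code) sum(as.integer(code) * 2^(seq_along(code) - 1L))

#' @keywords internal
default_feature_contract <- function(model_type, config,
                                     training_shells = c(1000, 2000, 3000)) {
  list(model_type = model_type,
       basis = "real symmetric SH, even degrees, degree-ascending / m = -l..l",
       normalization = "signal / mean(b0), clipped to [1e-6, 1.5]",
       shells = training_shells,
       lmax = if (inherits(config, "scnn_config")) config$lmax else NA_integer_,
       N_b = if (!inherits(config, "scnn_config")) config$N_b else NA_integer_)
}

#' Assemble a model checkpoint
#' @keywords internal
fw_checkpoint <- function(model_type, weights, state, config, fc_def = NULL,
                          feature_contract, training_meta = list()) {
  structure(list(version = 1L, model_type = model_type, weights = weights,
                 state = state, config = config, fc_def = fc_def,
                 feature_contract = feature_contract,
                 training_meta = training_meta),
            class = "fw_checkpoint")
}

#' Save / load checkpoints
#'
#' The checkpoint archive carries weights, configuration, the feature
#' contract (basis ordering and normalization descriptor) and training
#' metadata. Loading refuses a checkpoint whose feature contract does not
#' match the caller's expectation.
#'
#' @param checkpoint an `fw_checkpoint`.
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "fw_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expected_contract optional contract list to enforce on load.
#' @export
load_checkpoint <- function(path, expected_contract = NULL) {
  ck <- readRDS(path)
  if (!inherits(ck, "fw_checkpoint") || is.null(ck$version)) {
    stop("not a model checkpoint: ", path)
  }
  if (!is.null(expected_contract)) check_contract(ck, expected_contract)
  ck
}

#' @keywords internal
check_contract <- function(checkpoint, expected) {
  fc <- checkpoint$feature_contract
  for (key in names(expected)) {
    if (!identical(fc[[key]], expected[[key]])) {
      stop("feature-contract mismatch on '", key, "': checkpoint has ",
           paste(format(fc[[key]]), collapse = ","), ", caller expects ",
           paste(format(expected[[key]]), collapse = ","))
    }
  }
  invisible(TRUE)
}

#' @export
print.fw_checkpoint <- function(x, ...) {
  cat("fw_checkpoint:", x$model_type, "model")
  if (!is.null(x$training_meta$best_epoch)) {
    cat(", best epoch", x$training_meta$best_epoch,
        "val RMSE", signif(x$training_meta$val_rmse_best, 4))
  }
  cat("\n")
  invisible(x)
}

#' Predict free-water fractions with the spherical network
#'
#' @param features a `shell_feature_set` (code-zeroing is enforced) or a
#'   V x C x K array plus an explicit `code`.
#' @param checkpoint an `fw_checkpoint` of model type `"scnn"`.
#' @param code required when `features` is a bare array.
#' @param batch_size evaluation chunk size.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
forward_scnn <- function(features, checkpoint, code = NULL,
                         batch_size = 4096L) {
  if (checkpoint$model_type != "scnn") stop("checkpoint is not an scnn model")
  if (inherits(features, "shell_feature_set")) {
    features <- apply_shell_code(features, features$code)
    code <- features$code
    X <- features$coeffs
  } else {
    X <- features
    if (is.null(code)) stop("code required for bare feature arrays")
    code <- shell_code(code)
    for (k in which(code == 0L)) X[, , k] <- 0
  }
  check_contract(checkpoint,
                 list(lmax = as.integer(round(sqrt(8 * dim(X)[2L] + 1) / 2 - 1.5))))
  plan <- scnn_plan(checkpoint$config)
  V <- dim(X)[1L]
  out <- numeric(V)
  for (start in seq(1L, V, by = batch_size)) {
    idx <- start:min(V, start + batch_size - 1L)
    fw <- scnn_forward(checkpoint$weights, checkpoint$state,
                       checkpoint$config, X[idx, , , drop = FALSE], code,
                       train = FALSE, plan = plan, fc_def = checkpoint$fc_def)
    out[idx] <- fw$pred
  }
  out
}

#' Predict free-water fractions with the ANN baseline
#'
#' @param signal_vector normalized per-measurement input vector of length
#'   `N_b`, or a V x N_b matrix.
#' @param checkpoint an `fw_checkpoint` of model type `"ann"`.
#' @export
forward_ann <- function(signal_vector, checkpoint) {
  if (checkpoint$model_type != "ann") stop("checkpoint is not an ann model")
  X <- if (is.null(dim(signal_vector))) matrix(signal_vector, nrow = 1L)
    else as.matrix(signal_vector)
  if (ncol(X) != checkpoint$config$N_b) {
    stop("contract error: input length ", ncol(X), " != N_b = ",
         checkpoint$config$N_b)
  }
  mlp_def <- checkpoint$fc_def
  r <- mlp_forward(mlp_def, checkpoint$weights, X, train = FALSE,
                   state = checkpoint$state)
  as.numeric(squash01(drop(r$out)))
}

#' Predict free-water fractions from SHORE coefficients
#'
#' @param features a `shore_features` object, or a V x 50 coefficient
#'   matrix.
#' @param checkpoint an `fw_checkpoint` of model type `"shore"`.
#' @export
forward_shore_fcn <- function(features, checkpoint) {
  if (checkpoint$model_type != "shore") stop("checkpoint is not a shore model")
  X <- if (inherits(features, "shore_features")) matrix(features$coeffs, nrow = 1L)
    else as.matrix(features)
  if (ncol(X) != 50L) stop("contract error: expected 50 SHORE coefficients, got ", ncol(X))
  r <- mlp_forward(checkpoint$fc_def, checkpoint$weights, X, train = FALSE,
                   state = checkpoint$state)
  as.numeric(squash01(drop(r$out)))
}
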