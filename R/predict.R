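#' Estimate a free-water fraction map from a DWI series
#'
#' The learned single/multi-shell estimator: derives the
#' shell-availability code from the acquisition (optionally remapping a
#' sub-1500 s/mm^2 shell onto the 1000 s/mm^2 training shell first),
#' normalizes the signal, builds the model's input representation and
#' evaluates the checkpoint. This is the route for single-shell data,
#' where the nonlinear multi-shell fit ([fit_fwdti()]) is ill-posed.
#'
#' @param checkpoint an `fw_checkpoint`.
#' @param signal 4D array or V x N matrix of DWI intensities.
#' @param scheme a [gradient_scheme()].
#' @param mask optional logical array/vector; excluded voxels get f = 0.
#' @param remap remap the lowest sub-1500 shell to the training shell
#'   before feature extraction (default TRUE).
#' @return list with `f` (map, same spatial shape as the input), `code`
#'   (the shell code used), `scheme` (possibly remapped), `s0`.
#' @export
predict_fw <- function(checkpoint, signal, scheme, mask = NULL, remap = TRUE) {
  stopifnot(inherits(checkpoint, "fw_checkpoint"))
  dims <- NULL
  if (length(dim(signal)) == 4L) {
    dims <- dim(signal)[1:3]
    signal <- matrix(signal, prod(dims), dim(signal)[4L])
  }
  signal <- as.matrix(signal)
  shells <- checkpoint$feature_contract$shells
  if (remap) {
    rm <- remap_scheme_to_training(signal, scheme, target = shells[1L])
    signal <- rm$signal; scheme <- rm$scheme
  }
  code <- shell_code_for(scheme, shells)
  ns <- normalize_signal(signal, scheme)
  V <- nrow(signal)
  keep <- if (is.null(mask)) rep(TRUE, V) else as.logical(as.vector(mask))
  keep <- keep & as.vector(ns$valid)
  f <- numeric(V)
  if (checkpoint$model_type == "scnn") {
    feats <- build_feature_set(ns$normalized[keep, , drop = FALSE], scheme,
                               code = code, training_shells = shells,
                               max_degree = checkpoint$config$lmax)
    f[keep] <- forward_scnn(feats, checkpoint)
  } else if (checkpoint$model_type == "ann") {
    seg_len <- checkpoint$training_meta$segments
    X <- matrix(0, sum(keep), checkpoint$config$N_b)
    X[, 1L] <- rowMeans(ns$normalized[keep, scheme$b0_indices, drop = FALSE])
    off <- 1L
    for (k in seq_along(shells)) {
      w <- seg_len[[paste0("shell", shells[k])]]
      if (code[k] == 1L) {
        hit <- which(abs(scheme$nominal_bvals - shells[k]) <= scheme$shell_tolerance)
        idx <- scheme$shells[[hit[1L]]]
        if (length(idx) != w) {
          stop("contract error: shell ", shells[k], " has ", length(idx),
               " directions but the checkpoint expects ", w)
        }
        X[, off + seq_len(w)] <- ns$normalized[keep, idx, drop = FALSE]
      }
      off <- off + w
    }
    f[keep] <- forward_ann(X, checkpoint)
  } else if (checkpoint$model_type == "shore") {
    sf <- shore_fit_field(ns$normalized[keep, , drop = FALSE], scheme)
    f[keep] <- forward_shore_fcn(sf$coeffs, checkpoint)
  } else stop("unknown model type in checkpoint")
  if (!is.null(dims)) f <- array(f, dims)
  list(f = f, code = code, scheme = scheme, s0 = ns$s0)
}
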