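#' Training plan
#'
#' Describes a training (or fine-tuning) run: RMSE loss, a distribution
#' over the `2^K - 1` shell-availability codes used for per-batch shell
#' dropout, Adam settings, split and early-stopping policy. With
#' `fine_tune_scope = "fc_only"` every parameter outside the fully
#' connected head — including the dynamic head — is frozen.
#'
#' @param epochs number of passes over the training voxels.
#' @param batch_size voxels per batch.
#' @param lr Adam learning rate.
#' @param val_fraction fraction of voxel groups held out for validation
#'   (the split is by group, never by measurement).
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed RNG seed controlling the split, batch order, shell-code
#'   draws, dropout and weight init.
#' @param config_sampler list with `codes` (list of [shell_code()]) and
#'   `probs` (summing to 1); default: uniform over all valid codes for
#'   `K = 3`.
#' @param fine_tune_scope `"all"` or `"fc_only"`.
#' @export
training_plan <- function(epochs = 20L, batch_size = 256L, lr = 1e-3,
                          val_fraction = 0.1, patience = 10L, seed = 1L,
                          config_sampler = NULL,
                          fine_tune_scope = c("all", "fc_only"),
                          lr_schedule = c("cosine", "constant")) {
  fine_tune_scope <- match.arg(fine_tune_scope)
  lr_schedule <- match.arg(lr_schedule)
  if (is.null(config_sampler)) {
    codes <- all_shell_codes(3L)
    config_sampler <- list(codes = codes,
                           probs = rep(1 / length(codes), length(codes)))
  }
  if (abs(sum(config_sampler$probs) - 1) > 1e-8) {
    stop("config_sampler probabilities must sum to 1")
  }
  for (cd in config_sampler$codes) shell_code(cd)   # validates support
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction,
                 patience = as.integer(patience), seed = as.integer(seed),
                 loss = "rmse", config_sampler = config_sampler,
                 fine_tune_scope = fine_tune_scope,
                 lr_schedule = lr_schedule),
            class = "training_plan")
}

#' Assemble training data from a phantom
#'
#' Produces the per-model inputs: per-shell SH feature blocks for the
#' spherical network, the concatenated normalized signal vector
#' (mean-b0 entry followed by per-shell direction blocks) for the ANN,
#' and optionally per-configuration SHORE coefficients for the Deep SHORE
#' baseline (the SHORE basis depends on which shells are present, so each
#' of the 7 configurations gets its own fit). Targets default to the
#' phantom ground truth; `target = "silver"` fits the multi-shell
#' free-water model instead.
#'
#' @param phantom a `phantom_volume`.
#' @param training_shells nominal training shells.
#' @param include_shore also compute per-configuration SHORE coefficients
#'   (slow; only needed to train the Deep SHORE baseline).
#' @param target `"truth"` or `"silver"`.
#' @param group_size voxels per validation-split group.
#' @return list of class `fw_dataset`.
#' @export
prepare_training_data <- function(phantom, training_shells = c(1000, 2000, 3000),
                                  include_shore = FALSE,
                                  target = c("truth", "silver"),
                                  group_size = 512L) {
  target <- match.arg(target)
  sc <- phantom$scheme
  V <- if (length(dim(phantom$signal)) == 4L) prod(dim(phantom$signal)[1:3])
    else nrow(phantom$signal)
  sig <- matrix(phantom$signal, V, length(sc$bvals))
  ns <- normalize_signal(sig, sc)
  feats <- build_feature_set(ns$normalized, sc, training_shells = training_shells)

  segments <- list(b0 = 1L)
  ann_cols <- rowMeans(ns$normalized[, sc$b0_indices, drop = FALSE])
  off <- 1L
  tol <- sc$shell_tolerance
  for (k in seq_along(training_shells)) {
    hit <- which(abs(sc$nominal_bvals - training_shells[k]) <= tol)
    idx <- if (length(hit)) sc$shells[[hit[1L]]] else integer(0)
    segments[[paste0("shell", training_shells[k])]] <- off + seq_along(idx)
    if (length(idx)) ann_cols <- cbind(ann_cols, ns$normalized[, idx, drop = FALSE])
    off <- off + length(idx)
  }

  targets <- if (target == "truth") as.vector(phantom$truth_f) else {
    fit_fwdti(sig, sc, d_iso = phantom$d_iso)$f
  }

  shore <- NULL
  if (include_shore) {
    codes <- all_shell_codes(length(training_shells))
    shore <- array(0, c(V, 50L, length(codes)))
    md <- fit_dti_field(sig, sc)$md
    for (cd in codes) {
      keep <- sc$b0_indices
      for (k in which(cd == 1L)) {
        hit <- which(abs(sc$nominal_bvals - training_shells[k]) <= tol)
        keep <- c(keep, sc$shells[[hit[1L]]])
      }
      keep <- sort(keep)
      sub <- gradient_scheme(sc$bvals[keep], sc$bvecs[keep, ],
                             sc$b0_threshold, sc$shell_tolerance)
      sf <- shore_fit_field(ns$normalized[, keep, drop = FALSE], sub, md = md)
      shore[, , code_id(cd)] <- sf$coeffs
    }
  }

  structure(list(features = feats$coeffs, signals = ann_cols,
                 segments = segments, shore = shore, targets = targets,
                 groups = (seq_len(V) - 1L) %/% as.integer(group_size),
                 training_shells = training_shells,
                 N_b = ncol(ann_cols)),
            class = "fw_dataset")
}

#' @keywords internal
model_inputs <- function(model_type, data, idx, code) {
  if (model_type == "scnn") {
    X <- data$features[idx, , , drop = FALSE]
    for (k in which(code == 0L)) X[, , k] <- 0
    X
  } else if (model_type == "ann") {
    X <- data$signals[idx, , drop = FALSE]
    for (k in which(code == 0L)) {
      X[, data$segments[[paste0("shell", data$training_shells[k])]]] <- 0
    }
    X
  } else if (model_type == "shore") {
    if (is.null(data$shore)) stop("dataset lacks SHORE coefficients; rebuild with include_shore = TRUE")
    data$shore[, , code_id(code)][idx, , drop = FALSE]
  } else stop("unknown model type: ", model_type)
}

#' @keywords internal
model_predict_train <- function(model_type, params, state, config, fc_def,
                                X, code, train, plan = NULL,
                                freeze_bn_stat = FALSE) {
  if (model_type == "scnn") {
    scnn_forward(params, state, config, X, code, train = train, plan = plan,
                 fc_def = fc_def, freeze_bn_stat = freeze_bn_stat)
  } else {
    r <- mlp_forward(fc_def, params, X, train = train && !freeze_bn_stat,
                     state = state)
    z <- drop(r$out)
    y <- squash01(z)
    list(pred = as.numeric(y), z = z, state = if (train && !freeze_bn_stat)
      r$state else state,
      cache = list(fc = r$cache, dydz = attr(y, "dydz")))
  }
}

#' @keywords internal
eval_rmse_for_code <- function(model_type, params, state, config, fc_def,
                               data, idx, code, plan = NULL,
                               batch_size = 8192L) {
  n <- length(idx)
  se <- 0
  for (start in seq(1L, n, by = batch_size)) {
    sub <- idx[start:min(n, start + batch_size - 1L)]
    X <- model_inputs(model_type, data, sub, code)
    fw <- model_predict_train(model_type, params, state, config, fc_def, X,
                              code, train = FALSE, plan = plan)
    se <- se + sum((fw$pred - data$targets[sub])^2)
  }
  sqrt(se / n)
}

#' Validation RMSE of a checkpoint on a dataset
#'
#' Deterministic (inference-mode) RMSE against the dataset targets,
#' averaged over the given shell codes.
#'
#' @param checkpoint an `fw_checkpoint`.
#' @param data an `fw_dataset`.
#' @param idx voxel indices (default: all).
#' @param codes list of shell codes (default: all valid for K = 3).
#' @export
checkpoint_rmse <- function(checkpoint, data, idx = NULL, codes = NULL) {
  if (is.null(idx)) idx <- seq_along(data$targets)
  if (is.null(codes)) codes <- all_shell_codes(3L)
  plan <- if (checkpoint$model_type == "scnn") scnn_plan(checkpoint$config) else NULL
  vals <- vapply(codes, function(cd) {
    eval_rmse_for_code(checkpoint$model_type, checkpoint$weights,
                       checkpoint$state, checkpoint$config, checkpoint$fc_def,
                       data, idx, cd, plan)
  }, numeric(1))
  mean(vals)
}

#' Train a free-water regressor with shell-configuration dropout
#'
#' Per batch, a shell code is drawn from the plan's configuration sampler
#' and the absent-shell parts of the input are zeroed before the forward
#' pass, teaching one model every configuration. The RMSE loss drives
#' Adam; the returned checkpoint holds the best validation-RMSE epoch
#' (validation RMSE = inference-mode RMSE averaged over all valid codes,
#' on voxel groups held out from training).
#'
#' @param model `"scnn"`, `"ann"` or `"shore"`.
#' @param data an `fw_dataset` from [prepare_training_data()].
#' @param plan a [training_plan()].
#' @param config model configuration ([scnn_config()], [ann_config()],
#'   [shore_fcn_config()]); defaults are built from the data.
#' @param init optional `fw_checkpoint` to continue from.
#' @param freeze optional 0/1 parameter-tree mask (0 = frozen).
#' @param verbose print per-epoch losses.
#' @return an `fw_checkpoint`; `training_meta` carries the loss history
#'   (`data.frame` epoch / train_rmse / val_rmse), the best epoch, the
#'   shell-code draw histogram and the seed.
#' @export
fw_train <- function(model = c("scnn", "ann", "shore"), data, plan,
                     config = NULL, init = NULL, freeze = NULL,
                     verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(data, "fw_dataset"), inherits(plan, "training_plan"))
  if (any(data$targets < 0 | data$targets > 1)) stop("targets must lie in [0, 1]")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(plan$seed)

  # group-wise split
  grp <- unique(data$groups)
  n_val <- max(1L, round(plan$val_fraction * length(grp)))
  if (n_val >= length(grp)) stop("configuration error: validation split leaves no training groups")
  val_grp <- sample(grp, n_val)
  val_idx <- which(data$groups %in% val_grp)
  train_idx <- which(!(data$groups %in% val_grp))
  if (!length(val_idx)) stop("configuration error: empty validation split")

  if (!is.null(init)) {
    config <- init$config; params <- init$weights; state <- init$state
    fc_def <- init$fc_def
  } else if (model == "scnn") {
    if (is.null(config)) config <- scnn_config()
    net <- scnn_init(config, seed = plan$seed + 1L)
    params <- net$params; state <- net$state; fc_def <- net$fc_def
  } else {
    if (is.null(config)) {
      config <- if (model == "ann") ann_config(data$N_b) else shore_fcn_config()
    }
    m <- mlp_init(config$sizes, use_bn = config$use_bn, dropout = config$dropout)
    params <- m$params; state <- m$state
    fc_def <- m[c("sizes", "use_bn", "dropout")]
  }
  net_plan <- if (model == "scnn") scnn_plan(config) else NULL
  freeze_bn <- !is.null(freeze)   # fc_only scope: keep normalization statistics fixed

  if (is.null(init)) {
    # start the output unit at the mean training target (the output layer
    # weights start at zero, so the initial prediction is exactly that
    # mean): removes the long bias walk Adam would otherwise need
    p0 <- min(0.99, max(0.01, (mean(data$targets[train_idx]) + 0.025) / 1.05))
    z0 <- stats::qlogis(p0)
    if (model == "scnn") {
      params$fc$b[[length(params$fc$b)]][] <- z0
    } else {
      params$b[[length(params$b)]][] <- z0
    }
  }

  # One-off standardization of the invariant features (fixed thereafter,
  # and excluded from gradient updates): brings the degree-0 means and the
  # small high-degree fragment norms onto comparable scales for the head.
  if (model == "scnn" && is.null(init)) {
    calib_idx <- train_idx[seq_len(min(1024L, length(train_idx)))]
    acc <- NULL
    for (cd in plan$config_sampler$codes) {
      X <- model_inputs(model, data, calib_idx, cd)
      fwc <- scnn_forward(params, state, config, X, cd, train = FALSE,
                          plan = net_plan, fc_def = fc_def)
      acc <- rbind(acc, fwc$inv_raw)
    }
    params$inv_scale <- 1 / (apply(acc, 2L, stats::sd) + 1e-6)
  }

  opt <- adam_state(params)
  sampler <- plan$config_sampler
  code_hist <- integer(length(sampler$codes))
  best <- list(params = params, state = state,
               val = mean(vapply(sampler$codes, function(cd) {
                 eval_rmse_for_code(model, params, state, config, fc_def,
                                    data, val_idx, cd, net_plan)
               }, numeric(1))),
               epoch = 0L)
  history <- data.frame(epoch = 0L, train_rmse = NA_real_, val_rmse = best$val)
  since_best <- 0L

  for (epoch in seq_len(plan$epochs)) {
    lr_e <- if (plan$lr_schedule == "cosine") {
      plan$lr * (0.55 + 0.45 * cos(pi * (epoch - 1) / max(1, plan$epochs - 1)))
    } else plan$lr
    perm <- sample(train_idx)
    n_batch <- ceiling(length(perm) / plan$batch_size)
    batch_losses <- numeric(n_batch)
    for (bi in seq_len(n_batch)) {
      idx <- perm[((bi - 1L) * plan$batch_size + 1L):min(length(perm), bi * plan$batch_size)]
      ci <- sample.int(length(sampler$codes), 1L, prob = sampler$probs)
      code <- sampler$codes[[ci]]
      code_hist[ci] <- code_hist[ci] + 1L
      X <- model_inputs(model, data, idx, code)
      fw <- model_predict_train(model, params, state, config, fc_def, X,
                                code, train = TRUE, plan = net_plan,
                                freeze_bn_stat = freeze_bn)
      state <- fw$state
      resid <- fw$pred - data$targets[idx]
      loss <- sqrt(mean(resid^2))
      if (!is.finite(loss)) {
        stop("NaN/Inf loss at epoch ", epoch, ", batch ", bi,
             "; last finite batch loss ",
             if (bi > 1L) signif(batch_losses[bi - 1L], 4) else NA)
      }
      batch_losses[bi] <- loss
      # gradient of the mean squared error: same minimizer as the reported
      # RMSE, but its gradient vanishes at the optimum, letting Adam settle
      # (the RMSE gradient is scale-invariant and leaves a plateau of
      # learning-rate-sized parameter noise)
      dpred <- 2 * resid / length(idx)
      if (model == "scnn") {
        grads <- scnn_backward(params, config, fw, dpred)
        grads <- scnn_add_l1_grad(grads, params, config)
      } else {
        dz <- dpred * fw$cache$dydz
        grads <- mlp_backward(fc_def, params, fw$cache$fc,
                              matrix(dz, length(idx), 1L))$grads
      }
      stepres <- adam_step(params, grads, opt, lr = lr_e, mask = freeze)
      params <- stepres$params; opt <- stepres$state
    }
    val <- mean(vapply(sampler$codes, function(cd) {
      eval_rmse_for_code(model, params, state, config, fc_def, data,
                         val_idx, cd, net_plan)
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_rmse = mean(batch_losses),
                                         val_rmse = val))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                      mean(batch_losses), val))
    }
    if (val < best$val - 1e-9) {
      best <- list(params = params, state = state, val = val, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= plan$patience) break
    }
  }

  fw_checkpoint(model, best$params, best$state, config, fc_def,
                feature_contract = default_feature_contract(model, config,
                                                            data$training_shells),
                training_meta = list(seed = plan$seed,
                                     shells = data$training_shells,
                                     segments = lapply(data$segments, length),
                                     history = history,
                                     best_epoch = best$epoch,
                                     val_rmse_best = best$val,
                                     val_groups = val_grp,
                                     code_histogram = code_hist,
                                     plan = unclass(plan)))
}

#' Fine-tune a checkpoint on new data
#'
#' With the plan scope `fc_only`, only the fully connected head is
#' trainable: every other parameter (spherical convolutions, batch-norm
#' gains, dynamic head) is frozen, verified after training by comparing
#' parameter hashes — a violation is a hard failure. Normalization
#' statistics are likewise kept fixed. The returned checkpoint is the
#' best validation epoch, with the pre-fine-tuning weights retained if no
#' epoch improves on them, so fine-tuning never increases validation RMSE
#' on the adaptation data.
#'
#' @param checkpoint starting `fw_checkpoint`.
#' @param data adaptation `fw_dataset`.
#' @param plan a [training_plan()] with `fine_tune_scope = "fc_only"`.
#' @param verbose print per-epoch losses.
#' @export
fine_tune <- function(checkpoint, data, plan, verbose = FALSE) {
  stopifnot(inherits(checkpoint, "fw_checkpoint"))
  if (plan$fine_tune_scope != "fc_only") {
    stop("fine_tune requires plan with fine_tune_scope = 'fc_only'")
  }
  if (plan$epochs == 0L) return(checkpoint)
  frozen_hash <- param_hash(checkpoint$weights[setdiff(names(checkpoint$weights), "fc")])
  mask <- tree_zeros_like(checkpoint$weights)
  if (checkpoint$model_type == "scnn") {
    mask$fc <- tree_map(function(x) x * 0 + 1, checkpoint$weights$fc)
  } else {
    mask <- tree_map(function(x) x * 0 + 1, checkpoint$weights)   # all-FC models
  }
  ck <- fw_train(checkpoint$model_type, data, plan, config = checkpoint$config,
                 init = checkpoint, freeze = mask, verbose = verbose)
  if (checkpoint$model_type == "scnn") {
    new_hash <- param_hash(ck$weights[setdiff(names(ck$weights), "fc")])
    if (!identical(frozen_hash, new_hash)) {
      stop("scope violation: non-FC parameters changed during fc_only fine-tuning")
    }
  }
  ck$training_meta$fine_tuned_from <- checkpoint$training_meta$best_epoch
  ck
}
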