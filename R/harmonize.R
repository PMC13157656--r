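#' B-value remapping specification
#'
#' Under the linear-decay assumption (valid for roughly
#' 500 < b < 1500 s/mm^2) a shell acquired at `b_original` can be
#' re-expressed at `b_new` by scaling the log-attenuation:
#' \deqn{S_{b_{new}} = S_0 \exp\left(\frac{b_{new}}{b_{orig}}
#'   \log\frac{S_{b_{orig}}}{S_0}\right).}
#' Remapping is allowed when either endpoint lies inside (500, 1500\]
#' (matching how 1500 and 700 s/mm^2 shells are folded onto the 1000
#' training shell in practice); extrapolating upward from below the
#' linear-decay range triggers a warning.
#'
#' @param b_original,b_new source and target b-values (s/mm^2).
#' @param valid_range linear-decay regime bounds.
#' @export
remap_spec <- function(b_original, b_new, valid_range = c(500, 1500)) {
  in_range <- function(b) b > valid_range[1] & b <= valid_range[2]
  if (!in_range(b_original) && !in_range(b_new)) {
    stop("refuse-to-remap: neither b = ", b_original, " nor b = ", b_new,
         " lies in the linear-decay range (", valid_range[1], ", ",
         valid_range[2], "] s/mm^2")
  }
  if (b_new > b_original && b_original < 1000) {
    warning("remapping extrapolates upward from b = ", b_original,
            " s/mm^2 beyond the measured attenuation")
  }
  structure(list(b_original = b_original, b_new = b_new,
                 valid_range = valid_range),
            class = "remap_spec")
}

#' Remap diffusion signal to a new b-value
#'
#' @param signal per-measurement signal values (vector or V x N matrix of
#'   voxels x measurements) acquired at `spec$b_original`.
#' @param s0 per-voxel b0 reference (scalar or length-V).
#' @param spec a [remap_spec()].
#' @param floor relative signal floor applied before the log.
#' @return remapped signal, same shape as the input.
#' @export
remap_bvalue <- function(signal, s0, spec, floor = 1e-6) {
  stopifnot(inherits(spec, "remap_spec"))
  if (any(s0 <= 0)) stop("s0 must be positive")
  ratio <- spec$b_new / spec$b_original
  att <- pmax(signal / s0, floor)
  out <- s0 * exp(ratio * log(att))
  attributes(out) <- attributes(signal)
  out
}

#' Remap a scheme's sub-1500 shell onto the training 1000 s/mm^2 shell
#'
#' Applies the rule used for harmonizing acquisitions onto the training
#' scheme: among shells at or below 1500 s/mm^2, the lowest is remapped to
#' `target`; any other sub-1500 shell is dropped with a warning (their
#' handling is not defined by the linear-decay rule). Shells above 1500
#' pass through unchanged. Remapped measurements keep their directions.
#'
#' @param signal V x N matrix (voxels x measurements).
#' @param scheme a [gradient_scheme()].
#' @param target target b-value (default 1000 s/mm^2).
#' @return list with `signal` (possibly with columns dropped), `scheme`
#'   (relabeled b-values), and `remapped` (logical: was anything changed).
#' @export
remap_scheme_to_training <- function(signal, scheme, target = 1000) {
  low <- scheme$nominal_bvals[scheme$nominal_bvals <= 1500]
  if (!length(low)) return(list(signal = signal, scheme = scheme, remapped = FALSE))
  src <- min(low)
  if (abs(src - target) < 1e-9) {
    return(list(signal = signal, scheme = scheme, remapped = FALSE))
  }
  drop_shells <- setdiff(low, src)
  keep <- seq_along(scheme$bvals)
  for (b in drop_shells) {
    warning("dropping shell b = ", b, " s/mm^2: only the lowest sub-1500 ",
            "shell is remapped to ", target)
    keep <- setdiff(keep, scheme$shells[[as.character(b)]])
  }
  signal <- signal[, keep, drop = FALSE]
  bvals <- scheme$bvals[keep]
  bvecs <- scheme$bvecs[keep, , drop = FALSE]
  s0 <- rowMeans(signal[, bvals <= scheme$b0_threshold, drop = FALSE])
  spec <- remap_spec(src, target)
  idx <- which(abs(bvals - src) <= scheme$shell_tolerance & bvals > scheme$b0_threshold)
  signal[, idx] <- remap_bvalue(signal[, idx, drop = FALSE], s0, spec)
  bvals[idx] <- target
  list(signal = signal,
       scheme = gradient_scheme(bvals, bvecs, scheme$b0_threshold,
                                scheme$shell_tolerance),
       remapped = TRUE)
}

#' Normalize a DWI series by its b0 signal
#'
#' The S0 map is the mean over b0 volumes; every volume is divided
#' voxelwise by it and clipped to \[1e-6, 1.5\] (noise can push weighted
#' signals above S0). Voxels with nonpositive S0 are flagged invalid.
#'
#' @param signal 4D array or V x N matrix.
#' @param scheme a [gradient_scheme()] with >= 1 b0 volume.
#' @return list with `normalized` (same shape), `s0` (map), `valid`
#'   (logical map: S0 > 0).
#' @export
normalize_signal <- function(signal, scheme) {
  dims <- NULL
  if (length(dim(signal)) == 4L) {
    dims <- dim(signal)[1:3]
    signal <- matrix(signal, prod(dims), dim(signal)[4L])
  }
  signal <- as.matrix(signal)
  if (!length(scheme$b0_indices)) stop("need >= 1 b0 volume to normalize")
  s0 <- rowMeans(signal[, scheme$b0_indices, drop = FALSE])
  valid <- s0 > 0
  norm <- signal
  norm[valid, ] <- pmin(1.5, pmax(1e-6, signal[valid, , drop = FALSE] / s0[valid]))
  norm[!valid, ] <- 0
  if (!is.null(dims)) {
    norm <- array(norm, c(dims, ncol(signal)))
    s0 <- array(s0, dims); valid <- array(valid, dims)
  }
  list(normalized = norm, s0 = s0, valid = valid)
}
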