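#' Free-water elimination of a DWI volume
#'
#' Subtracts the estimated free-water compartment from the measured
#' signal:
#' \deqn{\hat S_i = S_i - S_0 \, f_{fw} \exp(-b_i D_{iso}).}
#' At b = 0 this gives \eqn{\hat S_0 = S_0 (1 - f)}, which is the b0
#' convention used throughout: downstream tensor fits on corrected data
#' use the corrected b0 as their reference, keeping the normalization
#' self-consistent. Negative results (possible under Rician noise) are
#' floored at 0 and counted.
#'
#' @param signal 4D array (x,y,z,measurement) or V x N matrix.
#' @param s0 S0 map (array or length-V vector), e.g. from
#'   [normalize_signal()].
#' @param f free-water fraction map (array or vector), values in \[0,1\].
#' @param scheme a [gradient_scheme()].
#' @param d_iso free-water diffusivity (mm^2/s).
#' @return object of class `corrected_dwi`: `signal_hat` (same shape as
#'   input), `scheme`, `floor_count`, `d_iso`.
#' @export
eliminate_free_water <- function(signal, s0, f, scheme, d_iso = 3.0e-3) {
  dims <- NULL
  if (length(dim(signal)) == 4L) {
    dims <- dim(signal)
    signal <- matrix(signal, prod(dims[1:3]), dims[4L])
  }
  signal <- as.matrix(signal)
  s0 <- as.vector(s0); f <- as.vector(f)
  if (length(s0) != nrow(signal) || length(f) != nrow(signal)) {
    stop("contract error: s0/f length does not match voxel count")
  }
  if (ncol(signal) != length(scheme$bvals)) {
    stop("contract error: measurement count does not match scheme")
  }
  if (any(f < -1e-9 | f > 1 + 1e-9)) stop("f must lie in [0, 1]")
  fw_term <- outer(s0 * f, exp(-scheme$bvals * d_iso))
  shat <- signal - fw_term
  floor_count <- sum(shat < 0)
  shat[shat < 0] <- 0
  if (!is.null(dims)) shat <- array(shat, dims)
  structure(list(signal_hat = shat, scheme = scheme,
                 floor_count = floor_count, d_iso = d_iso),
            class = "corrected_dwi")
}

#' @export
print.corrected_dwi <- function(x, ...) {
  cat("corrected_dwi:", length(x$signal_hat), "values,",
      x$floor_count, "floored at zero\n")
  invisible(x)
}

#' Write a corrected DWI series with its gradient files
#'
#' @param corrected a `corrected_dwi` with 4D `signal_hat`.
#' @param prefix output prefix; writes `<prefix>_dwi.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_corrected_dwi <- function(corrected, prefix) {
  if (length(dim(corrected$signal_hat)) != 4L) {
    stop("signal_hat has no spatial shape to write")
  }
  RNifti::writeNifti(RNifti::asNifti(corrected$signal_hat),
                     paste0(prefix, "_dwi.nii.gz"))
  write_gradients(corrected$scheme, paste0(prefix, ".bval"),
                  paste0(prefix, ".bvec"))
  invisible(prefix)
}
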