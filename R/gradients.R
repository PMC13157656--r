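#' Acquisition geometry of a diffusion-weighted series
#'
#' A `gradient_scheme` groups the measurements of a DWI series into b0
#' volumes and shells of (near-)constant diffusion weighting. Shells are
#' formed by clustering b-values around nominal centers within
#' `shell_tolerance`; every measurement belongs to exactly one of the b0
#' set or a single shell, shells are disjoint, and their nominal b-values
#' strictly increase. Non-b0 directions are renormalized to unit length.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs N x 3 (or 3 x N) matrix of gradient directions.
#' @param b0_threshold b-values at or below this are treated as b0
#'   (default 50 s/mm^2, catching interleaved "b0" volumes acquired at
#'   small nonzero weightings).
#' @param shell_tolerance half-width (s/mm^2) for assigning a measurement
#'   to a nominal shell center (default 100).
#' @return object of class `gradient_scheme` with fields `bvals`, `bvecs`,
#'   `b0_indices`, `shells` (named list, nominal b-value -> indices) and
#'   `nominal_bvals`.
#' @export
gradient_scheme <- function(bvals, bvecs, b0_threshold = 50,
                            shell_tolerance = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- as_direction_matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop("gradient format error: ", length(bvals), " b-values but ",
         nrow(bvecs), " directions")
  }
  nrm <- sqrt(rowSums(bvecs^2))
  b0 <- which(bvals <= b0_threshold)
  dwi <- setdiff(seq_along(bvals), b0)
  if (any(nrm[dwi] < 1e-8)) {
    stop("gradient format error: zero direction vector at nonzero b-value (index ",
         paste(dwi[nrm[dwi] < 1e-8], collapse = ", "), ")")
  }
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  bvecs[b0, ] <- 0

  shells <- list()
  if (length(dwi)) {
    # cluster b-values: nominal center = rounded mean of a tolerance group
    bs <- sort(unique(bvals[dwi]))
    centers <- numeric(0)
    members <- list()
    for (b in bs) {
      hit <- which(abs(centers - b) <= shell_tolerance)
      if (length(hit) > 1L) {
        stop("shell ambiguity error: b-value ", b,
             " lies within tolerance of two nominal shells (",
             paste(round(centers[hit]), collapse = ", "), ")")
      }
      if (length(hit) == 1L) {
        members[[hit]] <- c(members[[hit]], b)
      } else {
        centers <- c(centers, b)
        members[[length(centers)]] <- b
      }
    }
    nominal <- vapply(members, function(m) round(mean(m)), numeric(1))
    # a raw b-value within tolerance of two *nominal* centers is ambiguous
    for (b in bs) {
      if (sum(abs(nominal - b) <= shell_tolerance) > 1L) {
        stop("shell ambiguity error: b-value ", b,
             " is assignable to two nominal shells (",
             paste(round(nominal[abs(nominal - b) <= shell_tolerance]),
                   collapse = ", "), ")")
      }
    }
    ordidx <- order(nominal)
    nominal <- nominal[ordidx]; members <- members[ordidx]
    shells <- lapply(seq_along(nominal), function(k) {
      which(bvals %in% members[[k]] & seq_along(bvals) %in% dwi)
    })
    names(shells) <- as.character(nominal)
  }
  structure(
    list(bvals = bvals, bvecs = bvecs, b0_indices = b0, shells = shells,
         nominal_bvals = as.numeric(names(shells)),
         b0_threshold = b0_threshold, shell_tolerance = shell_tolerance),
    class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient_scheme:", length(x$bvals), "measurements,",
      length(x$b0_indices), "b0,",
      length(x$shells), "shell(s)\n")
  for (nm in names(x$shells)) {
    cat("  b=", nm, ": ", length(x$shells[[nm]]), " directions\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' Read FSL-style gradient files
#'
#' Reads a `.bval` file (one whitespace-separated row) and a `.bvec` file
#' (three whitespace-separated rows, or three columns — auto-detected) and
#' builds a [gradient_scheme()].
#'
#' @inheritParams gradient_scheme
#' @param bval_path,bvec_path paths to the text files.
#' @return a `gradient_scheme`.
#' @export
read_gradients <- function(bval_path, bvec_path, b0_threshold = 50,
                           shell_tolerance = 100) {
  for (p in c(bval_path, bvec_path)) {
    if (!file.exists(p)) stop("gradient file not found: ", p)
  }
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(rows, function(r) scan(text = r, what = numeric(), quiet = TRUE))
  if (length(vals) == 3L) {
    bvecs <- t(do.call(rbind, vals))            # 3 rows x N columns
  } else if (all(lengths(vals) == 3L)) {
    bvecs <- do.call(rbind, vals)               # N rows x 3 columns
  } else {
    stop("gradient format error: ", bvec_path,
         " is neither 3 rows x N nor N rows x 3")
  }
  if (nrow(bvecs) != length(bvals)) {
    stop("gradient format error: ", length(bvals), " b-values in ",
         bval_path, " but ", nrow(bvecs), " directions in ", bvec_path)
  }
  gradient_scheme(bvals, bvecs, b0_threshold, shell_tolerance)
}

#' Write FSL-style gradient files
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_gradients <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  v <- t(scheme$bvecs)
  lines <- apply(v, 1L, function(r) paste(format(r, digits = 17), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval = bval_path, bvec = bvec_path))
}

#' Shell-availability code for an acquisition
#'
#' Encodes which of the `K` training shells are present in a scheme as a
#' 0/1 vector — the condition for the dynamic head. With `K` shells there
#' are `2^K - 1` valid configurations; the training scheme here uses
#' b = 1000, 2000, 3000 s/mm^2, so `K = 3`.
#'
#' @param scheme a [gradient_scheme()].
#' @param training_shells sorted nominal b-values of the training scheme.
#' @param tolerance matching tolerance (s/mm^2).
#' @return object of class `shell_code`: integer 0/1 vector of length `K`.
#' @export
shell_code_for <- function(scheme, training_shells = c(1000, 2000, 3000),
                           tolerance = 100) {
  if (!length(training_shells) || is.unsorted(training_shells)) {
    stop("training_shells must be nonempty and sorted")
  }
  m <- vapply(training_shells, function(b) {
    as.integer(any(abs(scheme$nominal_bvals - b) <= tolerance))
  }, integer(1))
  if (!any(m == 1L)) {
    stop("unusable acquisition: no shell matches any training shell (",
         paste(training_shells, collapse = ", "), " s/mm^2)")
  }
  shell_code(m)
}

#' Construct/validate a shell code
#' @param m 0/1 vector, one entry per training shell.
#' @export
shell_code <- function(m) {
  m <- as.integer(m)
  if (!length(m) || !all(m %in% c(0L, 1L))) stop("shell code entries must be 0 or 1")
  if (!any(m == 1L)) stop("invalid shell code: at least one shell must be present")
  structure(m, class = "shell_code")
}

#' @export
print.shell_code <- function(x, ...) {
  cat("shell_code:", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

#' All valid shell codes for K training shells
#' @param K number of training shells.
#' @return list of the `2^K - 1` valid codes.
#' @export
all_shell_codes <- function(K = 3L) {
  out <- list()
  for (i in seq_len(2^K - 1L)) {
    bits <- as.integer(intToBits(i)[seq_len(K)])
    out[[length(out) + 1L]] <- shell_code(bits)
  }
  out
}
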