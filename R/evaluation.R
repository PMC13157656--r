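#' Root-mean-square error between fraction maps
#'
#' @param estimate,reference fraction maps (same shape).
#' @param mask logical mask (default: all voxels).
#' @return scalar RMSE over masked voxels.
#' @export
rmse_fraction <- function(estimate, reference, mask = NULL) {
  estimate <- as.vector(estimate); reference <- as.vector(reference)
  if (length(estimate) != length(reference)) stop("shape mismatch")
  if (is.null(mask)) mask <- rep(TRUE, length(estimate))
  mask <- as.logical(as.vector(mask))
  if (!any(mask)) stop("empty mask")
  sqrt(mean((estimate[mask] - reference[mask])^2))
}

#' FA/MD statistics in a centered cubic patch
#'
#' Means and standard deviations of FA and MD within a cube of the given
#' edge length centered in the volume — the ROI construction used to
#' quantify the correction effect around CSF-confined ventricles. Maps
#' may be given for several conditions (e.g. before/after correction) as
#' named lists.
#'
#' @param fa_map,md_map 3D arrays, or named lists of 3D arrays (one per
#'   condition).
#' @param patch_edge cube edge length in voxels (clipped to the volume
#'   with a warning if too large).
#' @param mask optional logical array.
#' @return data.frame with columns `metric`, `condition`, `mean`, `sd`,
#'   `n`.
#' @export
roi_patch_stats <- function(fa_map, md_map, patch_edge = 50L, mask = NULL) {
  as_cond_list <- function(x, nm) {
    if (is.list(x)) x else stats::setNames(list(x), nm)
  }
  fa_l <- as_cond_list(fa_map, "fa")
  md_l <- as_cond_list(md_map, "md")
  dims <- dim(fa_l[[1L]])
  if (length(dims) != 3L) stop("maps must be 3D arrays")
  edge <- rep(as.integer(patch_edge), length.out = 3L)
  if (any(edge > dims)) {
    warning("patch larger than volume; clipping to the volume extent")
    edge <- pmin(edge, dims)
  }
  lo <- pmax(1L, floor((dims - edge) / 2) + 1L)
  hi <- lo + edge - 1L
  sel <- array(FALSE, dims)
  sel[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  if (!is.null(mask)) sel <- sel & as.logical(mask)
  if (!any(sel)) stop("patch entirely outside mask")
  one <- function(metric, cond, m) {
    v <- m[sel]
    data.frame(metric = metric, condition = cond,
               mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  out <- rbind(
    do.call(rbind, lapply(names(fa_l), function(cd) one("FA", cd, fa_l[[cd]]))),
    do.call(rbind, lapply(names(md_l), function(cd) one("MD", cd, md_l[[cd]]))))
  rownames(out) <- NULL
  out
}

#' Scan-rescan percentage differences per region
#'
#' For each region the session means of a metric are compared as
#' \deqn{100 \, |m_1 - m_2| / ((m_1 + m_2)/2),}
#' the symmetric (session-mean denominator) absolute percentage
#' difference. Only voxels present in both sessions' region masks are
#' used; empty joint regions are skipped with a warning.
#'
#' @param metric_scan,metric_rescan metric maps of the two sessions
#'   (spatially aligned).
#' @param region_masks named list of logical arrays, or an integer label
#'   volume (labels > 0 become regions).
#' @param denominator `"session_mean"` (default) or `"first_session"`.
#' @return named numeric vector of percentages.
#' @export
retest_percent_diff <- function(metric_scan, metric_rescan, region_masks,
                                denominator = c("session_mean", "first_session")) {
  denominator <- match.arg(denominator)
  if (!is.list(region_masks)) {
    labs <- sort(unique(as.vector(region_masks[region_masks > 0])))
    region_masks <- stats::setNames(
      lapply(labs, function(lb) region_masks == lb),
      paste0("region", labs))
  }
  out <- numeric(0)
  for (nm in names(region_masks)) {
    joint <- as.logical(region_masks[[nm]]) &
      is.finite(metric_scan) & is.finite(metric_rescan)
    if (!any(joint)) {
      warning("region '", nm, "' empty in the joint mask; skipped")
      next
    }
    m1 <- mean(metric_scan[joint]); m2 <- mean(metric_rescan[joint])
    den <- if (denominator == "session_mean") (m1 + m2) / 2 else m1
    out[nm] <- 100 * abs(m1 - m2) / den
  }
  out
}

#' FA and MD histograms over a mask
#'
#' 100 bins on \[0, 1\] for FA and \[0, 3.5e-3\] for MD (values beyond
#' the range are clamped into the edge bins so counts always sum to the
#' masked voxel count).
#'
#' @param fa_map,md_map 3D metric maps.
#' @param mask logical array (default: all).
#' @param n_bins number of bins.
#' @return list with `fa` and `md`, each a data.frame (`mid`, `count`).
#' @export
fa_md_histograms <- function(fa_map, md_map, mask = NULL, n_bins = 100L) {
  if (is.null(mask)) mask <- rep(TRUE, length(fa_map))
  mask <- as.logical(as.vector(mask))
  hist1 <- function(v, lim) {
    v <- pmin(lim[2], pmax(lim[1], v))
    br <- seq(lim[1], lim[2], length.out = n_bins + 1L)
    ct <- tabulate(pmin(n_bins, findInterval(v, br, rightmost.closed = TRUE)),
                   nbins = n_bins)
    data.frame(mid = (br[-1] + br[-length(br)]) / 2, count = ct)
  }
  list(fa = hist1(as.vector(fa_map)[mask], c(0, 1)),
       md = hist1(as.vector(md_map)[mask], c(0, 3.5e-3)))
}
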