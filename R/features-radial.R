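# ---- radial intensity distribution -----------------------------------------

#' Extract radial intensity distribution features for one nucleus
#'
#' Partitions the nucleus into `n_rings` equal-width concentric distance bands
#' from the centroid out to the farthest pixel and reports, per ring: the
#' fraction of total intensity in the ring (`frac`), and that fraction
#' normalized by the ring's share of pixels (`meanfrac`; 1 everywhere for a
#' uniform nucleus). With `include_cv = TRUE` it also reports the coefficient
#' of variation of mean intensity across 8 angular wedges within each ring
#' (`radialcv`).
#'
#' Intensity fractions over rings always sum to 1. A degenerate nucleus whose
#' pixels are all equidistant from the centroid (e.g. a single pixel) falls
#' back to a single ring: `frac = meanfrac = 1` in ring 1, 0 elsewhere, CV 0.
#'
#' @param intensity Grayscale matrix.
#' @param labels Label matrix of the same dimensions.
#' @param nucleus_id Label to measure.
#' @param n_rings Number of concentric rings.
#' @param include_cv Also return per-ring angular-wedge CVs.
#' @return Named numeric vector `radial_frac_r*`, `radial_meanfrac_r*` (and
#'   optionally `radial_cv_r*`).
#' @export
extract_radial_features <- function(intensity, labels, nucleus_id,
                                    n_rings = 4L, include_cv = FALSE) {
  px <- which(labels == nucleus_id, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    rlang::abort(sprintf("Nucleus %s not present in the label mask.", nucleus_id),
                 class = "nucleoprog_missing_object_error")
  }
  stopifnot(n_rings >= 1)
  v <- intensity[px]
  cen <- colMeans(px)
  d <- sqrt((px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2)
  dmax <- max(d)
  if (dmax == 0) {
    ring <- rep(1L, nrow(px))
  } else {
    ring <- pmin(pmax(ceiling(d / dmax * n_rings), 1L), n_rings)
  }
  tot <- sum(v)
  ring_int <- vapply(seq_len(n_rings), function(k) sum(v[ring == k]), numeric(1))
  ring_n <- tabulate(ring, nbins = n_rings)
  frac <- if (tot > 0) ring_int / tot else ring_n / nrow(px)
  pixshare <- ring_n / nrow(px)
  meanfrac <- ifelse(pixshare > 0, frac / pixshare, 0)
  out <- c(stats::setNames(frac, paste0("radial_frac_r", seq_len(n_rings))),
           stats::setNames(meanfrac, paste0("radial_meanfrac_r", seq_len(n_rings))))
  if (include_cv) {
    ang <- atan2(px[, 1] - cen[1], px[, 2] - cen[2])
    wedge <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)
    cvs <- vapply(seq_len(n_rings), function(k) {
      sel <- ring == k
      if (!any(sel)) return(0)
      m <- vapply(split(v[sel], wedge[sel]), mean, numeric(1))
      if (length(m) < 2L || mean(m) == 0) return(0)
      stats::sd(m) / mean(m)
    }, numeric(1))
    out <- c(out, stats::setNames(cvs, paste0("radial_cv_r", seq_len(n_rings))))
  }
  out
}
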