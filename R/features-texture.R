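# ---- gray-level co-occurrence texture --------------------------------------

#' Names of the 13 Haralick statistics
#' @return Character vector of length 13.
#' @export
haralick_stat_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2")
}

#' Default texture settings
#'
#' @param n_gray_levels Number of quantization levels (per-nucleus min-max).
#' @param distances Pixel offset distances.
#' @param symmetric Count each pixel pair in both orders.
#' @return A list of texture settings.
#' @export
texture_settings <- function(n_gray_levels = 8L, distances = c(1L, 2L, 4L, 8L),
                             symmetric = TRUE) {
  stopifnot(n_gray_levels >= 2, all(distances >= 1))
  list(n_gray_levels = as.integer(n_gray_levels),
       distances = as.integer(distances), symmetric = isTRUE(symmetric))
}

# Per-nucleus min-max quantization to 1..L; constant input maps to level 1.
quantize_gray <- function(v, L) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(1L, length(v)))
  q <- floor((v - rng[1]) / (rng[2] - rng[1]) * L) + 1L
  pmin(as.integer(q), L)
}

#' Gray-level co-occurrence matrix of one nucleus
#'
#' Accumulates within-nucleus pixel pairs at offset distance `d` over the four
#' standard directions (0, 45, 90, 135 degrees), optionally in both orders
#' (symmetric), and normalizes so entries sum to 1. Pairs with either pixel
#' outside the nucleus are excluded.
#'
#' @param quant Integer matrix of quantized levels (`NA` outside the nucleus).
#' @param L Number of levels.
#' @param d Offset distance in pixels.
#' @param symmetric Count pairs in both orders.
#' @return `L x L` matrix summing to 1, or an all-zero matrix if the nucleus
#'   admits no pixel pair at this offset.
#' @export
glcm_matrix <- function(quant, L, d, symmetric = TRUE) {
  nr <- nrow(quant); nc <- ncol(quant)
  counts <- matrix(0, L, L)
  offsets <- list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (dr > nr - 1L || abs(dc) > nc - 1L) next
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- quant[r1, c1, drop = FALSE]
    b <- quant[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    idx <- (b[ok] - 1L) * L + a[ok]
    tab <- tabulate(idx, nbins = L * L)
    counts <- counts + matrix(tab, L, L)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

#' The 13 Haralick statistics of a normalized co-occurrence matrix
#'
#' Standard formulas over level indices with natural logarithms; the sum
#' variance is centred on the sum average. Degenerate marginals (zero
#' standard deviation) give correlation 0 and IMC1 0.
#'
#' @param p Normalized `L x L` co-occurrence matrix (entries sum to 1), or an
#'   all-zero matrix, for which all 13 statistics are 0.
#' @return Named numeric vector of length 13 (see [haralick_stat_names()]).
#' @export
haralick_statistics <- function(p) {
  L <- nrow(p)
  out <- stats::setNames(numeric(13), haralick_stat_names())
  tot <- sum(p)
  if (tot == 0) return(out)
  if (abs(tot - 1) > 1e-8) {
    rlang::abort("Co-occurrence matrix is not normalized.",
                 class = "nucleoprog_contract_error")
  }
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  nz <- p > 0

  out["asm"] <- sum(p^2)
  out["contrast"] <- sum((i - j)^2 * p)
  out["correlation"] <-
    if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 0
  out["variance"] <- sum((i - mux)^2 * p)
  out["idm"] <- sum(p / (1 + (i - j)^2))
  # p_{x+y}: k = 2..2L ; p_{x-y}: k = 0..L-1
  psum <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sa <- sum(ks * psum)
  out["sum_average"] <- sa
  out["sum_variance"] <- sum((ks - sa)^2 * psum)
  out["sum_entropy"] <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  out["entropy"] <- -sum(p[nz] * log(p[nz]))
  mud <- sum(kd * pdiff)
  out["difference_variance"] <- sum((kd - mud)^2 * pdiff)
  out["difference_entropy"] <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))
  hxy <- out["entropy"]
  pxy <- outer(px, py)
  ok <- pxy > 0
  hxy1 <- -sum(p[nz & ok] * log(pxy[nz & ok]))
  hxy2 <- -sum(pxy[ok] * log(pxy[ok]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  out["imc1"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  out["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out
}

#' Extract chromatin texture features for one nucleus
#'
#' Quantizes the within-nucleus intensities to `n_gray_levels` by per-nucleus
#' min-max scaling, builds the symmetric direction-pooled co-occurrence matrix
#' at each offset distance, and returns the 13 Haralick statistics per
#' distance. A nucleus admitting no pixel pair at a given distance yields 0
#' for that distance's 13 features, with a warning.
#'
#' @param intensity Grayscale matrix.
#' @param labels Label matrix of the same dimensions.
#' @param nucleus_id Label to measure.
#' @param settings A [texture_settings()] list.
#' @return Named numeric vector of length `13 * length(distances)`, ordered
#'   statistic-within-distance as `<stat>_d<d>`.
#' @export
extract_texture_features <- function(intensity, labels, nucleus_id,
                                     settings = texture_settings()) {
  px <- which(labels == nucleus_id, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    rlang::abort(sprintf("Nucleus %s not present in the label mask.", nucleus_id),
                 class = "nucleoprog_missing_object_error")
  }
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  nr <- max(px[, 1]) - r0 + 1L; nc <- max(px[, 2]) - c0 + 1L
  quant <- matrix(NA_integer_, nr, nc)
  lev <- quantize_gray(intensity[px], settings$n_gray_levels)
  quant[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- lev

  out <- numeric(0)
  for (d in settings$distances) {
    p <- glcm_matrix(quant, settings$n_gray_levels, d, settings$symmetric)
    if (sum(p) == 0) {
      rlang::warn(sprintf(
        "Nucleus %s has no pixel pair at offset distance %d; texture features set to 0.",
        nucleus_id, d), class = "nucleoprog_small_nucleus_warning")
      stats_d <- stats::setNames(numeric(13), haralick_stat_names())
    } else {
      stats_d <- haralick_statistics(p)
    }
    names(stats_d) <- paste0(names(stats_d), "_d", d)
    out <- c(out, stats_d)
  }
  out
}
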