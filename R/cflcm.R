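# ---- cell-feature-level co-occurrence (CFLCM) ------------------------------

#' Quantize per-nucleus feature values into equal-frequency levels
#'
#' Bins values into `1..n_levels` by per-ROI quantile (equal-frequency)
#' binning. Constant input maps every value to level 1.
#'
#' @param values Numeric vector (one value per nucleus; >= 1 value).
#' @param n_levels Number of levels (>= 2).
#' @return List with `levels` (integer vector in `1..n_levels`) and `edges`
#'   (the interior quantile bin edges used).
#' @export
quantize_feature <- function(values, n_levels = 8L) {
  if (length(values) == 0L) {
    rlang::abort("Cannot quantize an empty value vector.",
                 class = "nucleoprog_empty_roi_error")
  }
  stopifnot(n_levels >= 2)
  if (length(unique(values)) == 1L) {
    return(list(levels = rep(1L, length(values)), edges = numeric(0)))
  }
  edges <- stats::quantile(values, probs = seq_len(n_levels - 1L) / n_levels,
                           names = FALSE, type = 7)
  lev <- findInterval(values, vec = edges, left.open = TRUE) + 1L
  list(levels = as.integer(lev), edges = edges)
}

#' Build the spatial neighbor graph over nucleus centroids
#'
#' Symmetrized k-nearest-neighbor graph by Euclidean centroid distance: an
#' undirected edge joins i and j if either is among the other's `k` nearest.
#' Distance ties are broken by nucleus order (row index). A single nucleus
#' yields an empty edge set. A Delaunay-free, scale-free adjacency standing in
#' for the pixel offset of an ordinary co-occurrence matrix.
#'
#' @param centroids Two-column matrix or data frame of (row, col) positions.
#' @param k Number of nearest neighbors (default 5).
#' @return A tibble of undirected edges with columns `i`, `j` (`i < j`),
#'   of class `neighbor_graph` with attributes `n_nodes` and `k`.
#' @export
build_neighbor_graph <- function(centroids, k = 5L) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 1L) {
    rlang::abort("Need at least one centroid.", class = "nucleoprog_empty_roi_error")
  }
  edges <- if (n >= 2L) {
    kk <- min(k, n - 1L)
    d <- as.matrix(stats::dist(centroids))
    diag(d) <- Inf
    nbr <- vapply(seq_len(n), function(i) {
      order(d[i, ], seq_len(n))[seq_len(kk)]  # ties by index
    }, integer(kk))
    ii <- rep(seq_len(n), each = kk)
    jj <- as.vector(nbr)
    a <- pmin(ii, jj); b <- pmax(ii, jj)
    keep <- !duplicated(as.numeric(a) * (n + 1) + b)
    tibble::tibble(i = a[keep], j = b[keep])
  } else {
    tibble::tibble(i = integer(0), j = integer(0))
  }
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  structure(tibble::new_tibble(edges, class = "neighbor_graph"),
            n_nodes = n, k = as.integer(k))
}

#' Build a cell-feature-level co-occurrence matrix
#'
#' For every undirected edge (i, j) of the neighbor graph, increments cells
#' (level_i, level_j) and (level_j, level_i), then normalizes by the total
#' number of increments, giving a symmetric matrix summing to 1. With no
#' edges the all-zero matrix is returned, flagged degenerate.
#'
#' @param levels Integer level assignments, one per node of `graph`.
#' @param graph A [build_neighbor_graph()] result.
#' @param n_levels Matrix dimension; defaults to `max(levels)`.
#' @return `n_levels x n_levels` matrix with attribute `degenerate` (TRUE when
#'   the graph has no edges).
#' @export
build_cflcm <- function(levels, graph, n_levels = max(levels)) {
  n <- attr(graph, "n_nodes")
  if (length(levels) != n) {
    rlang::abort("`levels` must assign a level to every node of the graph.",
                 class = "nucleoprog_contract_error")
  }
  L <- n_levels
  m <- matrix(0, L, L)
  if (nrow(graph) == 0L) {
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  li <- levels[graph$i]; lj <- levels[graph$j]
  idx <- c((lj - 1L) * L + li, (li - 1L) * L + lj)
  tab <- tabulate(idx, nbins = L * L)
  m <- matrix(tab / (2 * nrow(graph)), L, L)
  attr(m, "degenerate") <- FALSE
  m
}

#' Names of the 10 CFLCM heterogeneity statistics
#' @return Character vector of length 10.
#' @export
cflcm_stat_names <- function() {
  c("contrast", "dissimilarity", "homogeneity", "asm", "entropy",
    "correlation", "cluster_shade", "cluster_prominence",
    "max_probability", "idm")
}

#' Heterogeneity statistics of a CFLCM
#'
#' Standard co-occurrence statistics over level indices: contrast,
#' dissimilarity, homogeneity (`sum p/(1+|i-j|)`), angular second moment,
#' entropy (natural log), correlation (0 when a marginal is degenerate),
#' cluster shade and prominence, maximum probability, and inverse difference
#' moment (`sum p/(1+(i-j)^2)`). A degenerate all-zero matrix returns all
#' statistics 0.
#'
#' @param m A normalized CFLCM from [build_cflcm()].
#' @return Named numeric vector of length 10 (see [cflcm_stat_names()]).
#' @export
cflcm_statistics <- function(m) {
  out <- stats::setNames(numeric(10), cflcm_stat_names())
  tot <- sum(m)
  if (tot == 0) return(out)
  if (abs(tot - 1) > 1e-8) {
    rlang::abort("CFLCM is not normalized.", class = "nucleoprog_contract_error")
  }
  L <- nrow(m)
  i <- matrix(seq_len(L), L, L); j <- t(i)
  px <- rowSums(m); py <- colSums(m)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  nz <- m > 0
  out["contrast"] <- sum((i - j)^2 * m)
  out["dissimilarity"] <- sum(abs(i - j) * m)
  out["homogeneity"] <- sum(m / (1 + abs(i - j)))
  out["asm"] <- sum(m^2)
  out["entropy"] <- -sum(m[nz] * log(m[nz]))
  out["correlation"] <-
    if (sx > 0 && sy > 0) (sum(i * j * m) - mux * muy) / (sx * sy) else 0
  out["cluster_shade"] <- sum((i + j - mux - muy)^3 * m)
  out["cluster_prominence"] <- sum((i + j - mux - muy)^4 * m)
  out["max_probability"] <- max(m)
  out["idm"] <- sum(m / (1 + (i - j)^2))
  out
}

#' ROI statistic names (12 per base feature)
#' @return Character vector: `mean`, `sd`, then the 10 CFLCM statistics
#'   prefixed `cflcm_`.
#' @export
roi_stat_names <- function() {
  c("mean", "sd", paste0("cflcm_", cflcm_stat_names()))
}

#' Aggregate a per-nucleus feature table to one ROI feature vector
#'
#' Converts a per-nucleus table into a single row of `12 * n_features` ROI
#' features: for each base feature, the per-ROI sample mean and standard
#' deviation (n-1 denominator) and the 10 CFLCM heterogeneity statistics
#' computed from the feature's equal-frequency quantization over the
#' symmetrized k-NN centroid graph. For the default 80-feature manifest the
#' result has 960 feature columns, ordered feature-major
#' (`<feature>_<statistic>`), a frozen order. The ROI vector is invariant to
#' the ordering of nucleus rows.
#'
#' @param nucleus_table Tibble from [extract_nucleus_table()] (or the
#'   synthetic fast path): `case_id`, `roi_id`, `nucleus_id`, `centroid_row`,
#'   `centroid_col`, then feature columns.
#' @param n_levels CFLCM quantization levels (default 8).
#' @param k Neighbors for the centroid graph (default 5).
#' @param min_nuclei ROIs with fewer nuclei are skipped (default 5); a skip
#'   returns a zero-row tibble with a warning giving the reason.
#' @return One-row tibble: `case_id`, `roi_id`, `n_nuclei`, then the ROI
#'   feature columns; zero rows if the ROI was skipped.
#' @export
aggregate_roi <- function(nucleus_table, n_levels = 8L, k = 5L,
                          min_nuclei = 5L) {
  meta <- c("case_id", "roi_id", "nucleus_id", "centroid_row", "centroid_col")
  stopifnot(all(meta %in% names(nucleus_table)))
  feats <- setdiff(names(nucleus_table), meta)
  n <- nrow(nucleus_table)
  empty <- tibble::tibble(case_id = character(0), roi_id = character(0),
                          n_nuclei = integer(0))
  if (n < min_nuclei) {
    rlang::warn(sprintf(
      "ROI %s/%s skipped: %d nuclei < minimum %d.",
      nucleus_table$case_id[1] %||% "?", nucleus_table$roi_id[1] %||% "?",
      n, min_nuclei), class = "nucleoprog_skip_roi_warning")
    return(empty)
  }
  nucleus_table <- dplyr::arrange(nucleus_table, .data$nucleus_id)
  graph <- build_neighbor_graph(
    nucleus_table[, c("centroid_row", "centroid_col")], k = k)
  vals <- purrr::map(feats, function(f) {
    v <- nucleus_table[[f]]
    lev <- quantize_feature(v, n_levels)$levels
    m <- build_cflcm(lev, graph, n_levels = n_levels)
    s <- cflcm_statistics(m)
    c(mean(v), stats::sd(v), s)
  })
  out <- unlist(vals, use.names = FALSE)
  row <- c(
    list(case_id = nucleus_table$case_id[1],
         roi_id = nucleus_table$roi_id[1],
         n_nuclei = n),
    stats::setNames(
      as.list(out),
      as.vector(t(outer(feats, roi_stat_names(), paste, sep = "_"))))
  )
  tibble::new_tibble(row, nrow = 1L)
}

#' Aggregate many ROIs at once
#'
#' Groups a multi-ROI per-nucleus table by `case_id`/`roi_id` and applies
#' [aggregate_roi()] to each group; skipped ROIs drop out (each with its own
#' warning).
#'
#' @inheritParams aggregate_roi
#' @return Tibble with one row per retained ROI.
#' @export
aggregate_rois <- function(nucleus_table, n_levels = 8L, k = 5L,
                           min_nuclei = 5L) {
  nucleus_table |>
    dplyr::group_by(.data$case_id, .data$roi_id) |>
    dplyr::group_split() |>
    purrr::map(aggregate_roi, n_levels = n_levels, k = k,
               min_nuclei = min_nuclei) |>
    dplyr::bind_rows()
}
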