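# Independent brute-force oracles and tiny fixture builders. These are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as ground truth on small instances.

# binary disk mask of radius r centered at (cr, cc) in an n x n image
make_disk_mask <- function(r, cr, cc, n) {
  labs <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - cr)^2 + (j - cc)^2 <= r^2) labs[i, j] <- 1L
    }
  }
  labs
}

# pixel-enumeration oracle for disk area
oracle_disk_area <- function(r, cr, cc, n) {
  cnt <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - cr)^2 + (j - cc)^2 <= r^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# brute-force GLCM: double loop over every ordered pixel pair of the nucleus,
# counting pairs whose positional offset matches one of the four directions
# at distance d (and the reverse order when symmetric)
oracle_glcm <- function(quant, L, d, symmetric = TRUE) {
  px <- which(!is.na(quant), arr.ind = TRUE)
  counts <- matrix(0, L, L)
  offs <- list(c(0, d), c(d, 0), c(d, d), c(d, -d))
  np <- nrow(px)
  for (a in seq_len(np)) {
    for (b in seq_len(np)) {
      dr <- px[b, 1] - px[a, 1]
      dc <- px[b, 2] - px[a, 2]
      for (off in offs) {
        if (dr == off[1] && dc == off[2]) {
          la <- quant[px[a, 1], px[a, 2]]
          lb <- quant[px[b, 1], px[b, 2]]
          counts[la, lb] <- counts[la, lb] + 1
          if (symmetric) counts[lb, la] <- counts[lb, la] + 1
        }
      }
    }
  }
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

# brute-force symmetrized k-NN edge set (list of sorted pairs)
oracle_knn_edges <- function(centroids, k) {
  n <- nrow(centroids)
  edges <- character(0)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) {
        d[j] <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      }
    }
    nb <- order(d, seq_len(n))[seq_len(min(k, n - 1))]
    for (j in nb) {
      edges <- c(edges, paste(min(i, j), max(i, j), sep = "-"))
    }
  }
  sort(unique(edges))
}

# brute-force CFLCM from an edge list
oracle_cflcm <- function(levels, edge_i, edge_j, L) {
  m <- matrix(0, L, L)
  for (e in seq_along(edge_i)) {
    a <- levels[edge_i[e]]; b <- levels[edge_j[e]]
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  tot <- sum(m)
  if (tot > 0) m / tot else m
}

# straight-line reimplementation of the full ROI aggregation for tiny tables:
# explicit loops, its own quantile binning and co-occurrence statistics
oracle_roi_vector <- function(nucleus_table, n_levels = 8, k = 5) {
  meta <- c("case_id", "roi_id", "nucleus_id", "centroid_row", "centroid_col")
  nucleus_table <- nucleus_table[order(nucleus_table$nucleus_id), ]
  feats <- setdiff(names(nucleus_table), meta)
  cen <- as.matrix(nucleus_table[, c("centroid_row", "centroid_col")])
  ek <- oracle_knn_edges(cen, k)
  ei <- as.integer(sub("-.*", "", ek))
  ej <- as.integer(sub(".*-", "", ek))
  out <- c()
  for (f in feats) {
    v <- nucleus_table[[f]]
    if (length(unique(v)) == 1) {
      lev <- rep(1L, length(v))
    } else {
      edges <- stats::quantile(v, probs = (1:(n_levels - 1)) / n_levels,
                               names = FALSE)
      lev <- integer(length(v))
      for (a in seq_along(v)) {
        lev[a] <- 1L + sum(v[a] > edges)
      }
    }
    m <- oracle_cflcm(lev, ei, ej, n_levels)
    s <- numeric(10)
    names(s) <- c("contrast", "dissimilarity", "homogeneity", "asm",
                  "entropy", "correlation", "cluster_shade",
                  "cluster_prominence", "max_probability", "idm")
    if (sum(m) > 0) {
      px <- rowSums(m); py <- colSums(m)
      mux <- sum((1:n_levels) * px); muy <- sum((1:n_levels) * py)
      sx <- sqrt(sum(((1:n_levels) - mux)^2 * px))
      sy <- sqrt(sum(((1:n_levels) - muy)^2 * py))
      corr_num <- 0
      for (i in 1:n_levels) {
        for (j in 1:n_levels) {
          p <- m[i, j]
          s["contrast"] <- s["contrast"] + (i - j)^2 * p
          s["dissimilarity"] <- s["dissimilarity"] + abs(i - j) * p
          s["homogeneity"] <- s["homogeneity"] + p / (1 + abs(i - j))
          s["asm"] <- s["asm"] + p^2
          if (p > 0) s["entropy"] <- s["entropy"] - p * log(p)
          corr_num <- corr_num + i * j * p
          s["cluster_shade"] <- s["cluster_shade"] + (i + j - mux - muy)^3 * p
          s["cluster_prominence"] <- s["cluster_prominence"] + (i + j - mux - muy)^4 * p
          s["idm"] <- s["idm"] + p / (1 + (i - j)^2)
        }
      }
      s["correlation"] <- if (sx > 0 && sy > 0) (corr_num - mux * muy) / (sx * sy) else 0
      s["max_probability"] <- max(m)
    }
    vec <- c(mean(v), stats::sd(v), s)
    names(vec) <- paste0(f, "_", c("mean", "sd", paste0("cflcm_", names(s))))
    out <- c(out, vec)
  }
  out
}

# small deterministic nucleus table with explicit centroids and features
toy_nucleus_table <- function(centroids, features) {
  stopifnot(nrow(centroids) == nrow(features))
  tibble::tibble(
    case_id = "c1", roi_id = "r1", nucleus_id = seq_len(nrow(centroids)),
    centroid_row = centroids[, 1], centroid_col = centroids[, 2],
    !!!as.data.frame(features)
  )
}
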