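# CFLCM spatial-heterogeneity aggregation

test_that("equal-frequency quantization matches its defining examples", {
  q <- quantize_feature(c(1, 2, 3, 4), 2)
  expect_identical(q$levels, c(1L, 1L, 2L, 2L))
  expect_identical(quantize_feature(rep(3.7, 6), 8)$levels, rep(1L, 6))
  set.seed(1)
  lev <- quantize_feature(stats::rnorm(1000), 8)$levels
  counts <- as.vector(table(factor(lev, 1:8)))
  expect_true(all(abs(counts - 125) <= 1))
  expect_error(quantize_feature(numeric(0), 4),
               class = "nucleoprog_empty_roi_error")
})

test_that("the neighbor graph matches hand geometry and the k-NN oracle", {
  g <- build_neighbor_graph(cbind(c(0, 0), c(0, 3)), k = 1)
  expect_equal(nrow(g), 1)
  g <- build_neighbor_graph(cbind(c(0, 0, 0), c(0, 5, 10)), k = 1)
  expect_equal(paste(g$i, g$j, sep = "-"), c("1-2", "2-3"))
  # single nucleus: empty edge set
  g1 <- build_neighbor_graph(cbind(1, 1), k = 5)
  expect_equal(nrow(g1), 0)
  set.seed(23)
  for (rep in 1:4) {
    n <- sample(5:50, 1)
    cen <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
    for (k in c(1, 3, 5)) {
      g <- build_neighbor_graph(cen, k = k)
      expect_identical(sort(paste(g$i, g$j, sep = "-")),
                       oracle_knn_edges(cen, k))
    }
  }
})

test_that("duplicate centroids are allowed with ties broken by id", {
  cen <- cbind(c(0, 0, 10), c(0, 0, 0))
  g <- build_neighbor_graph(cen, k = 1)
  # 1 and 2 coincide: both pick each other (tie -> lowest id); 3 picks 1
  expect_true(all(c("1-2", "1-3") %in% paste(g$i, g$j, sep = "-")))
})

test_that("CFLCM construction matches hand counts and the pair oracle", {
  g <- build_neighbor_graph(cbind(c(0, 0), c(0, 1)), k = 1)
  m <- build_cflcm(c(1L, 2L), g, n_levels = 2)
  expect_equal(m, matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  # all nuclei at the same level: single diagonal cell of mass 1
  m1 <- build_cflcm(rep(1L, 2), g, n_levels = 3)
  expect_equal(m1[1, 1], 1)
  expect_equal(sum(m1), 1)
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(4:20, 1)
    cen <- cbind(stats::runif(n, 0, 50), stats::runif(n, 0, 50))
    lev <- sample.int(4, n, replace = TRUE)
    g <- build_neighbor_graph(cen, k = 3)
    expect_equal(build_cflcm(lev, g, n_levels = 4),
                 oracle_cflcm(lev, g$i, g$j, 4),
                 ignore_attr = TRUE)
  }
})

test_that("CFLCMs are symmetric and normalized; the no-edge case is degenerate", {
  set.seed(5)
  cen <- cbind(stats::runif(12), stats::runif(12))
  g <- build_neighbor_graph(cen, k = 4)
  m <- build_cflcm(sample.int(8, 12, replace = TRUE), g, n_levels = 8)
  expect_equal(sum(m), 1)
  expect_equal(m, t(m), ignore_attr = TRUE)
  g0 <- build_neighbor_graph(cbind(1, 1), k = 3)
  m0 <- build_cflcm(1L, g0, n_levels = 4)
  expect_true(attr(m0, "degenerate"))
  expect_equal(sum(m0), 0)
  expect_true(all(cflcm_statistics(m0) == 0))
})

test_that("CFLCM statistics match closed-form values and definitional bounds", {
  # all mass at one diagonal cell
  m <- matrix(0, 4, 4); m[2, 2] <- 1
  s <- cflcm_statistics(m)
  expect_equal(unname(s["asm"]), 1)
  expect_equal(unname(s["entropy"]), 0)
  expect_equal(unname(s["contrast"]), 0)
  expect_equal(unname(s["max_probability"]), 1)
  s2 <- cflcm_statistics(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(unname(s2["contrast"]), 1)
  expect_equal(unname(s2["asm"]), 0.5)
  set.seed(17)
  for (rep in 1:5) {
    a <- matrix(stats::runif(16), 4)
    a <- (a + t(a)); a <- a / sum(a)
    s <- cflcm_statistics(a)
    expect_gte(unname(s["entropy"]), 0)
    expect_lte(unname(s["asm"]), 1)
    expect_equal(unname(s["max_probability"]), max(a))
  }
  expect_error(cflcm_statistics(matrix(1, 3, 3)),
               class = "nucleoprog_contract_error")
})

test_that("ROI aggregation emits a frozen-order 960-vector for 80 features", {
  tab <- generate_nucleus_table(20, seed = 3)
  rv <- aggregate_roi(tab)
  expect_equal(ncol(rv) - 3, 960)
  expect_identical(
    names(rv)[4:15],
    paste0("area_", c("mean", "sd", paste0("cflcm_", cflcm_stat_names())))
  )
  expect_true(all(is.finite(as.matrix(rv[, -(1:2)]))))
})

test_that("identical nuclei give zero SD and zero contrast everywhere", {
  feats <- matrix(2.5, 8, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  cen <- cbind(seq_len(8), rep(1, 8))
  tab <- toy_nucleus_table(cen, feats)
  rv <- aggregate_roi(tab)
  expect_equal(unname(unlist(rv[, paste0(c("f1", "f2", "f3"), "_sd")])),
               rep(0, 3))
  expect_equal(unname(unlist(rv[, paste0(c("f1", "f2", "f3"), "_cflcm_contrast")])),
               rep(0, 3))
})

test_that("the ROI vector is invariant to nucleus record permutation", {
  tab <- generate_nucleus_table(25, seed = 8)
  rv1 <- aggregate_roi(tab)
  set.seed(1)
  rv2 <- aggregate_roi(tab[sample.int(25), ])
  expect_equal(rv1, rv2)
})

test_that("a 5-nucleus toy ROI equals the straight-line reimplementation", {
  set.seed(12)
  cen <- cbind(stats::runif(5, 0, 10), stats::runif(5, 0, 10))
  feats <- matrix(stats::rnorm(5 * 4), 5, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  tab <- toy_nucleus_table(cen, feats)
  rv <- aggregate_roi(tab, min_nuclei = 5)
  oracle <- oracle_roi_vector(tab)
  expect_equal(unlist(rv[, -(1:3)]), oracle)
})

test_that("spatial mixing changes CFLCM contrast but not means or SDs", {
  # same per-nucleus feature values, two spatial arrangements on a 6x6 grid:
  # clustered (variants fill one half) vs interleaved (checkerboard)
  n <- 36
  grid <- expand.grid(r = 1:6, c = 1:6)
  variant_clustered <- grid$r <= 3
  variant_inter <- (grid$r + grid$c) %% 2 == 0
  vals <- ifelse(variant_clustered, 10, 0) + seq_len(n) * 1e-6
  f_clu <- matrix(vals, ncol = 1, dimnames = list(NULL, "f1"))
  # reassign the SAME multiset of values to the interleaved arrangement
  vals_int <- numeric(n)
  vals_int[variant_inter] <- vals[variant_clustered]
  vals_int[!variant_inter] <- vals[!variant_clustered]
  f_int <- matrix(vals_int, ncol = 1, dimnames = list(NULL, "f1"))
  tab_clu <- toy_nucleus_table(as.matrix(grid) * 10, f_clu)
  tab_int <- toy_nucleus_table(as.matrix(grid) * 10, f_int)
  rv_clu <- aggregate_roi(tab_clu, n_levels = 2)
  rv_int <- aggregate_roi(tab_int, n_levels = 2)
  expect_equal(rv_clu$f1_mean, rv_int$f1_mean)
  expect_equal(rv_clu$f1_sd, rv_int$f1_sd)
  expect_gt(rv_int$f1_cflcm_contrast, 3 * rv_clu$f1_cflcm_contrast)
})

test_that("the generator's mixing control reproduces the same contrast ordering", {
  t_clu <- generate_nucleus_table(60, feature_names = paste0("g", 1:4),
                                  variant_shift = 8, mixing = 0,
                                  variant_features = 1:2, seed = 44)
  t_int <- generate_nucleus_table(60, feature_names = paste0("g", 1:4),
                                  variant_shift = 8, mixing = 1,
                                  variant_features = 1:2, seed = 44)
  rv_clu <- aggregate_roi(t_clu)
  rv_int <- aggregate_roi(t_int)
  expect_gt(rv_int$g1_cflcm_contrast, rv_clu$g1_cflcm_contrast)
})

test_that("undersized ROIs are skipped with a logged reason", {
  tab <- generate_nucleus_table(3, seed = 2)
  expect_warning(out <- aggregate_roi(tab, min_nuclei = 5),
                 class = "nucleoprog_skip_roi_warning")
  expect_equal(nrow(out), 0)
})
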