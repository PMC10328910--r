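# Cohort grouping, horizon models, probability aggregation, quadrants

test_that("group assignment follows the four-group timing scheme", {
  expect_equal(assign_group(TRUE, 36), "A")
  expect_equal(assign_group(TRUE, 60), "A")
  expect_equal(assign_group(TRUE, 90), "B")
  expect_equal(assign_group(FALSE, 60), "C")
  expect_equal(assign_group(FALSE, 150), "D")
  expect_true(is.na(assign_group(FALSE, 48)))  # < 5 years follow-up: excluded
  expect_warning(g <- assign_group(TRUE, 145),
                 class = "nucleoprog_late_recurrence_warning")
  expect_true(is.na(g))
})

test_that("horizon labels: 5y is A vs rest; 10y is A/B vs D with C unlabeled", {
  cohort <- tibble::tibble(case_id = paste0("c", 1:4),
                           group = c("A", "B", "C", "D"))
  l5 <- build_label_sets(cohort, "5y")
  expect_identical(l5$label, c(TRUE, FALSE, FALSE, FALSE))
  l10 <- build_label_sets(cohort, "10y")
  expect_identical(l10$label, c(TRUE, TRUE, NA, FALSE))
})

test_that("the stratified split partitions every case exactly once, deterministically", {
  cohort <- tibble::tibble(case_id = paste0("c", 1:4),
                           group = c("A", "B", "C", "D"))
  s1 <- split_cohort(cohort, seed = 2)
  expect_setequal(s1$case_id, cohort$case_id)
  expect_true(all(s1$split %in% c("training", "test")))
  s2 <- split_cohort(cohort, seed = 2)
  expect_identical(s1, s2)
})

test_that("study-sized groups with pinned test counts give the 5-year bookkeeping", {
  cohort <- tibble::tibble(
    case_id = sprintf("c%03d", 1:131),
    group = rep(c("A", "B", "C", "D"), c(40, 22, 37, 32))
  )
  s <- split_cohort(cohort, seed = 7, n_test = c(A = 10, B = 4, C = 9, D = 8))
  l5 <- build_label_sets(s, "5y")
  tab <- table(l5$label, l5$split)
  expect_equal(tab["TRUE", "training"], 30)
  expect_equal(tab["TRUE", "test"], 10)
  expect_equal(tab["FALSE", "training"], 70)
  expect_equal(tab["FALSE", "test"], 21)
  # 10-year bookkeeping: 94 labeled cases, 72 training / 22 test
  l10 <- build_label_sets(s, "10y")
  lab10 <- l10[!is.na(l10$label), ]
  expect_equal(nrow(lab10), 94)
  expect_equal(sum(lab10$split == "training"), 72)
  expect_equal(sum(lab10$split == "test"), 22)
})

test_that("an empty group warns and the rest still split", {
  cohort <- tibble::tibble(case_id = paste0("c", 1:8),
                           group = rep(c("A", "B"), 4))
  expect_warning(s <- split_cohort(cohort, seed = 1),
                 class = "nucleoprog_stratification_warning")
  expect_setequal(s$case_id, cohort$case_id)
})

make_separable_training <- function(n_cases_pos = 6, n_cases_neg = 6,
                                    rois = 3, gap = 5, seed = 10) {
  withr::with_seed(seed, {
    feats <- paste0("v", 1:6)
    make <- function(cid, shift) {
      purrr::map(seq_len(rois), function(r) {
        tibble::tibble(case_id = cid, roi_id = paste0("r", r),
                       !!!stats::setNames(
                         as.list(stats::rnorm(6, mean = shift)), feats))
      }) |> dplyr::bind_rows()
    }
    pos <- purrr::map(seq_len(n_cases_pos),
                      function(i) make(sprintf("p%02d", i), gap)) |>
      dplyr::bind_rows()
    neg <- purrr::map(seq_len(n_cases_neg),
                      function(i) make(sprintf("n%02d", i), 0)) |>
      dplyr::bind_rows()
    feats_tbl <- dplyr::bind_rows(pos, neg)
    labels <- tibble::tibble(
      case_id = unique(feats_tbl$case_id),
      label = grepl("^p", unique(feats_tbl$case_id))
    )
    list(features = feats_tbl, labels = labels)
  })
}

test_that("a linearly separable training set is fit to 100% ROI accuracy", {
  d <- make_separable_training(gap = 5)
  m <- train_horizon_model(d$features, d$labels, "5y")
  expect_equal(accuracy(m$training_confusion), 100)
  expect_s3_class(m, "horizon_model")
})

test_that("the decision value is an affine function of the input", {
  d <- make_separable_training(gap = 3)
  m <- train_horizon_model(d$features, d$labels, "5y")
  probe <- function(x) {
    xz <- scale(matrix(x, nrow = 1, dimnames = list(NULL, m$features)),
                center = m$center, scale = m$scale)
    attr(stats::predict(m$fit, xz, decision.values = TRUE),
         "decision.values")[1]
  }
  set.seed(3)
  a <- stats::rnorm(6); b <- stats::rnorm(6)
  expect_equal(probe((a + b) / 2), (probe(a) + probe(b)) / 2,
               tolerance = 1e-6)
  # and tidy() exposes the same affine map explicitly
  w <- tidy(m)
  expect_equal(nrow(w), 7)
  za <- (a - m$center) / m$scale
  expect_equal(unname(sum(w$estimate[-1] * za) + w$estimate[1]),
               unname(probe(a)), tolerance = 1e-6)
})

test_that("duplicating every training ROI leaves the separable decision boundary unchanged", {
  d <- make_separable_training(gap = 5)
  m1 <- train_horizon_model(d$features, d$labels, "5y")
  dup <- dplyr::bind_rows(
    d$features,
    dplyr::mutate(d$features, roi_id = paste0(.data$roi_id, "_dup")))
  m2 <- train_horizon_model(dup, d$labels, "5y")
  w1 <- tidy(m1)$estimate
  w2 <- tidy(m2)$estimate
  expect_equal(w1, w2, tolerance = 0.02)  # solver stopping tolerance
})

test_that("permuted labels give test accuracy near the majority-class rate", {
  set.seed(99)
  d <- make_separable_training(n_cases_pos = 10, n_cases_neg = 10,
                               rois = 3, gap = 0, seed = 15)
  # gap 0: no signal at all; train/test split by case
  train_ids <- d$labels$case_id[c(1:7, 11:17)]
  test_ids <- setdiff(d$labels$case_id, train_ids)
  m <- train_horizon_model(
    dplyr::filter(d$features, .data$case_id %in% train_ids),
    d$labels, "5y")
  pred <- predict_case(m, dplyr::filter(d$features,
                                        .data$case_id %in% test_ids))
  truth <- d$labels$label[match(pred$case_id, d$labels$case_id)]
  acc <- mean(pred$call == truth)
  expect_lt(acc, 0.95)  # far from the perfect accuracy a real signal gives
})

test_that("single-class training is an unlearnable error", {
  d <- make_separable_training()
  d$labels$label <- TRUE
  expect_error(train_horizon_model(d$features, d$labels, "5y"),
               class = "nucleoprog_unlearnable_error")
})

test_that("case probability is the arithmetic mean of ROI probabilities", {
  # probability identity checked on the aggregation itself
  d <- make_separable_training(gap = 5)
  m <- train_horizon_model(d$features, d$labels, "5y")
  roi_p <- predict_roi(m, d$features)
  case_p <- predict_case(m, d$features)
  manual <- tapply(roi_p$probability, roi_p$case_id, mean)
  expect_equal(case_p$probability,
               as.numeric(manual[case_p$case_id]))
  expect_identical(case_p$call, case_p$probability > 0.5)
  expect_true(all(case_p$probability >= 0 & case_p$probability <= 1))
  expect_error(predict_case(m, d$features[0, ]),
               class = "nucleoprog_empty_case_error")
})

test_that("the quadrant combiner maps the four reference points correctly", {
  d <- combine_horizons(c(0.8, 0.3, 0.2, 0.7), c(0.9, 0.7, 0.1, 0.2))
  expect_identical(d$quadrant, c("Q1", "Q2", "Q3", "Q4"))
  expect_identical(d$predicted_timing,
                   c("recur_within_5y", "recur_5_to_10y",
                     "recurrence_free_10y", "contradictory"))
  # a case at exactly 0.50 sits on the non-recurrence side
  expect_identical(combine_horizons(0.5, 0.5)$quadrant, "Q3")
  expect_error(combine_horizons(1.2, 0.5),
               class = "nucleoprog_contract_error")
})

test_that("the quadrant categories partition the unit square", {
  set.seed(4)
  p5 <- c(stats::runif(400), 0, 1, 0.5, 0.5, 0.5)
  p10 <- c(stats::runif(400), 0, 1, 0.5, 0, 1)
  d <- combine_horizons(p5, p10)
  expect_false(any(is.na(d$quadrant)))
  expect_true(all(d$quadrant %in% paste0("Q", 1:4)))
  # each point satisfies exactly one quadrant predicate
  hits <- (p5 > 0.5 & p10 > 0.5) + (p5 <= 0.5 & p10 > 0.5) +
    (p5 <= 0.5 & p10 <= 0.5) + (p5 > 0.5 & p10 <= 0.5)
  expect_true(all(hits == 1))
})
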