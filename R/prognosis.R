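# ---- cohort grouping, horizon labels, split --------------------------------

#' Assign the recurrence-timing group of a case
#'
#' Maps (recurrence flag, follow-up or time-to-recurrence in months) to the
#' four-group scheme: A = recurrence within 5 years; B = recurrence between 5
#' and 10 years; C = recurrence-free with 5-10 years of follow-up; D =
#' recurrence-free for more than 10 years. Recurrence-free cases followed for
#' less than 5 years are excluded (`NA`), as are the out-of-scheme recurrences
#' after 10 years (with a warning).
#'
#' @param recurrence Logical vector.
#' @param months Positive numeric vector, same length.
#' @return Character vector in `c("A","B","C","D")`, `NA` for excluded cases.
#' @export
assign_group <- function(recurrence, months) {
  stopifnot(length(recurrence) == length(months), all(months > 0))
  recurrence <- as.logical(recurrence)
  out <- rep(NA_character_, length(months))
  out[recurrence & months <= 60] <- "A"
  out[recurrence & months > 60 & months <= 120] <- "B"
  out[!recurrence & months >= 60 & months <= 120] <- "C"
  out[!recurrence & months > 120] <- "D"
  late <- recurrence & months > 120
  if (any(late)) {
    rlang::warn(sprintf(
      "%d case(s) with recurrence after 120 months fall outside the group scheme and are excluded.",
      sum(late)), class = "nucleoprog_late_recurrence_warning")
  }
  out
}

#' Attach horizon-specific training labels to a cohort
#'
#' For the 5-year horizon, group A is positive and B, C, D negative. For the
#' 10-year horizon, A and B are positive, D negative, and C is unlabeled
#' (`NA`): its follow-up is too short to establish 10-year recurrence-free
#' status, so C cases are carried through as prediction-only.
#'
#' @param cohort Tibble with at least a `group` column (values A-D).
#' @param horizon `"5y"` or `"10y"`.
#' @return `cohort` with an added logical `label` column (`NA` = unlabeled).
#' @export
build_label_sets <- function(cohort, horizon = c("5y", "10y")) {
  horizon <- match.arg(horizon)
  stopifnot("group" %in% names(cohort))
  lab <- if (horizon == "5y") {
    cohort$group == "A"
  } else {
    dplyr::case_when(cohort$group %in% c("A", "B") ~ TRUE,
                     cohort$group == "D" ~ FALSE,
                     TRUE ~ NA)
  }
  dplyr::mutate(cohort, label = lab)
}

#' Group-stratified train/test split of a cohort
#'
#' Randomly assigns each case to the training or test set, stratified by
#' group, at the given training proportion (3:1 by default). `n_test` can pin
#' the exact per-group test counts (e.g. `c(A = 10, B = 4, C = 9, D = 8)` to
#' reproduce a 131-case bookkeeping of 100 training and 31 test cases). The
#' split is deterministic for a fixed seed; every case is assigned exactly
#' once.
#'
#' @param cohort Tibble with `case_id` and `group` columns.
#' @param prop_train Training proportion (default 0.75).
#' @param seed Integer seed.
#' @param n_test Optional named integer vector of per-group test counts.
#' @return `cohort` with an added `split` column (`"training"`/`"test"`).
#' @export
split_cohort <- function(cohort, prop_train = 0.75, seed = 1L, n_test = NULL) {
  stopifnot(all(c("case_id", "group") %in% names(cohort)))
  groups <- unique(cohort$group)
  empty <- setdiff(c("A", "B", "C", "D"), groups)
  if (length(empty) > 0L) {
    rlang::warn(sprintf("Empty group(s): %s; remaining groups split as given.",
                        paste(empty, collapse = ", ")),
                class = "nucleoprog_stratification_warning")
  }
  withr::with_seed(seed, {
    assign_tbl <- cohort |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(function(df, key) {
        nt <- if (!is.null(n_test) && key$group %in% names(n_test)) {
          n_test[[key$group]]
        } else {
          round(nrow(df) * (1 - prop_train))
        }
        nt <- min(nt, nrow(df))
        test_idx <- sample.int(nrow(df), nt)
        df$split <- "training"
        df$split[test_idx] <- "test"
        df
      }) |>
      dplyr::ungroup()
  })
  assign_tbl[match(cohort$case_id, assign_tbl$case_id), ]
}

# ---- horizon model ----------------------------------------------------------

#' Train a horizon-specific recurrence classifier on ROI feature vectors
#'
#' Fits a linear-kernel support vector machine (via e1071, the engine the
#' underlying study names) on z-scored ROI feature vectors. Every ROI
#' inherits its case's horizon label; cases with `label = NA` are dropped from
#' training. Feature standardization parameters (per-feature training mean
#' and SD; SD 0 replaced by 1) are stored in the model and re-applied at
#' prediction time. Probabilities come from the standard sigmoid-on-margin
#' (Platt) calibration.
#'
#' @param roi_features Tibble from [aggregate_rois()]: `case_id`, `roi_id`,
#'   feature columns.
#' @param labeled_cohort Tibble with `case_id` and logical `label`.
#' @param horizon `"5y"` or `"10y"` (metadata tag).
#' @param cost SVM cost parameter (library default 1; recorded in the model).
#' @return An object of class `horizon_model`.
#' @export
train_horizon_model <- function(roi_features, labeled_cohort,
                                horizon = c("5y", "10y"), cost = 1) {
  horizon <- match.arg(horizon)
  dat <- dplyr::inner_join(
    roi_features,
    dplyr::select(labeled_cohort, "case_id", "label"),
    by = "case_id"
  )
  dat <- dplyr::filter(dat, !is.na(.data$label))
  feats <- setdiff(names(dat),
                   c("case_id", "roi_id", "n_nuclei", "label"))
  if (nrow(dat) == 0L || length(unique(dat$label)) < 2L) {
    rlang::abort("Training set must contain ROIs of both classes.",
                 class = "nucleoprog_unlearnable_error")
  }
  x <- as.matrix(dat[, feats])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xz <- scale(x, center = center, scale = scale_)
  y <- factor(ifelse(dat$label, "rec", "nonrec"), levels = c("nonrec", "rec"))
  fit <- e1071::svm(xz, y, kernel = "linear", cost = cost,
                    scale = FALSE, probability = TRUE)
  pred_train <- stats::predict(fit, xz)
  train_cm <- confusion(dat$label, pred_train == "rec",
                        level = "ROI", split = "training")
  structure(
    list(fit = fit, horizon = horizon, features = feats,
         center = center, scale = scale_, cost = cost,
         n_rois = nrow(dat), n_cases = length(unique(dat$case_id)),
         training_confusion = train_cm),
    class = "horizon_model"
  )
}

#' @export
print.horizon_model <- function(x, ...) {
  cat(sprintf(
    "<horizon_model %s> linear SVM on %d features; %d training ROIs from %d cases; training ROI accuracy %.1f%%\n",
    x$horizon, length(x$features), x$n_rois, x$n_cases,
    accuracy(x$training_confusion)))
  invisible(x)
}

# standardize a feature matrix with the model's training parameters
model_design <- function(model, roi_features) {
  missing <- setdiff(model$features, names(roi_features))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("ROI features missing %d model columns (e.g. %s).",
                         length(missing), missing[1]),
                 class = "nucleoprog_contract_error")
  }
  x <- as.matrix(roi_features[, model$features])
  scale(x, center = model$center, scale = model$scale)
}

#' Per-ROI recurrence probabilities
#'
#' @param model A [train_horizon_model()] fit.
#' @param roi_features ROI feature tibble.
#' @return Tibble `case_id`, `roi_id`, `probability`.
#' @export
predict_roi <- function(model, roi_features) {
  stopifnot(inherits(model, "horizon_model"))
  xz <- model_design(model, roi_features)
  pred <- stats::predict(model$fit, xz, probability = TRUE)
  p <- attr(pred, "probabilities")[, "rec"]
  tibble::tibble(case_id = roi_features$case_id,
                 roi_id = roi_features$roi_id,
                 probability = unname(p))
}

#' Case-level recurrence probability by ROI averaging
#'
#' The case probability is the arithmetic mean of the case's ROI recurrence
#' probabilities; the binary call is recurrence iff the probability is
#' strictly greater than 0.50 (a tie at exactly 0.50 is the non-recurrence
#' side, since recurrence is defined as "more than 50%").
#'
#' @inheritParams predict_roi
#' @return Tibble `case_id`, `probability`, `call` (logical), `n_rois`.
#' @export
predict_case <- function(model, roi_features) {
  if (nrow(roi_features) == 0L) {
    rlang::abort("Case has no ROI feature vectors.",
                 class = "nucleoprog_empty_case_error")
  }
  predict_roi(model, roi_features) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(probability = mean(.data$probability),
                     n_rois = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(call = .data$probability > 0.5) |>
    dplyr::select("case_id", "probability", "call", "n_rois")
}

# ---- dual-horizon quadrant combiner ----------------------------------------

#' Combine 5- and 10-year probabilities into a recurrence-timing quadrant
#'
#' Against the 0.50 cutoff, the (p5, p10) plane partitions into four
#' quadrants: Q1 (both > 0.5) predicts recurrence within 5 years; Q2 (p5 <=
#' 0.5, p10 > 0.5) recurrence between 5 and 10 years; Q3 (both <= 0.5)
#' recurrence-free within 10 years; Q4 (p5 > 0.5, p10 <= 0.5) a contradictory
#' prediction. Every (p5, p10) in the unit square maps to exactly one
#' quadrant.
#'
#' @param p5,p10 Numeric vectors of case probabilities in `[0, 1]`.
#' @param case_id Optional identifiers.
#' @return Tibble `case_id`, `p5`, `p10`, `quadrant` (Q1-Q4),
#'   `predicted_timing`.
#' @export
combine_horizons <- function(p5, p10, case_id = NULL) {
  stopifnot(length(p5) == length(p10))
  if (any(p5 < 0 | p5 > 1 | p10 < 0 | p10 > 1, na.rm = TRUE)) {
    rlang::abort("Probabilities must lie in [0, 1].",
                 class = "nucleoprog_contract_error")
  }
  if (is.null(case_id)) case_id <- paste0("case", seq_along(p5))
  quadrant <- dplyr::case_when(
    p5 > 0.5 & p10 > 0.5 ~ "Q1",
    p5 <= 0.5 & p10 > 0.5 ~ "Q2",
    p5 <= 0.5 & p10 <= 0.5 ~ "Q3",
    p5 > 0.5 & p10 <= 0.5 ~ "Q4"
  )
  timing <- c(Q1 = "recur_within_5y", Q2 = "recur_5_to_10y",
              Q3 = "recurrence_free_10y", Q4 = "contradictory")[quadrant]
  tibble::tibble(case_id = case_id, p5 = p5, p10 = p10,
                 quadrant = quadrant, predicted_timing = unname(timing))
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a horizon model into per-feature linear weights
#'
#' The linear SVM decision value is an affine function `w . x + b` of the
#' z-scored input; `tidy()` returns `w` per feature plus the intercept term.
#'
#' @param x A `horizon_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.horizon_model <- function(x, ...) {
  w <- drop(crossprod(x$fit$coefs, x$fit$SV))
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(-x$fit$rho, unname(w)))
}

#' One-row summary of a horizon model
#'
#' @param x A `horizon_model`.
#' @param ... Unused.
#' @return Tibble with horizon, training sizes, cost, support-vector count
#'   and training ROI accuracy.
#' @export
glance.horizon_model <- function(x, ...) {
  tibble::tibble(horizon = x$horizon, n_rois = x$n_rois, n_cases = x$n_cases,
                 n_features = length(x$features), cost = x$cost,
                 n_support_vectors = nrow(x$fit$SV),
                 training_accuracy = accuracy(x$training_confusion))
}
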