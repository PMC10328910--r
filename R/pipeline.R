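# ---- end-to-end study runner and reporting ---------------------------------

#' Run the dual-horizon recurrence study on a cohort of ROI feature vectors
#'
#' The full modeling stage: a group-stratified case-level 3:1 split (no case
#' contributes ROIs to both sides), horizon-specific labeling (5y: A vs
#' B/C/D; 10y: A/B vs D with C prediction-only), linear-SVM training on
#' training-set ROIs, ROI- and case-level prediction on the test set, and the
#' dual-horizon quadrant combination for the 5-year test cases (the cases the
#' timing plot evaluates, including prediction-only group C).
#'
#' @param roi_features Tibble from [aggregate_rois()].
#' @param cohort Tibble with `case_id`, `group` (A-D), and ideally
#'   `recurrence`, `months`.
#' @param seed Integer seed for the split.
#' @param prop_train Training proportion (default 0.75).
#' @param n_test Optional per-group test counts (see [split_cohort()]).
#' @param cost SVM cost.
#' @return An object of class `recurrence_study`: the split cohort, the two
#'   `horizon_model`s, per-horizon ROI/case predictions and test labels, and
#'   the dual-prediction table.
#' @export
run_recurrence_study <- function(roi_features, cohort, seed = 1L,
                                 prop_train = 0.75, n_test = NULL, cost = 1) {
  cohort <- split_cohort(cohort, prop_train = prop_train, seed = seed,
                         n_test = n_test)
  horizons <- c("5y", "10y")
  fits <- purrr::map(horizons, function(h) {
    labeled <- build_label_sets(cohort, h)
    train_cases <- dplyr::filter(labeled, .data$split == "training",
                                 !is.na(.data$label))
    test_cases <- dplyr::filter(labeled, .data$split == "test")
    train_feats <- dplyr::semi_join(roi_features, train_cases, by = "case_id")
    model <- train_horizon_model(train_feats, train_cases, horizon = h,
                                 cost = cost)
    test_feats <- dplyr::semi_join(roi_features, test_cases, by = "case_id")
    roi_pred <- predict_roi(model, test_feats) |>
      dplyr::left_join(dplyr::select(test_cases, "case_id", "label", "group"),
                       by = "case_id")
    case_pred <- predict_case(model, test_feats) |>
      dplyr::left_join(dplyr::select(test_cases, "case_id", "label", "group"),
                       by = "case_id")
    list(model = model, roi_pred = roi_pred, case_pred = case_pred)
  })
  names(fits) <- horizons

  # dual prediction for the 5y test cases (all four groups, C prediction-only)
  test5 <- dplyr::filter(cohort, .data$split == "test")
  p5 <- fits[["5y"]]$case_pred
  p10_feats <- dplyr::semi_join(roi_features, test5, by = "case_id")
  p10 <- predict_case(fits[["10y"]]$model, p10_feats)
  dual <- combine_horizons(
    p5 = p5$probability[match(test5$case_id, p5$case_id)],
    p10 = p10$probability[match(test5$case_id, p10$case_id)],
    case_id = test5$case_id
  ) |>
    dplyr::left_join(dplyr::select(cohort, "case_id", "group"), by = "case_id")

  structure(
    list(cohort = cohort, seed = seed,
         models = list(`5y` = fits[["5y"]]$model, `10y` = fits[["10y"]]$model),
         roi_predictions = list(`5y` = fits[["5y"]]$roi_pred,
                                `10y` = fits[["10y"]]$roi_pred),
         case_predictions = list(`5y` = fits[["5y"]]$case_pred,
                                 `10y` = fits[["10y"]]$case_pred),
         dual = dual),
    class = "recurrence_study"
  )
}

#' @export
print.recurrence_study <- function(x, ...) {
  cat(sprintf("<recurrence_study> %d cases (%d test); seed %d\n",
              nrow(x$cohort), sum(x$cohort$split == "test"), x$seed))
  qt <- table(x$dual$group, x$dual$quadrant)
  print(qt)
  invisible(x)
}

#' Assemble the result bundle of a study run
#'
#' Emits the six confusion matrices mirroring a dual-horizon result report (2
#' horizons x {training ROI, test ROI, test case}; unlabeled prediction-only
#' cases are excluded from the matrices), the quadrant table of the dual
#' prediction, the per-case scatter data (p5, p10, group), and a manifest of
#' settings. Cohort cases that received no prediction are listed under
#' `missing_cases`, never silently dropped.
#'
#' @param study A [run_recurrence_study()] result.
#' @return An object of class `result_bundle`.
#' @export
report_run <- function(study) {
  stopifnot(inherits(study, "recurrence_study"))
  cms <- list()
  for (h in c("5y", "10y")) {
    cms[[paste0(h, "_train_roi")]] <- study$models[[h]]$training_confusion
    rp <- dplyr::filter(study$roi_predictions[[h]], !is.na(.data$label))
    cms[[paste0(h, "_test_roi")]] <- if (nrow(rp) > 0) {
      confusion(rp$label, rp$probability > 0.5, level = "ROI", split = "test")
    } else NULL
    cp <- dplyr::filter(study$case_predictions[[h]], !is.na(.data$label))
    cms[[paste0(h, "_test_case")]] <- if (nrow(cp) > 0) {
      confusion(cp$label, cp$call, level = "case", split = "test")
    } else NULL
  }
  empty_splits <- names(cms)[vapply(cms, is.null, logical(1))]
  cms <- cms[!vapply(cms, is.null, logical(1))]

  predicted <- unique(study$dual$case_id)
  missing <- setdiff(dplyr::filter(study$cohort, .data$split == "test")$case_id,
                     predicted)
  structure(
    list(
      confusions = cms,
      accuracies = purrr::map_dbl(cms, accuracy),
      quadrant_table = dplyr::count(study$dual, .data$group, .data$quadrant),
      scatter = dplyr::select(study$dual, "case_id", "p5", "p10", "group",
                              "quadrant", "predicted_timing"),
      missing_cases = missing,
      empty_splits = empty_splits,
      settings = list(seed = study$seed,
                      cost = study$models[["5y"]]$cost,
                      n_features = length(study$models[["5y"]]$features))
    ),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n accuracies (%):\n")
  print(round(x$accuracies, 1))
  invisible(x)
}

#' Write / read a result bundle (JSON + CSV)
#'
#' The confusion matrices, accuracies and settings go to
#' `<dir>/bundle.json`; the per-case scatter data to `<dir>/scatter.csv`.
#' `read_result_bundle()` restores an equivalent bundle, so serialization
#' round-trips losslessly.
#'
#' @param bundle A [report_run()] bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly; or the restored `result_bundle`.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    confusions = purrr::map(bundle$confusions, function(cm) {
      cm[c("tp", "fn", "fp", "tn", "level", "split")]
    }),
    accuracies = as.list(bundle$accuracies),
    quadrant_table = bundle$quadrant_table,
    missing_cases = bundle$missing_cases,
    empty_splits = bundle$empty_splits,
    settings = bundle$settings
  )
  jsonlite::write_json(json, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(bundle$scatter, file.path(dir, "scatter.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_result_bundle
#' @export
read_result_bundle <- function(dir) {
  x <- jsonlite::read_json(file.path(dir, "bundle.json"),
                           simplifyVector = TRUE)
  cms <- purrr::map(x$confusions, function(cm) {
    confusion_from_cells(cm$tp, cm$fn, cm$fp, cm$tn,
                         level = cm$level, split = cm$split)
  })
  structure(
    list(confusions = cms,
         accuracies = unlist(x$accuracies),
         quadrant_table = tibble::as_tibble(x$quadrant_table),
         scatter = tibble::as_tibble(
           utils::read.csv(file.path(dir, "scatter.csv"))),
         missing_cases = as.character(x$missing_cases %||% character(0)),
         empty_splits = as.character(x$empty_splits %||% character(0)),
         settings = x$settings),
    class = "result_bundle"
  )
}

#' Quadrant scatter plot of dual-horizon predictions
#'
#' The timing plot: each test case at (p5, p10), colored by its true group,
#' with the 0.50 cutoffs dividing the unit square into the four timing
#' quadrants.
#'
#' @param object A `recurrence_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recurrence_study <- function(object, ...) {
  dual <- object$dual
  ggplot2::ggplot(dual, ggplot2::aes(x = .data$p5, y = .data$p10,
                                     color = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(A = "#d62728", B = "#e6b800",
                                           C = "grey55", D = "#1f77b4")) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "5-year model recurrence probability",
                  y = "10-year model recurrence probability",
                  color = "Group") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.recurrence_study
#' @param study A `recurrence_study`.
#' @export
plot_quadrants <- function(study) autoplot.recurrence_study(study)
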