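# ---- confusion matrices and accuracy ---------------------------------------

#' Build a 2x2 recurrence confusion matrix
#'
#' Tallies truth against prediction over the recurrence / non-recurrence
#' classes. The four counts partition the pairs, so the marginals reproduce
#' the total row and column of a printed result table.
#'
#' @param truth,predicted Logical vectors of equal length (>= 1); `TRUE` =
#'   recurrence.
#' @param level Optional tag, e.g. `"ROI"` or `"case"`.
#' @param split Optional tag, e.g. `"training"` or `"test"`.
#' @return An object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `fp`, `tn` and the tags.
#' @export
confusion <- function(truth, predicted, level = NULL, split = NULL) {
  if (length(truth) != length(predicted) || length(truth) < 1L) {
    rlang::abort("`truth` and `predicted` must have equal length >= 1.",
                 class = "nucleoprog_contract_error")
  }
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  structure(
    list(tp = sum(truth & predicted), fn = sum(truth & !predicted),
         fp = sum(!truth & predicted), tn = sum(!truth & !predicted),
         level = level, split = split),
    class = "confusion_matrix"
  )
}

#' Construct a confusion matrix from its four printed cells
#'
#' @param tp,fn,fp,tn Nonnegative counts.
#' @inheritParams confusion
#' @return A `confusion_matrix`.
#' @export
confusion_from_cells <- function(tp, fn, fp, tn, level = NULL, split = NULL) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 level = level, split = split),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  tag <- paste(c(x$split, x$level), collapse = " ")
  cat(sprintf("<confusion_matrix%s> accuracy %.1f%%\n",
              if (nzchar(tag)) paste0(" ", tag) else "", accuracy(x)))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(truth = c("rec(+)", "rec(-)"),
                              prediction = c("rec(+)", "rec(-)")))
  print(m)
  invisible(x)
}

#' Tidy a confusion matrix
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Long tibble `truth`, `prediction`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(
    truth = c(TRUE, TRUE, FALSE, FALSE),
    prediction = c(TRUE, FALSE, TRUE, FALSE),
    n = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Classification accuracy of a confusion matrix, in percent
#'
#' `100 * (tp + tn) / total`, rounded half-up to `digits` decimals for
#' reporting (result tables print one decimal). Use `digits = NULL` for the
#' raw value.
#'
#' @param cm A `confusion_matrix`.
#' @param digits Decimals for half-up rounding; `NULL` for unrounded.
#' @return Accuracy in `[0, 100]`.
#' @export
accuracy <- function(cm, digits = 1) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total <= 0) {
    rlang::abort("Confusion matrix has zero total.",
                 class = "nucleoprog_contract_error")
  }
  acc <- 100 * (cm$tp + cm$tn) / total
  if (is.null(digits)) acc else floor(acc * 10^digits + 0.5) / 10^digits
}
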