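#' Construct an ROI image
#'
#' An ROI (region of interest) image pairs a grayscale intensity matrix with
#' an integer label mask of the same dimensions. Label 0 is background; nuclei
#' are labeled `1..N` with every label present.
#'
#' @param intensity Numeric matrix of grayscale values (conventionally 0-255).
#' @param labels Integer matrix of the same dimensions; 0 = background.
#' @param roi_id,case_id Identifiers carried through downstream tables.
#'
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(intensity, labels, roi_id = "roi1", case_id = "case1") {
  stopifnot(is.matrix(intensity), is.matrix(labels))
  if (!identical(dim(intensity), dim(labels))) {
    rlang::abort("`intensity` and `labels` must have identical dimensions.",
                 class = "nucleoprog_dim_error")
  }
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (any(labels < 0L)) {
    rlang::abort("`labels` must be nonnegative integers.")
  }
  present <- sort(unique(labels[labels > 0L]))
  n <- length(present)
  if (n > 0L && !identical(present, seq_len(n))) {
    rlang::abort("Labels must be consecutive 1..N with every label present.",
                 class = "nucleoprog_label_error")
  }
  structure(
    list(intensity = intensity, labels = labels,
         roi_id = roi_id, case_id = case_id),
    class = "roi_image"
  )
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %s / %s: %d x %d px, %d nuclei\n",
              x$case_id, x$roi_id, nrow(x$labels), ncol(x$labels),
              n_nuclei(x)))
  invisible(x)
}

#' Number of labeled nuclei in an ROI image
#' @param roi An `roi_image`.
#' @return Integer count of distinct nonzero labels.
#' @export
n_nuclei <- function(roi) {
  stopifnot(inherits(roi, "roi_image"))
  length(unique(roi$labels[roi$labels > 0L]))
}

#' Write / read an ROI image as a TIFF pair
#'
#' The mask is stored as 16-bit and the intensity as 8-bit grayscale TIFF, the
#' formats typical of segmentation outputs. `read_roi_image()` inverts the
#' scaling so a write/read round trip is exact for integer-valued images.
#'
#' @param roi An `roi_image`.
#' @param path Base path without extension; writes `<path>_mask.tif` and
#'   `<path>_intensity.tif`.
#' @return `write_roi_image()` the two paths invisibly; `read_roi_image()` an
#'   `roi_image`.
#' @export
write_roi_image <- function(roi, path) {
  stopifnot(inherits(roi, "roi_image"))
  mask_path <- paste0(path, "_mask.tif")
  int_path <- paste0(path, "_intensity.tif")
  tiff::writeTIFF(roi$labels / 65535, mask_path, bits.per.sample = 16L)
  tiff::writeTIFF(pmin(pmax(roi$intensity, 0), 255) / 255, int_path,
                  bits.per.sample = 8L)
  invisible(c(mask = mask_path, intensity = int_path))
}

#' @rdname write_roi_image
#' @param roi_id,case_id Identifiers to attach to the read image.
#' @export
read_roi_image <- function(path, roi_id = "roi1", case_id = "case1") {
  labels <- round(tiff::readTIFF(paste0(path, "_mask.tif")) * 65535)
  intensity <- round(tiff::readTIFF(paste0(path, "_intensity.tif")) * 255)
  roi_image(intensity, labels, roi_id = roi_id, case_id = case_id)
}
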