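#' The default per-nucleus feature manifest
#'
#' The default manifest names exactly 80 features per nucleus: 20 size/shape
#' descriptors, 52 chromatin texture features (13 Haralick statistics at
#' offset distances 1, 2, 4 and 8 pixels, direction-pooled, symmetric, 8 gray
#' levels quantized per nucleus by min-max), and 8 radial intensity
#' distribution features (intensity fraction and pixel-share-normalized mean
#' fraction for 4 concentric rings). The name order is frozen; downstream ROI
#' aggregation multiplies it by 12 statistics to 960 ROI features.
#'
#' @param texture A [texture_settings()] list.
#' @param n_rings Number of radial rings.
#' @return An object of class `feature_manifest`: list with `names` (ordered
#'   feature names), `families` (one of shape/texture/radial per feature),
#'   `texture` settings and `n_rings`.
#' @export
default_manifest <- function(texture = texture_settings(), n_rings = 4L) {
  shape <- shape_feature_names()
  tex <- as.vector(vapply(
    texture$distances,
    function(d) paste0(haralick_stat_names(), "_d", d),
    character(13)
  ))
  radial <- c(paste0("radial_frac_r", seq_len(n_rings)),
              paste0("radial_meanfrac_r", seq_len(n_rings)))
  nm <- c(shape, tex, radial)
  stopifnot(!anyDuplicated(nm))
  structure(
    list(names = nm,
         families = c(rep("shape", length(shape)),
                      rep("texture", length(tex)),
                      rep("radial", length(radial))),
         texture = texture,
         n_rings = as.integer(n_rings)),
    class = "feature_manifest"
  )
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat(sprintf("<feature_manifest> %d features (%s)\n", length(x$names),
              paste(sprintf("%s: %d", names(table(x$families)),
                            as.integer(table(x$families))), collapse = ", ")))
  invisible(x)
}

#' @export
length.feature_manifest <- function(x) length(x$names)

#' Serialize / deserialize a feature manifest as JSON
#'
#' Round-trips losslessly: `read_manifest(write_manifest(m, f))` reproduces
#' `m` including the frozen name order.
#'
#' @param manifest A `feature_manifest`.
#' @param path File path for the JSON.
#' @return `write_manifest()` the path invisibly; `read_manifest()` a
#'   `feature_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "feature_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$texture <- texture_settings(x$texture$n_gray_levels, x$texture$distances,
                                x$texture$symmetric)
  x$n_rings <- as.integer(x$n_rings)
  structure(x, class = "feature_manifest")
}

#' Extract the per-nucleus feature table of an ROI
#'
#' Runs shape, texture and radial extraction for every labeled nucleus of an
#' ROI image and returns one row per nucleus with the centroid and the
#' manifest's features in its frozen column order. Rows are in ascending
#' `nucleus_id`. Feature values depend only on each nucleus's own pixels, so
#' renumbering labels permutes rows without changing any feature vector.
#'
#' @param roi An [roi_image()].
#' @param manifest A [default_manifest()]-style manifest.
#' @return A tibble with columns `case_id`, `roi_id`, `nucleus_id`,
#'   `centroid_row`, `centroid_col`, then one column per manifest feature
#'   (80 for the default manifest).
#' @export
extract_nucleus_table <- function(roi, manifest = default_manifest()) {
  stopifnot(inherits(roi, "roi_image"), inherits(manifest, "feature_manifest"))
  n <- n_nuclei(roi)
  if (n == 0L) {
    rlang::abort("ROI contains no labeled nuclei.",
                 class = "nucleoprog_empty_roi_error")
  }
  rows <- purrr::map(seq_len(n), function(id) {
    px <- which(roi$labels == id, arr.ind = TRUE)
    cen <- colMeans(px)
    fv <- c(
      extract_shape_features(roi$labels, id),
      extract_texture_features(roi$intensity, roi$labels, id,
                               settings = manifest$texture),
      extract_radial_features(roi$intensity, roi$labels, id,
                              n_rings = manifest$n_rings)
    )
    fv <- fv[manifest$names]
    tibble::tibble(
      case_id = roi$case_id, roi_id = roi$roi_id, nucleus_id = id,
      centroid_row = cen[[1]], centroid_col = cen[[2]],
      !!!stats::setNames(as.list(unname(fv)), manifest$names)
    )
  })
  dplyr::bind_rows(rows)
}
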