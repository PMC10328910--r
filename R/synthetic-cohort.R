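# ---- synthetic cohorts ------------------------------------------------------

#' Specify a synthetic recurrence cohort
#'
#' Group semantics follow the four-group timing scheme (A: recurrence within
#' 5 years; B: recurrence between 5 and 10 years; C: recurrence-free with
#' 5-10 years of follow-up; D: recurrence-free beyond 10 years). The
#' recurrence-group nuclear phenotypes are shifted relative to the
#' recurrence-free baseline by `effect_size` (per-nucleus standard-deviation
#' units): group A is shifted along both the early- and late-recurrence
#' feature axes, group B along the late axis only, so the A shift dominates
#' the B shift and the two horizons stay distinguishable. `effect_size = 0`
#' makes all groups exchangeable.
#'
#' @param n_cases_per_group Named counts for exactly the groups A, B, C, D.
#' @param rois_per_case ROIs generated per case (>= 1).
#' @param nuclei_per_roi Nuclei per ROI (>= 1).
#' @param effect_size Nonnegative phenotype separation (default 1).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases_per_group = c(A = 40, B = 22, C = 37, D = 32),
                        rois_per_case = 10L, nuclei_per_roi = 100L,
                        effect_size = 1, seed = 1L) {
  if (!setequal(names(n_cases_per_group), c("A", "B", "C", "D"))) {
    rlang::abort("`n_cases_per_group` must name exactly the groups A, B, C, D.")
  }
  stopifnot(all(n_cases_per_group >= 1), rois_per_case >= 1,
            nuclei_per_roi >= 1, effect_size >= 0)
  structure(
    list(n_cases_per_group = n_cases_per_group[c("A", "B", "C", "D")],
         rois_per_case = as.integer(rois_per_case),
         nuclei_per_roi = as.integer(nuclei_per_roi),
         effect_size = effect_size, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Write / read a cohort spec as JSON
#' @param spec A `cohort_spec`.
#' @param path JSON file path.
#' @return The path invisibly, or the restored `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$n_cases_per_group <- as.list(x$n_cases_per_group)  # keep group names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(unlist(x$n_cases_per_group), x$rois_per_case, x$nuclei_per_roi,
              x$effect_size, x$seed)
}

# Follow-up months per group; the timing windows match the group definitions
# (exact month distributions are a modeling choice, uniform within window).
draw_months <- function(group, n) {
  switch(group,
         A = stats::runif(n, 6, 59),
         B = stats::runif(n, 61, 119),
         C = stats::runif(n, 61, 119),
         D = stats::runif(n, 121, 200))
}

# Per-nucleus mean shifts (in SD units) of the two latent recurrence axes:
# the early axis occupies the first half of the feature list, the late axis
# the second half.
group_shift <- function(group, effect_size, n_features) {
  half <- n_features %/% 2
  shift <- numeric(n_features)
  if (group == "A") {
    shift[seq_len(half)] <- effect_size
    shift[(half + 1):n_features] <- effect_size
  } else if (group == "B") {
    shift[(half + 1):n_features] <- effect_size
  }
  shift
}

#' Generate a synthetic per-nucleus feature table directly
#'
#' The fast path of the synthetic generator: Gaussian per-nucleus features
#' with a given mean shift, plus a two-subpopulation structure ("base" vs
#' "variant" nuclei) whose spatial arrangement is controlled by `mixing`.
#' Variant nuclei carry an extra `variant_shift` on the features named by
#' `variant_features`. With `mixing = 0` the variant nuclei occupy one side
#' of the ROI (maximal spatial clustering); with `mixing = 1` variant status
#' is spatially random (full interleaving); intermediate values blend a
#' smooth spatial score with noise. Feature marginals are unaffected by
#' `mixing` — only the spatial arrangement changes, which is exactly what the
#' CFLCM statistics respond to.
#'
#' @param n_nuclei Number of nuclei.
#' @param feature_names Feature column names (default the 80-name manifest).
#' @param shift Mean shift per feature (length 1 or `length(feature_names)`).
#' @param variant_fraction Fraction of variant nuclei (default 0.5).
#' @param variant_shift Extra mean shift of variant nuclei (default 1).
#' @param variant_features Indices or names of features the variant shift
#'   touches (default the first quarter).
#' @param mixing Spatial interleaving in `[0, 1]` (default 0.5).
#' @param roi_size Side length of the (continuous) centroid domain.
#' @param case_id,roi_id Identifiers.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Per-nucleus tibble compatible with [aggregate_roi()].
#' @export
generate_nucleus_table <- function(n_nuclei,
                                   feature_names = default_manifest()$names,
                                   shift = 0, variant_fraction = 0.5,
                                   variant_shift = 1,
                                   variant_features = seq_len(max(1L, length(feature_names) %/% 4L)),
                                   mixing = 0.5, roi_size = 512,
                                   case_id = "case1", roi_id = "roi1",
                                   seed = NULL) {
  gen <- function() {
    p <- length(feature_names)
    shift_vec <- rep_len(shift, p)
    cen_r <- stats::runif(n_nuclei, 0, roi_size)
    cen_c <- stats::runif(n_nuclei, 0, roi_size)
    # spatially autocorrelated variant assignment: blend a smooth coordinate
    # score with iid noise, take the top variant_fraction
    score <- (1 - mixing) * (cen_r / roi_size) + mixing * stats::runif(n_nuclei)
    n_var <- round(variant_fraction * n_nuclei)
    variant <- rank(-score, ties.method = "first") <= n_var
    x <- matrix(stats::rnorm(n_nuclei * p), n_nuclei, p)
    x <- sweep(x, 2, shift_vec, "+")
    if (n_var > 0 && length(variant_features) > 0) {
      vf <- if (is.character(variant_features)) {
        match(variant_features, feature_names)
      } else variant_features
      x[variant, vf] <- x[variant, vf] + variant_shift
    }
    colnames(x) <- feature_names
    tibble::tibble(
      case_id = case_id, roi_id = roi_id, nucleus_id = seq_len(n_nuclei),
      centroid_row = cen_r, centroid_col = cen_c,
      !!!tibble::as_tibble(x)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic cohort
#'
#' Builds a cohort table (case id, group, recurrence flag, months) whose
#' (recurrence, months) pairs are consistent with [assign_group()] by
#' construction, plus per-case nuclear data. `mode = "table"` (the fast path)
#' draws per-nucleus feature tables directly — Gaussian features with
#' group-shifted means under the default 80-name manifest — ready for
#' [aggregate_rois()]. `mode = "image"` renders actual ROI images through
#' [generate_roi_image()] with group-shifted phenotypes (larger, more
#' eccentric, more coarsely textured nuclei for recurrence groups), for
#' small-scale end-to-end runs through the image feature extractor.
#'
#' Identical specs produce identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"table"` or `"image"`.
#' @param image_size Image side length for `mode = "image"`.
#' @return A list with `cohort` (tibble: `case_id`, `group`, `recurrence`,
#'   `months`) and either `nuclei` (combined per-nucleus tibble) or `images`
#'   (named list of `roi_image`s).
#' @export
generate_cohort <- function(spec, mode = c("table", "image"),
                            image_size = 192L) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  groups <- rep(names(spec$n_cases_per_group), spec$n_cases_per_group)
  n <- length(groups)
  case_ids <- sprintf("case%03d", seq_len(n))

  withr::with_seed(spec$seed, {
    months <- numeric(n)
    for (g in unique(groups)) {
      sel <- groups == g
      months[sel] <- draw_months(g, sum(sel))
    }
    cohort <- tibble::tibble(
      case_id = case_ids, group = groups,
      recurrence = groups %in% c("A", "B"), months = months
    )
    if (mode == "table") {
      p <- length(default_manifest()$names)
      nuclei <- purrr::map2(case_ids, groups, function(cid, g) {
        shift <- group_shift(g, spec$effect_size, p)
        purrr::map(seq_len(spec$rois_per_case), function(r) {
          generate_nucleus_table(
            n_nuclei = spec$nuclei_per_roi, shift = shift,
            case_id = cid, roi_id = sprintf("roi%02d", r), seed = NULL)
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
      list(cohort = cohort, nuclei = nuclei)
    } else {
      images <- list()
      for (ci in seq_len(n)) {
        g <- groups[ci]
        e <- spec$effect_size
        bump <- switch(g, A = e, B = 0.5 * e, 0)
        phen <- nucleus_phenotype(
          mean_area = 120 * (1 + 0.25 * bump),
          area_cv = 0.3 * (1 + 0.3 * bump),
          mean_eccentricity = min(0.95, 0.5 + 0.1 * bump),
          texture_contrast_level = 1 + bump
        )
        for (r in seq_len(spec$rois_per_case)) {
          id <- sprintf("%s_roi%02d", case_ids[ci], r)
          img <- generate_roi_image(
            phen, n_nuclei = spec$nuclei_per_roi, image_size = image_size,
            seed = sample.int(.Machine$integer.max, 1))
          img$case_id <- case_ids[ci]
          img$roi_id <- sprintf("roi%02d", r)
          images[[id]] <- img
        }
      }
      list(cohort = cohort, images = images)
    }
  })
}

#' Write a cohort table as CSV
#'
#' Columns `case_id`, `group`, `recurrence` (0/1), `months`.
#'
#' @param cohort Cohort tibble.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- dplyr::mutate(cohort, recurrence = as.integer(.data$recurrence))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- tibble::as_tibble(utils::read.csv(path))
  dplyr::mutate(x, recurrence = as.logical(.data$recurrence))
}
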