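#' Describe a synthetic nucleus phenotype
#'
#' Parameters of the ellipse-plus-texture model used by
#' [generate_roi_image()]. Nuclear areas are lognormal with mean `mean_area`
#' and coefficient of variation `area_cv`; eccentricities are Beta-distributed
#' around `mean_eccentricity`; chromatin texture is smoothed multiplicative
#' noise whose spatial frequency and amplitude grow with
#' `texture_contrast_level`.
#'
#' @param mean_area Mean nucleus area in pixels^2 (> 0).
#' @param area_cv Coefficient of variation of area (>= 0).
#' @param mean_eccentricity Mean ellipse eccentricity in `[0, 1)`.
#' @param texture_contrast_level Nonnegative scalar; 0 gives flat nuclei.
#' @param spatial_mixing Fraction in `[0, 1]` controlling how phenotype
#'   variants intermix across an ROI (0 = fully clustered, 1 = fully
#'   interleaved); used by the cohort generators.
#'
#' @return An object of class `nucleus_phenotype`.
#' @export
nucleus_phenotype <- function(mean_area = 150, area_cv = 0.3,
                              mean_eccentricity = 0.6,
                              texture_contrast_level = 1,
                              spatial_mixing = 0.5) {
  stopifnot(mean_area > 0, area_cv >= 0,
            mean_eccentricity >= 0, mean_eccentricity < 1,
            texture_contrast_level >= 0,
            spatial_mixing >= 0, spatial_mixing <= 1)
  structure(
    list(mean_area = mean_area, area_cv = area_cv,
         mean_eccentricity = mean_eccentricity,
         texture_contrast_level = texture_contrast_level,
         spatial_mixing = spatial_mixing),
    class = "nucleus_phenotype"
  )
}

# Smooth a standard-normal field with a separable Gaussian kernel and rescale
# to unit sd. sigma shrinks as the contrast level rises, so stronger phenotypes
# show finer-grained chromatin patterning.
smooth_noise_field <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)), , drop = FALSE]
    conv_rows <- function(m) {
      mp <- pad(m, half)
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(k)) out <- out + k[i] * mp[seq_len(nrow(m)) + i - 1L, , drop = FALSE]
      out
    }
    z <- conv_rows(z)
    z <- t(conv_rows(t(z)))
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

# Pixel set of an axis-rotated ellipse; returns arr.ind-style matrix or NULL
# if it falls outside the image.
ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  r0 <- floor(cr - a); r1 <- ceiling(cr + a)
  c0 <- floor(cc - a); c1 <- ceiling(cc + a)
  if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc) return(NULL)
  rr <- rep(r0:r1, times = c1 - c0 + 1)
  cc2 <- rep(c0:c1, each = r1 - r0 + 1)
  dr <- rr - cr; dc <- cc2 - cc
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  keep <- u * u + v * v <= 1
  if (!any(keep)) return(NULL)
  cbind(row = rr[keep], col = cc2[keep])
}

#' Generate a synthetic ROI image of non-overlapping textured nuclei
#'
#' Places `n_nuclei` rotated ellipses by rejection sampling (up to 1000
#' placement attempts per nucleus), with at least one background pixel between
#' nuclei so components are unambiguous. The intensity image has textured
#' values inside nuclei and a constant background. Identical arguments and
#' seed give bit-identical output.
#'
#' @param phenotype A [nucleus_phenotype()].
#' @param n_nuclei Number of nuclei to place (>= 1).
#' @param image_size Side length in pixels (square image) or `c(rows, cols)`.
#' @param seed Integer seed; the global RNG state is left untouched.
#'
#' @return An [roi_image()] whose mask holds labels `1..n_nuclei`.
#' @export
generate_roi_image <- function(phenotype, n_nuclei, image_size = 256L,
                               seed = 1L) {
  stopifnot(inherits(phenotype, "nucleus_phenotype"), n_nuclei >= 1)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  nr <- as.integer(image_size[1]); nc <- as.integer(image_size[2])

  withr::with_seed(seed, {
    labels <- matrix(0L, nr, nc)
    blocked <- matrix(FALSE, nr, nc)  # nuclei plus a 1-px halo
    sdlog <- sqrt(log(1 + phenotype$area_cv^2))
    meanlog <- log(phenotype$mean_area) - sdlog^2 / 2
    me <- phenotype$mean_eccentricity

    for (id in seq_len(n_nuclei)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        area <- stats::rlnorm(1, meanlog, sdlog)
        if (area < 4) next
        ecc <- if (me <= 0) 0 else stats::rbeta(1, me * 20, (1 - me) * 20)
        a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
        b <- a * sqrt(1 - ecc^2)
        theta <- stats::runif(1, 0, pi)
        if (2 * a + 4 >= min(nr, nc)) next  # cannot fit at any position
        cr <- stats::runif(1, a + 2, nr - a - 1)
        cc <- stats::runif(1, a + 2, nc - a - 1)
        px <- ellipse_pixels(cr, cc, a, b, theta, nr, nc)
        if (is.null(px)) next
        if (any(blocked[px])) next
        labels[px] <- id
        halo <- rbind(px,
                      cbind(px[, 1] + 1L, px[, 2]), cbind(px[, 1] - 1L, px[, 2]),
                      cbind(px[, 1], px[, 2] + 1L), cbind(px[, 1], px[, 2] - 1L))
        halo <- halo[halo[, 1] >= 1 & halo[, 1] <= nr &
                       halo[, 2] >= 1 & halo[, 2] <= nc, , drop = FALSE]
        blocked[halo] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) {
        rlang::abort(
          sprintf("Could not place nucleus %d after 1000 attempts; image too small for the requested density.", id),
          class = "nucleoprog_capacity_error"
        )
      }
    }

    tcl <- phenotype$texture_contrast_level
    sigma <- if (tcl > 0) 3 / (1 + tcl) else 2
    field <- smooth_noise_field(nr, nc, sigma)
    intensity <- matrix(30, nr, nc)
    inside <- labels > 0L
    amp <- 0.25 * tcl
    intensity[inside] <- 160 * (1 + amp * field[inside])
    intensity <- round(pmin(pmax(intensity, 1), 255))
    roi_image(intensity, labels)
  })
}
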