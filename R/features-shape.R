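# ---- low-level geometry helpers -------------------------------------------

# Weighted boundary-crack perimeter estimator (4-connectivity weight table:
# categories 1, sqrt(2) and (1+sqrt(2))/2 over the border-pixel neighbourhood
# code). Returns 0 for an isolated pixel, a known property of this estimator.
perimeter_crack <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bw
  sub <- function(m, ri, ci) m[ri, ci, drop = FALSE]
  core <- sub(pad, 2:(nr + 1L), 2:(nc + 1L))
  up    <- sub(pad, 1:nr, 2:(nc + 1L))
  down  <- sub(pad, 3:(nr + 2L), 2:(nc + 1L))
  left  <- sub(pad, 2:(nr + 1L), 1:nc)
  right <- sub(pad, 2:(nr + 1L), 3:(nc + 2L))
  border <- core & !(up & down & left & right)
  bp <- matrix(0L, nr + 2L, nc + 2L)
  bp[2:(nr + 1L), 2:(nc + 1L)] <- border
  code <- 10L * (sub(bp, 1:nr, 1:nc) + sub(bp, 1:nr, 3:(nc + 2L)) +
                   sub(bp, 3:(nr + 2L), 1:nc) + sub(bp, 3:(nr + 2L), 3:(nc + 2L))) +
    2L * (sub(bp, 1:nr, 2:(nc + 1L)) + sub(bp, 3:(nr + 2L), 2:(nc + 1L)) +
            sub(bp, 2:(nr + 1L), 1:nc) + sub(bp, 2:(nr + 1L), 3:(nc + 2L))) +
    sub(bp, 2:(nr + 1L), 2:(nc + 1L))
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(w[code[border] + 1L])
}

# Border pixels of a binary mask (4-connectivity).
border_pixels <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bw
  sub <- function(m, ri, ci) m[ri, ci, drop = FALSE]
  core <- sub(pad, 2:(nr + 1L), 2:(nc + 1L))
  border <- core & !(sub(pad, 1:nr, 2:(nc + 1L)) & sub(pad, 3:(nr + 2L), 2:(nc + 1L)) &
                       sub(pad, 2:(nr + 1L), 1:nc) & sub(pad, 2:(nr + 1L), 3:(nc + 2L)))
  which(border, arr.ind = TRUE)
}

# Euler number (4-connectivity) via the 2x2 quad-count formula.
euler_number4 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bw
  a <- pad[1:(nr + 1L), 1:(nc + 1L), drop = FALSE]
  b <- pad[1:(nr + 1L), 2:(nc + 2L), drop = FALSE]
  d <- pad[2:(nr + 2L), 1:(nc + 1L), drop = FALSE]
  e <- pad[2:(nr + 2L), 2:(nc + 2L), drop = FALSE]
  s <- a + b + d + e
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a == 1L & e == 1L) | (b == 1L & d == 1L)))
  (q1 - q3 + 2L * qd) / 4
}

# Convex hull of pixel centers: area as pixel count whose center lies inside
# the hull polygon, plus the hull vertex coordinates.
convex_hull_info <- function(rows, cols) {
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) <= 2L) {
    return(list(vertices = pts, convex_area = nrow(unique(cbind(rows, cols)))))
  }
  h <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  verts <- pts[h, , drop = FALSE]
  if (nrow(verts) <= 2L) {
    return(list(vertices = verts, convex_area = length(rows)))
  }
  nv <- nrow(verts)
  jj <- c(2:nv, 1L)
  signed2 <- sum(verts[, 2] * verts[jj, 1] - verts[jj, 2] * verts[, 1])
  if (abs(signed2) < 1e-9) {
    # degenerate (collinear) hull: the hull is the pixel set itself
    return(list(vertices = verts, convex_area = length(rows)))
  }
  sgn <- sign(signed2)
  # candidate pixels: bounding box grid
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  gr <- rep(r0:r1, times = c1 - c0 + 1L)
  gc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- rep(TRUE, length(gr))
  eps <- 1e-9
  for (i in seq_len(nv)) {
    j <- jj[i]
    ex <- verts[j, 2] - verts[i, 2]; ey <- verts[j, 1] - verts[i, 1]
    cx <- gc - verts[i, 2]; cy <- gr - verts[i, 1]
    inside <- inside & (sgn * (ex * cy - ey * cx) >= -eps)
  }
  list(vertices = verts, convex_area = sum(inside))
}

# Max Feret: max pairwise distance among hull vertices. Min Feret: min over
# hull edges of the max distance of vertices from the edge line (exact for
# convex polygons).
feret_diameters <- function(verts) {
  n <- nrow(verts)
  if (n == 1L) return(c(max = 0, min = 0))
  d <- as.matrix(stats::dist(verts))
  fmax <- max(d)
  if (n == 2L) return(c(max = fmax, min = 0))
  fmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- verts[j, 2] - verts[i, 2]; ey <- verts[j, 1] - verts[i, 1]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    dd <- abs(ex * (verts[, 1] - verts[i, 1]) -
                ey * (verts[, 2] - verts[i, 2])) / len
    fmin <- min(fmin, max(dd))
  }
  if (!is.finite(fmin)) fmin <- 0
  c(max = fmax, min = fmin)
}

#' Names of the default shape features
#' @return Character vector of length 20.
#' @export
shape_feature_names <- function() {
  c("area", "perimeter", "form_factor", "eccentricity", "solidity",
    "extent", "major_axis_length", "minor_axis_length", "orientation",
    "equivalent_diameter", "compactness", "max_feret_diameter",
    "min_feret_diameter", "bbox_height", "bbox_width", "euler_number",
    "convex_area", "mean_radius", "max_radius", "aspect_ratio")
}

#' Extract size and shape features for one nucleus
#'
#' Computes the 20 default size/shape descriptors of a labeled component:
#' pixel-count area, weighted boundary-crack perimeter, form factor
#' (`4*pi*area/perimeter^2`; may slightly exceed 1 on digitized disks, not
#' clamped), moment-based eccentricity, axis lengths and orientation
#' (radians, major axis vs. the column axis), solidity and convex area from
#' the pixel-center convex hull, bounding-box extent and dimensions,
#' equivalent diameter, compactness (`2*pi*E[d^2]/area`, 1 for a disk),
#' Feret diameters, Euler number, centroid-to-boundary mean/max radius, and
#' aspect ratio (`minor/major`, in `[0, 1]`).
#'
#' All features are invariant to translation of the nucleus within the image.
#'
#' @param labels Integer label matrix (0 = background).
#' @param nucleus_id Label to measure; must be present in `labels`.
#' @return Named numeric vector of length 20 (see [shape_feature_names()]).
#' @export
extract_shape_features <- function(labels, nucleus_id) {
  px <- which(labels == nucleus_id, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    rlang::abort(sprintf("Nucleus %s not present in the label mask.", nucleus_id),
                 class = "nucleoprog_missing_object_error")
  }
  rows <- px[, 1]; cols <- px[, 2]
  area <- nrow(px)

  # crop to the component's bounding box for the mask-based estimators
  r0 <- min(rows); c0 <- min(cols)
  bw <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  bw[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE

  perim <- perimeter_crack(bw)
  form_factor <- if (perim > 0) 4 * pi * area / perim^2 else 0

  cen_r <- mean(rows); cen_c <- mean(cols)
  dr <- rows - cen_r; dc <- cols - cen_c
  mu20 <- mean(dr^2); mu02 <- mean(dc^2); mu11 <- mean(dr * dc)
  common <- sqrt(4 * mu11^2 + (mu20 - mu02)^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  orientation <- if (common > 0) 0.5 * atan2(2 * mu11, mu02 - mu20) else 0

  hull <- convex_hull_info(rows, cols)
  solidity <- if (hull$convex_area > 0) area / hull$convex_area else 0
  fer <- feret_diameters(hull$vertices)

  bbox_h <- max(rows) - r0 + 1L
  bbox_w <- max(cols) - c0 + 1L
  extent <- area / (bbox_h * bbox_w)

  d2 <- dr^2 + dc^2
  compactness <- 2 * pi * mean(d2) / area

  bp <- border_pixels(bw)
  brad <- sqrt((bp[, 1] - (cen_r - r0 + 1))^2 + (bp[, 2] - (cen_c - c0 + 1))^2)

  out <- c(
    area = area,
    perimeter = perim,
    form_factor = form_factor,
    eccentricity = ecc,
    solidity = solidity,
    extent = extent,
    major_axis_length = major,
    minor_axis_length = minor,
    orientation = orientation,
    equivalent_diameter = sqrt(4 * area / pi),
    compactness = compactness,
    max_feret_diameter = unname(fer["max"]),
    min_feret_diameter = unname(fer["min"]),
    bbox_height = bbox_h,
    bbox_width = bbox_w,
    euler_number = euler_number4(bw),
    convex_area = hull$convex_area,
    mean_radius = mean(brad),
    max_radius = max(brad),
    aspect_ratio = if (major > 0) minor / major else 0
  )
  out[shape_feature_names()]
}
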