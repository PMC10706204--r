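#' Pupil search ranges for Daugman's operator
#'
#' Candidate pupil centres lie in a square box centred on the detected
#' corneal centre with side `center_box * cornea_radius`; candidate radii
#' span `r_min`..`r_max` times the corneal radius; the circular integral is
#' sampled over the full 0-360 degree range.
#'
#' @param center_box box side as a fraction of the corneal radius.
#' @param r_min,r_max radius search range as fractions of the corneal radius.
#' @param gaussian_sigma sigma (px) of the Gaussian applied to the radial
#'   derivative.
#' @param radial_step radius grid step in px.
#' @param angle_step arc sampling step in degrees.
#' @return object of class `pupil_search_spec`.
#' @export
pupil_search_spec <- function(center_box = 0.35, r_min = 0.15, r_max = 0.35,
                              gaussian_sigma = 2, radial_step = 1,
                              angle_step = 1) {
  stopifnot(r_min < r_max)
  structure(list(center_box = center_box, r_min = r_min, r_max = r_max,
                 gaussian_sigma = gaussian_sigma, radial_step = radial_step,
                 angle_step = angle_step),
            class = "pupil_search_spec")
}

#' Locate the cornea from the binarized sclera
#'
#' Otsu-thresholds the preprocessed red channel to separate the bright
#' sclera, then takes the widest horizontal chord of the largest non-sclera
#' component as the corneal diameter: the centre is the chord midpoint and
#' the radius half the chord.
#'
#' @param gray preprocessed gray matrix, 0-255 (sclera brighter than cornea).
#' @param min_separation minimum Otsu class-mean separation (intensity
#'   units) below which localization fails.
#' @return list `(center = c(row, col), radius)`.
#' @export
find_cornea <- function(gray, min_separation = 25) {
  if (stats::sd(gray) < 1e-9) stop("cornea localization failed: flat image")
  thr <- from_unit(EBImage::otsu(to_unit(gray), range = c(0, 1)))
  m_lo <- mean(gray[gray <= thr]); m_hi <- mean(gray[gray > thr])
  if (!is.finite(m_lo) || !is.finite(m_hi) || m_hi - m_lo < min_separation)
    stop("cornea localization failed: no bimodal sclera/cornea separation")
  dark <- gray <= thr
  lab <- label_components(dark, 4)
  if (max(lab) == 0) stop("cornea localization failed: no corneal region")
  areas <- tabulate(lab[lab > 0], max(lab))
  comp <- lab == which.max(areas)
  widths <- vapply(seq_len(nrow(comp)), function(r) {
    cs <- which(comp[r, ])
    if (!length(cs)) 0L else max(cs) - min(cs) + 1L
  }, integer(1))
  # the chord profile of a circle is flat near its widest point; average
  # the near-maximal rows for an unbiased centre estimate
  near <- which(widths >= max(widths) - 2)
  r0 <- round(mean(near))
  cs <- which(comp[r0, ])
  list(center = c(r0, (min(cs) + max(cs)) / 2),
       radius = max(widths) / 2)
}

# Gaussian smoothing along the radius axis (columns of m), truncated kernel
smooth_rows <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  n <- ncol(m)
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= n
    W[idx[ok], j] <- k[ok] / sum(k[ok])
  }
  m %*% W
}

# objective values for all candidate centres: |G_sigma * d/dr (circular mean)|
daugman_objective <- function(gray, centers, radii, sigma, angle_step) {
  ang <- seq(0, 360 - angle_step, by = angle_step) * pi / 180
  m <- matrix(0, nrow(centers), length(radii))
  for (j in seq_along(radii)) {
    r <- radii[j]
    rows <- outer(centers[, 1], r * sin(ang), "+")
    cols <- outer(centers[, 2], r * cos(ang), "+")
    m[, j] <- rowMeans(matrix(bilinear(gray, as.vector(rows),
                                       as.vector(cols)),
                              nrow(centers)))
  }
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  abs(smooth_rows(d, sigma))
}

#' Detect the pupil with Daugman's integrodifferential operator
#'
#' Maximizes the absolute Gaussian-smoothed radial derivative of the
#' circular mean intensity over a discrete grid of candidate centres and
#' radii (coarse 2 px grid refined to 1 px around the optimum). The
#' circular mean is sampled at `angle_step`-degree arc points with bilinear
#' interpolation, which realizes the 1/(2*pi*r) arc-length normalization.
#'
#' @param gray preprocessed gray matrix, 0-255.
#' @param cornea `list(center, radius)` from [find_cornea()].
#' @param spec a [pupil_search_spec()].
#' @return list `(center = c(row, col), radius, objective,
#'   low_confidence)`. In the operator's (x0, y0) notation, x0 is the
#'   column and y0 the row.
#' @export
daugman_pupil <- function(gray, cornea, spec = pupil_search_spec()) {
  R <- cornea$radius
  half <- spec$center_box * R / 2
  radii <- seq(spec$r_min * R, spec$r_max * R, by = spec$radial_step)
  if (length(radii) < 3) stop("pupil radius search grid is empty")
  grid1 <- function(ctr, half_w, step) {
    rs <- seq(ctr[1] - half_w, ctr[1] + half_w, by = step)
    cs <- seq(ctr[2] - half_w, ctr[2] + half_w, by = step)
    as.matrix(expand.grid(row = rs, col = cs))
  }
  # coarse pass on a 2 px centre grid with 3x coarser arc sampling, then
  # full-resolution refinement on a 1 px grid around the optimum
  centers <- grid1(cornea$center, half, 2)
  obj <- daugman_objective(gray, centers, radii, spec$gaussian_sigma,
                           3 * spec$angle_step)
  best <- arrayInd(which.max(obj), dim(obj))
  ctr <- centers[best[1], ]
  # refine on a 1 px grid around the coarse optimum, clipped to the box
  fine <- grid1(ctr, 2, 1)
  keep <- abs(fine[, 1] - cornea$center[1]) <= half &
    abs(fine[, 2] - cornea$center[2]) <= half
  fine <- fine[keep, , drop = FALSE]
  obj2 <- daugman_objective(gray, fine, radii, spec$gaussian_sigma,
                            spec$angle_step)
  best2 <- arrayInd(which.max(obj2), dim(obj2))
  # derivative j corresponds to the midpoint between radii j and j+1
  r_hat <- (radii[best2[2]] + radii[best2[2] + 1]) / 2
  list(center = as.numeric(fine[best2[1], ]), radius = r_hat,
       objective = max(obj2),
       low_confidence = (max(obj2) - min(obj2)) < 1e-6)
}

#' Inferior 90-degree sector ROI mask
#'
#' The sector apex sits at the pupil centre; the sector radius is the
#' distance from the pupil centre to the bottom edge of the cornea; the
#' sector spans 45 degrees either side of the downward image vertical.
#'
#' @param shape `c(height, width)` of the frame.
#' @param pupil_center `c(row, col)` apex.
#' @param cornea `list(center, radius)`.
#' @return logical matrix mask.
#' @export
inferior_roi <- function(shape, pupil_center, cornea) {
  bottom <- c(cornea$center[1] + cornea$radius, cornea$center[2])
  sect_r <- sqrt(sum((bottom - pupil_center)^2))
  if (sect_r <= 0) stop("sector radius must be positive")
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dr <- rr - pupil_center[1]; dc <- cc - pupil_center[2]
  d <- sqrt(dr^2 + dc^2)
  inside <- d <= sect_r & d > 0
  inside & (dr / pmax(d, 1e-9) >= cos(pi / 4))
}

#' Locate the full corneal geometry of one image
#'
#' Runs [find_cornea()], [daugman_pupil()] and [inferior_roi()] on a
#' preprocessed image and collects the results.
#'
#' @param gray preprocessed gray matrix from [preprocess_image()].
#' @param spec a [pupil_search_spec()].
#' @return object of class `cornea_geometry` with fields `cornea_center`,
#'   `cornea_radius`, `pupil_center`, `pupil_radius`, `roi_mask`,
#'   `sector_radius`.
#' @export
locate_roi <- function(gray, spec = pupil_search_spec()) {
  cor <- find_cornea(gray)
  pup <- daugman_pupil(gray, cor, spec)
  mask <- inferior_roi(dim(gray), pup$center, cor)
  structure(list(cornea_center = cor$center, cornea_radius = cor$radius,
                 pupil_center = pup$center, pupil_radius = pup$radius,
                 roi_mask = mask,
                 sector_radius = cor$center[1] + cor$radius - pup$center[1],
                 low_confidence = pup$low_confidence),
            class = "cornea_geometry")
}

#' Crop and normalize the ROI
#'
#' Crops the sector bounding box out of an image (and out of any companion
#' masks) and resizes it to the normalized ROI frame with bilinear
#' interpolation (nearest-neighbour thresholding for masks). The clinical
#' default frame is 596 x 1104.
#'
#' @param image RGB array or gray matrix, full frame.
#' @param geometry a [locate_roi()] result.
#' @param size `c(height, width)` of the normalized ROI.
#' @return list `(rgb` or `gray`, `mask)` in the normalized frame.
#' @export
extract_roi <- function(image, geometry, size = c(596, 1104)) {
  m <- geometry$roi_mask
  rws <- range(which(rowSums(m) > 0)); cls <- range(which(colSums(m) > 0))
  rs <- rws[1]:rws[2]; cs <- cls[1]:cls[2]
  rsz <- function(x) EBImage::resize(x, w = size[1], h = size[2])
  mask_n <- rsz(m[rs, cs] * 1) > 0.5
  if (length(dim(image)) == 3) {
    out <- array(0, c(size, 3))
    for (ch in 1:3) out[, , ch] <- clip255(rsz(image[rs, cs, ch]))
    list(rgb = out, mask = mask_n)
  } else {
    list(gray = clip255(rsz(image[rs, cs])), mask = mask_n)
  }
}
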