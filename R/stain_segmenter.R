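#' Grayscale reconstruction by dilation
#'
#' Geodesic reconstruction: the marker is iteratively dilated with the
#' 8-connected unit structuring element and clipped by the mask image until
#' stability.
#'
#' @param marker gray matrix, pointwise <= `mask_img`.
#' @param mask_img gray matrix bounding the reconstruction.
#' @param max_iter iteration cap.
#' @return reconstructed gray matrix.
#' @export
reconstruct_dilation <- function(marker, mask_img, max_iter = 1000L) {
  stopifnot(all(dim(marker) == dim(mask_img)))
  # EBImage grayscale morphology clamps to [0, 1]; work in the unit domain
  sc <- max(1, max(mask_img), max(marker))
  k <- matrix(1, 3, 3)
  cur <- pmin(marker, mask_img) / sc
  mu <- mask_img / sc
  for (i in seq_len(max_iter)) {
    nxt <- pmin(EBImage::dilate(cur, k), mu)
    if (max(abs(nxt - cur)) < 1e-12) break
    cur <- nxt
  }
  cur * sc
}

#' Top-hat by reconstruction
#'
#' Opens the image with a discrete disk, reconstructs the image by dilation
#' from the opening, and returns the residual `image - reconstruction`.
#' Small bright structures (staining dots) survive in the residual while
#' smooth background of any level is removed, making detection robust to
#' contrast and illumination offsets.
#'
#' @param gray gray matrix, 0-255 (green ROI channel).
#' @param opening_radius radius in px of the circular structuring element
#'   (clinical default 10 in the normalized ROI frame).
#' @return non-negative gray matrix, same shape.
#' @export
tophat_reconstruction <- function(gray, opening_radius = 10) {
  k <- disk_kernel(opening_radius)
  if (nrow(k) > nrow(gray) || ncol(k) > ncol(gray))
    stop("structuring element larger than the image")
  sc <- max(1, max(gray))
  opened <- EBImage::opening(gray / sc, k) * sc
  rec <- reconstruct_dilation(opened, gray)
  pmax(gray - rec, 0)
}

#' Construct a stain map from a binary mask
#'
#' Labels 8-connected components and records per-region centroids, areas
#' and perimeters.
#'
#' @param mask logical or 0/1 matrix of staining pixels.
#' @return object of class `stain_map` with fields `binary_mask`, `labels`,
#'   `n`, `centroids` (n x 2, row/col), `areas`, `perimeters`.
#' @export
stain_map <- function(mask) {
  mask <- mask != 0
  lab <- label_components(mask, 8)
  n <- max(lab)
  if (n == 0) {
    return(structure(list(binary_mask = mask, labels = lab, n = 0L,
                          centroids = matrix(numeric(0), 0, 2),
                          areas = numeric(0), perimeters = numeric(0)),
                     class = "stain_map"))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  centroids <- cbind(tapply(idx[, 1], l, mean), tapply(idx[, 2], l, mean))
  areas <- as.numeric(tabulate(l, n))
  # chain-code perimeter: length of the closed outer contour, diagonal
  # steps weighted sqrt(2); a single pixel counts its unit square
  ct <- EBImage::ocontour(lab)
  perims <- vapply(seq_len(n), function(i) {
    pts <- ct[[i]]
    if (is.null(pts) || nrow(pts) < 2) return(4)
    steps <- diff(rbind(pts, pts[1, , drop = FALSE]))
    max(sum(sqrt(rowSums(steps^2))), 4)
  }, numeric(1))
  structure(list(binary_mask = mask, labels = lab, n = as.integer(n),
                 centroids = unname(centroids), areas = areas,
                 perimeters = perims),
            class = "stain_map")
}

#' Segmentation configuration
#'
#' @param opening_radius structuring-element radius for the top-hat (px).
#' @param threshold_frac fallback threshold as a fraction of the top-hat
#'   maximum, used as a floor under the Otsu threshold.
#' @param min_contrast absolute top-hat floor (intensity units) below which
#'   nothing is detected; suppresses detections on stain-free noise.
#' @param min_size smallest retained region area in px^2.
#' @param mask_margin erosion radius (px) applied to the ROI mask before
#'   detection, guarding against the bright limbal rim at the sector arc.
#' @return object of class `segment_config`.
#' @export
segment_config <- function(opening_radius = 10, threshold_frac = 0.15,
                           min_contrast = 10, min_size = 5,
                           mask_margin = 8) {
  structure(list(opening_radius = opening_radius,
                 threshold_frac = threshold_frac,
                 min_contrast = min_contrast, min_size = min_size,
                 mask_margin = mask_margin),
            class = "segment_config")
}

#' Segment staining regions inside the ROI
#'
#' Green channel, top-hat by reconstruction, thresholding, small-object
#' removal and 8-connected labeling restricted to the ROI mask. The
#' threshold is the Otsu level of the in-mask top-hat values floored at
#' `threshold_frac` of the top-hat maximum (the floor takes over when the
#' top-hat histogram is effectively unimodal) and at `min_contrast`.
#'
#' @param roi_rgb normalized ROI RGB array, 0-255.
#' @param roi_mask logical sector mask in the same frame.
#' @param cfg a [segment_config()].
#' @return a [stain_map()].
#' @export
segment_stains <- function(roi_rgb, roi_mask, cfg = segment_config()) {
  if (!any(roi_mask)) stop("empty ROI mask")
  green <- if (length(dim(roi_rgb)) == 3) roi_rgb[, , 2] else roi_rgb
  th <- tophat_reconstruction(green, cfg$opening_radius)
  mask_in <- roi_mask
  if (cfg$mask_margin > 0)
    mask_in <- EBImage::erode(roi_mask * 1,
                              disk_kernel(cfg$mask_margin)) > 0.5
  vals <- th[mask_in]
  thr <- cfg$min_contrast
  if (length(vals) && max(vals) > 0) {
    t_otsu <- tryCatch(
      from_unit(EBImage::otsu(to_unit(matrix(vals)), range = c(0, 1))),
      error = function(e) 0)
    thr <- max(t_otsu, cfg$threshold_frac * max(vals), cfg$min_contrast)
  }
  bin <- th >= thr & mask_in
  lab <- label_components(bin, 8)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    bin[matrix(areas[ifelse(lab > 0, lab, 1)] < cfg$min_size &
                 lab > 0, nrow(lab), ncol(lab))] <- FALSE
  }
  stain_map(bin)
}
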