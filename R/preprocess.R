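#' Preprocessing configuration
#'
#' @param median_kernel side of the square median-filter neighborhood in px;
#'   odd, >= 3. The clinical default is 21 at full 1944 x 2592 resolution.
#' @param clahe_clip CLAHE clip limit as a fraction of the tile histogram.
#' @param clahe_tiles `(rows, cols)` CLAHE tile grid.
#' @param reflection_max_frac bright connected components covering more than
#'   this fraction of the frame are treated as sclera, not reflections.
#' @return object of class `preproc_config`.
#' @export
preproc_config <- function(median_kernel = 21, clahe_clip = 0.01,
                           clahe_tiles = c(8, 8),
                           reflection_max_frac = 0.01) {
  if (median_kernel < 3 || median_kernel %% 2 != 1)
    stop("median_kernel must be odd and >= 3")
  structure(list(median_kernel = median_kernel, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles,
                 reflection_max_frac = reflection_max_frac),
            class = "preproc_config")
}

#' Extract the red channel
#'
#' The red plane carries the sclera/cornea contrast while fluorescein
#' staining (green) is nearly invisible in it, so corneal edges are enhanced
#' and staining does not disturb localization.
#'
#' @param image height x width x 3 array, 0-255.
#' @return gray matrix (the red plane).
#' @export
extract_red <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("expected a 3-channel RGB image")
  image[, , 1]
}

#' Median filtering followed by CLAHE
#'
#' @param gray gray matrix, 0-255.
#' @param cfg a [preproc_config()].
#' @return enhanced gray matrix, 0-255, same shape.
#' @export
enhance <- function(gray, cfg = preproc_config()) {
  if (!is.matrix(gray)) stop("expected a single-channel image matrix")
  u <- to_unit(gray)
  u <- if (cfg$median_kernel == 3) median3x3(u)
  else EBImage::medianFilter(u, size = (cfg$median_kernel - 1) / 2)
  if (stats::sd(u) > 1e-9) {
    # EBImage's limit is the per-bin clip multiplier; map the MATLAB-style
    # clip fraction onto it via the histogram bin count. The implementation
    # needs dimensions divisible by the tile grid, so pad by edge
    # replication and crop back.
    nx <- cfg$clahe_tiles[2]; ny <- cfg$clahe_tiles[1]
    pr <- (nx - nrow(u) %% nx) %% nx  # EBImage x-axis is dim 1
    pc <- (ny - ncol(u) %% ny) %% ny
    up <- u[c(seq_len(nrow(u)), rep(nrow(u), pr)),
            c(seq_len(ncol(u)), rep(ncol(u), pc))]
    up <- EBImage::clahe(up, nx = nx, ny = ny, bins = 256,
                         limit = max(cfg$clahe_clip * 256, 1))
    u <- up[seq_len(nrow(u)), seq_len(ncol(u))]
  }
  from_unit(pmin(pmax(u, 0), 1))
}

#' Detect and inpaint specular reflections
#'
#' Reflections are the brightest compact areas of the red channel. Pixels
#' above the Otsu threshold are candidates; large bright components (the
#' sclera) are excluded by an area rule, which operationally restricts the
#' mask to the corneal interior before the cornea has been located. Masked
#' pixels are replaced by the median of the unmasked pixels in a 21 x 21
#' neighborhood.
#'
#' @param gray gray matrix, 0-255.
#' @param max_frac components covering more than this fraction of the frame
#'   are not reflections.
#' @return list `(image, mask)`.
#' @export
remove_reflections <- function(gray, max_frac = 0.01) {
  if (!is.matrix(gray)) stop("expected a single-channel image matrix")
  mask <- matrix(FALSE, nrow(gray), ncol(gray))
  if (stats::sd(gray) > 1e-9) {
    thr <- from_unit(EBImage::otsu(to_unit(gray), range = c(0, 1)))
    bright <- gray > thr
    lab <- label_components(bright, 8)
    if (max(lab) > 0) {
      areas <- tabulate(lab[lab > 0], max(lab))
      # reflections are compact AND near-saturated: exclude the sclera (too
      # large) and mild noise excursions just above the Otsu level
      lum <- tapply(gray[lab > 0], lab[lab > 0], mean)
      bright_enough <- lum >= thr + 0.5 * (max(gray) - thr)
      keep <- which(areas <= max_frac * length(gray) & bright_enough)
      mask <- matrix(lab %in% keep, nrow(gray), ncol(gray))
    }
  }
  out <- gray
  if (any(mask)) {
    half <- 10L
    idx <- which(mask, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      rs <- max(1, r - half):min(nrow(gray), r + half)
      cs <- max(1, c - half):min(ncol(gray), c + half)
      vals <- gray[rs, cs][!mask[rs, cs]]
      if (length(vals)) out[r, c] <- stats::median(vals)
    }
  }
  list(image = out, mask = mask)
}

#' Full preprocessing pipeline
#'
#' Fixed order: red channel, median filter, CLAHE, reflection removal.
#'
#' @param image RGB array, 0-255.
#' @param cfg a [preproc_config()].
#' @return list `(image, reflection_mask)` where `image` is the enhanced,
#'   reflection-free red channel.
#' @export
preprocess_image <- function(image, cfg = preproc_config()) {
  g <- enhance(extract_red(image), cfg)
  rr <- remove_reflections(g, cfg$reflection_max_frac)
  list(image = rr$image, reflection_mask = rr$mask)
}
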