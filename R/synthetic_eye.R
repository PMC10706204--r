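#' Specify the anatomy of a synthetic anterior-segment image
#'
#' Describes the fixed anatomy rendered by [render_eye()]: a bright sclera
#' field, a darker corneal disk and a dark pupil, mimicking the red-channel
#' contrast of a fluorescein slit-lamp photograph. Clinical frames are
#' nominally 1944 x 2592 px; smaller frames with proportionally scaled
#' geometry are used throughout the tests.
#'
#' @param image_height,image_width frame size in px.
#' @param cornea_center,cornea_radius corneal circle, (row, col) px and px.
#' @param pupil_center,pupil_radius pupil circle; must lie wholly inside the
#'   cornea.
#' @param sclera_intensity,cornea_intensity,pupil_intensity red-channel
#'   intensities (0-255); must be strictly decreasing in that order.
#' @return an object of class `eye_spec`.
#' @export
eye_spec <- function(image_height = 512, image_width = 512,
                     cornea_center = c(image_height / 2, image_width / 2),
                     cornea_radius = 0.36 * min(image_height, image_width),
                     pupil_center = cornea_center,
                     pupil_radius = 0.25 * cornea_radius,
                     sclera_intensity = 210, cornea_intensity = 120,
                     pupil_intensity = 40) {
  spec <- list(image_height = image_height, image_width = image_width,
               cornea_center = as.numeric(cornea_center),
               cornea_radius = cornea_radius,
               pupil_center = as.numeric(pupil_center),
               pupil_radius = pupil_radius,
               sclera_intensity = sclera_intensity,
               cornea_intensity = cornea_intensity,
               pupil_intensity = pupil_intensity)
  if (pupil_radius >= cornea_radius)
    stop("pupil_radius must be smaller than cornea_radius")
  if (sqrt(sum((spec$pupil_center - spec$cornea_center)^2)) + pupil_radius >
      cornea_radius)
    stop("pupil circle must lie wholly inside the cornea circle")
  if (!(sclera_intensity > cornea_intensity && cornea_intensity > pupil_intensity))
    stop("intensities must satisfy sclera > cornea > pupil")
  structure(spec, class = "eye_spec")
}

#' Specify the staining content of a synthetic image
#'
#' Staining dots are rendered as 2-D Gaussian green blobs whose half-peak
#' radius equals `dot_radii`; ground truth marks pixels at or above half the
#' nominal peak. Confluent patches are flat-topped elliptical blobs. All
#' stain geometry must lie inside the cornea.
#'
#' @param dot_centers n x 2 matrix of (row, col) dot centres, or `NULL`.
#' @param dot_radii half-peak radius in px (scalar or per-dot vector).
#' @param dot_peak_green peak green intensity added by each dot (0-255).
#' @param confluent_patches list of patches, each
#'   `list(center = c(row, col), radii = c(a, b), angle = degrees)`.
#' @param linear_band optional `c(row, half_height)` descriptor recording
#'   that dots were arranged in a horizontal band (metadata only).
#' @param filaments if `TRUE`, a thin wavy filament is rendered and the
#'   corresponding ground-truth flag set. Off by default.
#' @param noise_sigma Gaussian sensor-noise standard deviation (intensity).
#' @param reflection_spots list of `list(center = c(row, col), radius)`
#'   saturated specular reflections.
#' @param confluent_area area in px^2 at or above which a single stained
#'   region counts as a patch of confluent staining in the ground truth.
#' @param central_fraction a stained pixel closer than
#'   `central_fraction * cornea_radius` to the pupil centre counts as
#'   central staining.
#' @param dot_peak_jitter per-dot peak variation as a fraction of
#'   `dot_peak_green` (uniform, symmetric).
#' @param illumination optional photometric nuisance:
#'   `list(scale, grad_r, grad_c, mottle_amp)` — a per-image exposure
#'   factor, linear illumination gradients along rows/columns (fractions),
#'   and the amplitude of low-frequency tear-film mottle added to the
#'   green channel.
#' @param seed integer; fully determines the rendered pixels.
#' @return an object of class `stain_spec`.
#' @export
stain_spec <- function(dot_centers = NULL, dot_radii = 5, dot_peak_green = 150,
                       confluent_patches = list(), linear_band = NULL,
                       filaments = FALSE, noise_sigma = 3,
                       reflection_spots = list(), confluent_area = 120,
                       central_fraction = 0.35, dot_peak_jitter = 0,
                       dot_irregularity = 0, haze = NULL,
                       illumination = NULL, seed = 1L) {
  if (!is.null(dot_centers)) {
    dot_centers <- matrix(as.numeric(dot_centers), ncol = 2)
    dot_radii <- rep_len(dot_radii, nrow(dot_centers))
  }
  structure(list(dot_centers = dot_centers, dot_radii = dot_radii,
                 dot_peak_green = dot_peak_green,
                 confluent_patches = confluent_patches,
                 linear_band = linear_band, filaments = filaments,
                 noise_sigma = noise_sigma,
                 reflection_spots = reflection_spots,
                 confluent_area = confluent_area,
                 central_fraction = central_fraction,
                 dot_peak_jitter = dot_peak_jitter,
                 dot_irregularity = dot_irregularity, haze = haze,
                 illumination = illumination,
                 seed = as.integer(seed)),
            class = "stain_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ocular Staining Score for one corneal region of interest
#'
#' Maps a staining-dot count and modifier flags to the 0-5 OSS grade used
#' for the inferior cornea: base score 0 for no staining, 1 for one to five
#' dots, 2 for six to thirty dots, 3 for more than thirty dots; one extra
#' point for each of confluent staining, corneal filaments, and staining in
#' the central cornea, with the total capped at 5.
#'
#' @param count number of staining dots (non-negative integer).
#' @param has_confluent,has_central,has_filament modifier flags.
#' @return integer score in 0..5.
#' @examples
#' oss_score(12, FALSE, FALSE, FALSE)  # 2
#' oss_score(31, TRUE, TRUE, FALSE)    # 5
#' @export
oss_score <- function(count, has_confluent = FALSE, has_central = FALSE,
                      has_filament = FALSE) {
  if (length(count) != 1 || is.na(count) || count < 0 || count != round(count))
    stop("count must be a single non-negative integer")
  base <- if (count == 0) 0L else if (count <= 5) 1L else if (count <= 30) 2L else 3L
  extra <- sum(isTRUE(has_confluent), isTRUE(has_central), isTRUE(has_filament))
  min(base + extra, 5L)
}

#' Render a synthetic anterior-segment image with ground truth
#'
#' Paints the anatomy described by an [eye_spec()] (red channel carries the
#' sclera/cornea/pupil contrast), adds green Gaussian staining dots and
#' patches per the [stain_spec()], saturated reflections, and Gaussian
#' sensor noise. The ground-truth stain mask marks exactly the rendered
#' stain pixels at or above half the nominal peak, before noise.
#'
#' @param eye an [eye_spec()].
#' @param stain a [stain_spec()].
#' @return list with `image` (height x width x 3 array, 0-255) and `truth`
#'   (class `cfs_truth`: `stain_mask`, `region_count`, `oss_grade`,
#'   `has_confluent`, `has_central`, `has_filament`).
#' @export
render_eye <- function(eye, stain = stain_spec()) {
  stopifnot(inherits(eye, "eye_spec"), inherits(stain, "stain_spec"))
  with_seed(stain$seed, render_eye_impl(eye, stain))
}

render_eye_impl <- function(eye, stain) {
  h <- eye$image_height; w <- eye$image_width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d_cor <- sqrt((rr - eye$cornea_center[1])^2 + (cc - eye$cornea_center[2])^2)
  d_pup <- sqrt((rr - eye$pupil_center[1])^2 + (cc - eye$pupil_center[2])^2)
  edge <- function(d, R) stats::plogis((R - d) / 1.2)  # soft 1-2 px rim
  red <- eye$sclera_intensity +
    (eye$cornea_intensity - eye$sclera_intensity) * edge(d_cor, eye$cornea_radius) +
    (eye$pupil_intensity - eye$cornea_intensity) * edge(d_pup, eye$pupil_radius)

  # stain layer (noise-free); ground truth thresholds this at half the
  # nominal peak
  layer <- matrix(0, h, w)
  if (!is.null(stain$dot_centers) && nrow(stain$dot_centers)) {
    n_dots <- nrow(stain$dot_centers)
    peaks <- stain$dot_peak_green *
      (1 + stats::runif(n_dots, -stain$dot_peak_jitter,
                        stain$dot_peak_jitter))
    for (i in seq_len(n_dots)) {
      ctr <- stain$dot_centers[i, ]
      if (sqrt(sum((ctr - eye$cornea_center)^2)) + stain$dot_radii[i] >
          eye$cornea_radius)
        stop("stain dot ", i, " extends outside the cornea")
      sig <- stain$dot_radii[i] / sqrt(2 * log(2))
      d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
      win <- d2 <= (4 * stain$dot_radii[i])^2
      if (stats::runif(1) < stain$dot_irregularity) {
        # irregular lesion: a connected core plus dimmer satellite lobes;
        # one ground-truth region, but the detector may fragment it
        layer[win] <- layer[win] +
          0.9 * peaks[i] * exp(-d2[win] / (2 * sig^2))
        for (k in seq_len(sample(2:4, 1))) {
          off <- stats::runif(2, -0.8, 0.8) * stain$dot_radii[i]
          d2s <- (rr - ctr[1] - off[1])^2 + (cc - ctr[2] - off[2])^2
          wins <- d2s <= (3 * stain$dot_radii[i])^2
          layer[wins] <- layer[wins] + stats::runif(1, 0.45, 0.8) *
            peaks[i] * exp(-d2s[wins] / (2 * (0.6 * sig)^2))
        }
      } else {
        layer[win] <- layer[win] + peaks[i] * exp(-d2[win] / (2 * sig^2))
      }
    }
  }
  for (p in stain$confluent_patches) {
    a <- p$radii[1]; b <- p$radii[2]; th <- (p$angle %||% 0) * pi / 180
    if (sqrt(sum((p$center - eye$cornea_center)^2)) + max(a, b) >
        eye$cornea_radius)
      stop("confluent patch extends outside the cornea")
    u <- (rr - p$center[1]) * cos(th) + (cc - p$center[2]) * sin(th)
    v <- -(rr - p$center[1]) * sin(th) + (cc - p$center[2]) * cos(th)
    q2 <- (u / a)^2 + (v / b)^2
    layer <- layer + stain$dot_peak_green * exp(log(0.5) * q2^2)
  }
  if (isTRUE(stain$filaments)) {
    # thin wavy strand hanging below the pupil
    t <- seq(0, 1, length.out = 200)
    fr <- eye$pupil_center[1] + eye$pupil_radius + 4 +
      t * 0.45 * eye$cornea_radius
    fc <- eye$pupil_center[2] + 6 * sin(6 * pi * t)
    for (i in seq_along(t)) {
      d2 <- (rr - fr[i])^2 + (cc - fc[i])^2
      layer <- pmax(layer, stain$dot_peak_green * exp(-d2 / (2 * 1.1^2)))
    }
  }
  gt_mask <- layer >= 0.5 * stain$dot_peak_green
  lab <- label_components(gt_mask, 8)
  region_count <- max(lab)
  areas <- if (region_count) tabulate(lab[lab > 0], region_count) else integer(0)
  has_confluent <- any(areas >= stain$confluent_area)
  has_central <- any(gt_mask &
                       d_pup <= stain$central_fraction * eye$cornea_radius)
  truth <- structure(list(stain_mask = gt_mask, region_count = region_count,
                          oss_grade = oss_score(region_count, has_confluent,
                                                has_central,
                                                isTRUE(stain$filaments)),
                          has_confluent = has_confluent,
                          has_central = has_central,
                          has_filament = isTRUE(stain$filaments)),
                     class = "cfs_truth")

  green <- 0.72 * red + layer
  blue <- 0.55 * red
  out <- array(0, c(h, w, 3))
  out[, , 1] <- red; out[, , 2] <- green; out[, , 3] <- blue
  il <- stain$illumination
  if (!is.null(il) && !is.null(il$iris_amp) && il$iris_amp > 0) {
    # iris radial streaks visible through the cornea
    theta <- atan2(rr - eye$pupil_center[1], cc - eye$pupil_center[2])
    annulus <- stats::plogis((d_pup - 1.1 * eye$pupil_radius) / 2) *
      stats::plogis((0.97 * eye$cornea_radius - d_cor) / 2)
    iris <- il$iris_amp * sin(il$iris_freq * theta + il$iris_phase) * annulus
    for (ch in 1:3) out[, , ch] <- out[, , ch] + c(1, 0.8, 0.6)[ch] * iris
    if (!is.null(il$crypt_amp) && il$crypt_amp > 0) {
      # irregular dark iris crypts: rectified random field, lesion-scale
      # correlation; darkens only, so the bright-spot detector ignores it
      f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w),
                          sigma = il$crypt_sigma)
      f <- f / stats::sd(f)
      dark <- il$crypt_amp * pmax(f, 0) * annulus
      out[, , 1] <- out[, , 1] - 0.6 * dark
      out[, , 2] <- out[, , 2] - dark
    }
  }
  if (!is.null(il)) {
    # per-image exposure, channel gain, and a linear illumination gradient
    plane <- il$scale * (1 + il$grad_r * (rr / h - 0.5) +
                           il$grad_c * (cc / w - 0.5))
    for (ch in 1:3) out[, , ch] <- out[, , ch] * plane
    if (!is.null(il$green_gain))
      out[, , 2] <- out[, , 2] * il$green_gain
    if (!is.null(il$defocus) && il$defocus > 0.05)
      for (ch in 1:3)
        out[, , ch] <- EBImage::gblur(out[, , ch], sigma = il$defocus)
    if (il$mottle_amp > 0) {
      # low-frequency tear-film mottle in the green channel
      coarse <- matrix(stats::rnorm(144), 12, 12)
      mot <- EBImage::resize(coarse, w = h, h = w)
      out[, , 2] <- out[, , 2] + il$mottle_amp * (mot / stats::sd(mot))
    }
  }
  if (!is.null(stain$haze)) {
    place_blob <- function(amp, sigma) {
      a <- stats::runif(1, 50, 130) * pi / 180
      rad <- stats::runif(1, 0.25, 0.9) * eye$cornea_radius
      hc <- eye$pupil_center + rad * c(sin(a), cos(a))
      d2h <- (rr - hc[1])^2 + (cc - hc[2])^2
      win <- d2h <= (4 * sigma)^2
      out[, , 2][win] <<- out[, , 2][win] + amp * exp(-d2h[win] / (2 * sigma^2))
    }
    for (k in seq_len(stain$haze$n %||% 0))          # broad veiling pools
      place_blob(stats::runif(1, 0.5, 1) * stain$haze$amp,
                 stain$haze$radius * stats::runif(1, 0.7, 1.6))
    for (k in seq_len(stain$haze$n_speckle %||% 0))  # sub-threshold specks
      place_blob(stats::runif(1, 0.5, 1) * stain$haze$amp_speckle,
                 stain$haze$radius_speckle * stats::runif(1, 0.8, 1.5))
  }
  for (sp in stain$reflection_spots) {
    m <- stats::plogis((sp$radius -
      sqrt((rr - sp$center[1])^2 + (cc - sp$center[2])^2)) / 0.8)
    for (ch in 1:3) out[, , ch] <- out[, , ch] + (255 - out[, , ch]) * m
  }
  if (stain$noise_sigma > 0)
    out <- out + array(stats::rnorm(h * w * 3, 0, stain$noise_sigma),
                       c(h, w, 3))
  list(image = clip255(out), truth = truth)
}

# ---- cohort generation ------------------------------------------------------

# sample a stain_spec producing (with high probability) the requested grade;
# grade is re-derived from the rendered mask so labels are always consistent.
sample_scene <- function(eye, grade, seed) {
  with_seed(seed, {
    R <- eye$cornea_radius
    pc <- eye$pupil_center
    dot_r <- if (grade >= 3) stats::runif(1, 0.020, 0.026) * R
    else stats::runif(1, 0.020, 0.030) * R
    peak <- stats::runif(1, 100, 180)
    n_dots <- switch(as.character(grade),
                     "0" = 0L,
                     "1" = sample(1:5, 1),
                     "2" = sample(8:28, 1),
                     "3" = sample(36:46, 1),
                     "4" = sample(36:46, 1))
    spread <- switch(as.character(grade), "0" = NA, "1" = NA,
                     "2" = 0.24 * R, "3" = 0.17 * R, "4" = 0.13 * R)
    n_clust <- switch(as.character(grade), "0" = 0L, "1" = 0L,
                      "2" = sample(2:4, 1), "3" = sample(4:6, 1),
                      "4" = sample(4:5, 1))
    patches <- list()
    if (grade == 4) {
      # horizontal-leaning elongated streaks of confluent staining
      for (k in seq_len(1L)) {
        ang <- stats::runif(1, 62, 118) * pi / 180   # downward = 90 deg
        rad <- stats::runif(1, 0.55, 0.75) * R
        patches[[k]] <- list(center = pc + rad * c(sin(ang), cos(ang)),
                             radii = c(stats::runif(1, 0.042, 0.052),
                                       stats::runif(1, 0.10, 0.13)) * R,
                             angle = stats::runif(1, -25, 25))
      }
    }
    avoid <- if (length(patches))
      t(vapply(patches, function(p) c(p$center, max(p$radii) + 2), numeric(3)))
    else NULL
    sep0 <- (if (grade == 4) 3.4 else 3.8) * dot_r
    centers <- NULL
    for (relax in c(1, 0.9, 0.81)) {   # never below the no-merge spacing
      centers <- place_dots(n_dots, pc, R, n_clust, spread,
                            min_sep = sep0 * relax,
                            cornea_center = eye$cornea_center,
                            margin = dot_r + 1, avoid = avoid)
      if (grade <= 2 || nrow(centers) >= min(n_dots, 33)) break
    }
    refl <- list(list(center = eye$cornea_center +
                        c(-0.55 * R, stats::runif(1, -0.2, 0.2) * R),
                      radius = stats::runif(1, 0.03, 0.06) * R))
    stain_spec(dot_centers = centers, dot_radii = dot_r,
               dot_peak_green = peak, confluent_patches = patches,
               noise_sigma = 3, reflection_spots = refl,
               confluent_area = round(0.010 * R^2),
               dot_peak_jitter = 0.3,
               dot_irregularity = 0.6,
               haze = list(n = sample(6:16, 1), amp = 25,
                           radius = 3.5 * dot_r,
                           n_speckle = sample(40:100, 1), amp_speckle = 6,
                           radius_speckle = 0.85 * dot_r),
               illumination = list(scale = stats::runif(1, 0.7, 1.35),
                                   grad_r = stats::runif(1, -0.3, 0.3),
                                   grad_c = stats::runif(1, -0.3, 0.3),
                                   mottle_amp = stats::runif(1, 6, 14),
                                   iris_amp = stats::runif(1, 3, 8),
                                   iris_freq = sample(30:70, 1),
                                   iris_phase = stats::runif(1, 0, 2 * pi),
                                   defocus = stats::runif(1, 0.2, 1.0),
                                   green_gain = stats::runif(1, 0.75, 1.25)),
               seed = derive_seed(seed, 7L))
  })
}

# rejection-sample dot centres in the inferior sector annulus, optionally
# around cluster centres, with a minimum separation (no merged dots)
place_dots <- function(n, pupil_center, R, n_clusters, spread, min_sep,
                       radial = c(0.42, 0.84), half_angle = 36,
                       cornea_center = pupil_center, margin = 0,
                       avoid = NULL) {
  if (n == 0) return(NULL)
  clust <- NULL
  if (n_clusters > 0) {
    ang <- stats::runif(n_clusters, 90 - 0.75 * half_angle,
                        90 + 0.75 * half_angle) * pi / 180
    rad <- stats::runif(n_clusters, 0.52, 0.78) * R
    clust <- cbind(pupil_center[1] + rad * sin(ang),
                   pupil_center[2] + rad * cos(ang))
  }
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    widen <- 1
    for (try in seq_len(500L)) {
      if (try %% 100 == 0) widen <- widen * 1.3  # relax crowded clusters
      if (is.null(clust)) {
        a <- stats::runif(1, 90 - half_angle, 90 + half_angle) * pi / 180
        r <- sqrt(stats::runif(1, radial[1]^2, radial[2]^2)) * R
        cand <- pupil_center + r * c(sin(a), cos(a))
      } else {
        k <- sample(nrow(clust), 1)
        cand <- clust[k, ] + stats::rnorm(2, 0, spread * widen)
        # keep inside the sector annulus
        v <- cand - pupil_center
        r <- sqrt(sum(v^2))
        a <- atan2(v[1], v[2]) * 180 / pi
        if (r < radial[1] * R || r > radial[2] * R ||
            abs(a - 90) > half_angle) next
      }
      if (sqrt(sum((cand - cornea_center)^2)) + margin > R) next
      if (!is.null(avoid) &&
          any(sqrt((avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2) <
                avoid[, 3] + margin)) next
      if (nrow(pts) &&
          min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                         byrow = TRUE))^2))) < min_sep) next
      pts <- rbind(pts, cand)
      break
    }
  }
  pts
}

#' Generate a graded synthetic cohort
#'
#' Draws a stratified cohort of synthetic eyes whose OSS grade is driven by
#' dot count and by spatial clustering: higher grades carry more dots in
#' tighter clusters, and grade 4 adds confluent elliptical patches. Grade
#' strata sizes follow `grade_mix` by largest-remainder allocation; every
#' image's label is re-derived from its own rendered ground truth.
#'
#' @param n cohort size.
#' @param grade_mix named proportions over grades (names in "0".."5");
#'   default uniform over 0-4. Must sum to 1.
#' @param seed master seed; per-image seeds are derived from it.
#' @param image_size frame side in px (square frames).
#' @return list of class `cfs_cohort`; each element has `image`, `truth`,
#'   `eye`, `stain`.
#' @export
make_cohort <- function(n, grade_mix = stats::setNames(rep(0.2, 5), 0:4),
                        seed = 1L, image_size = 300) {
  stopifnot(n >= 1)
  if (is.null(names(grade_mix))) names(grade_mix) <- seq_along(grade_mix) - 1
  grades <- as.integer(names(grade_mix))
  if (any(is.na(grades)) || any(grades < 0) || any(grades > 5))
    stop("grade_mix names must be grades in 0..5")
  if (abs(sum(grade_mix) - 1) > 1e-8) stop("grade_mix must sum to 1")
  counts <- floor(n * grade_mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * grade_mix - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  wanted <- rep(grades, counts)
  wanted <- with_seed(derive_seed(seed, 0L), sample(wanted))
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    eye <- with_seed(si, {
      R <- image_size * stats::runif(1, 0.33, 0.38)
      ctr <- image_size / 2 + stats::runif(2, -0.02, 0.02) * image_size
      off_r <- stats::runif(1, 0, 0.12) * R
      off_a <- stats::runif(1, 0, 2 * pi)
      eye_spec(image_size, image_size, cornea_center = ctr, cornea_radius = R,
               pupil_center = ctr + off_r * c(cos(off_a), sin(off_a)),
               pupil_radius = stats::runif(1, 0.18, 0.32) * R)
    })
    st <- sample_scene(eye, wanted[i], derive_seed(si, 11L))
    out <- render_eye(eye, st)
    list(image = out$image, truth = out$truth, eye = eye, stain = st)
  }) -> cohort
  structure(cohort, class = "cfs_cohort", seed = seed)
}

#' @export
`[.cfs_cohort` <- function(x, i) {
  structure(NextMethod(), class = "cfs_cohort", seed = attr(x, "seed"))
}

#' Write a cohort to disk
#'
#' Writes one PNG per image, a JSON ground-truth sidecar per image, and a
#' manifest CSV (`filename, grade, region_count, has_confluent, has_central,
#' has_filament`).
#'
#' @param cohort a [make_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    fn <- sprintf("eye_%04d.png", i)
    png::writePNG(aperm(cohort[[i]]$image / 255, c(1, 2, 3)),
                  file.path(dir, fn))
    tr <- cohort[[i]]$truth
    jsonlite::write_json(
      list(oss_grade = tr$oss_grade, region_count = tr$region_count,
           has_confluent = tr$has_confluent, has_central = tr$has_central,
           has_filament = tr$has_filament),
      file.path(dir, sub("\\.png$", ".json", fn)), auto_unbox = TRUE)
    data.frame(filename = fn, grade = tr$oss_grade,
               region_count = tr$region_count,
               has_confluent = tr$has_confluent,
               has_central = tr$has_central,
               has_filament = tr$has_filament)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
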