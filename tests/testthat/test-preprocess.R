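test_that("red channel extraction isolates anatomy from stain", {
  img <- array(0, c(8, 8, 3)); img[, , 1] <- 255
  expect_true(all(extract_red(img) == 255))
  img2 <- array(0, c(8, 8, 3)); img2[, , 2] <- 255
  expect_true(all(extract_red(img2) == 0))
  expect_error(extract_red(matrix(0, 8, 8)), "3-channel")
  # on a rendered eye, green dots are nearly invisible in the red plane
  eye <- eye_spec(220, 220, cornea_radius = 80)
  dots <- rbind(c(160, 110))
  out <- render_eye(eye, stain_spec(dot_centers = dots, dot_radii = 5,
                                    noise_sigma = 2, seed = 1))
  red <- extract_red(out$image)
  dot_px <- out$truth$stain_mask
  bg_px <- !dot_px & (red > 100 & red < 140)  # corneal background
  expect_lt(abs(mean(red[dot_px]) - mean(red[bg_px])), 8)
})

test_that("the 3x3 median network matches a direct median", {
  set.seed(4)
  x <- matrix(runif(400), 20, 20)
  ref <- x
  for (i in 1:20) for (j in 1:20) {
    rs <- max(1, i - 1):min(20, i + 1); cs <- max(1, j - 1):min(20, j + 1)
    w <- as.vector(x[rs, cs])
    w <- c(w, rep(x[i, j], 9 - length(w)))  # replicate border
    ref[i, j] <- median(w)
  }
  expect_equal(cfstopo:::median3x3(x), ref)
})

test_that("enhancement leaves flat fields flat and sharpens corneal edges", {
  flat <- matrix(120, 40, 40)
  expect_equal(enhance(flat, preproc_config(median_kernel = 3)), flat)
  # low-contrast eye: gradient across the corneal edge strictly increases
  eye <- eye_spec(220, 220, cornea_radius = 80, sclera_intensity = 140,
                  cornea_intensity = 110, pupil_intensity = 90)
  out <- render_eye(eye, stain_spec(noise_sigma = 1, seed = 1))
  red <- extract_red(out$image)
  enh <- enhance(red, preproc_config(median_kernel = 3))
  edge_jump <- function(m) {
    ring <- function(r) {
      th <- seq(0, 2 * pi, length.out = 90)
      mean(cfstopo:::bilinear(m, 110 + r * sin(th), 110 + r * cos(th)))
    }
    ring(86) - ring(74)
  }
  expect_gt(edge_jump(enh), edge_jump(red))
})

test_that("median filtering removes impulse noise while keeping a step edge", {
  step <- matrix(50, 40, 40); step[, 21:40] <- 200
  set.seed(2)
  noisy <- step
  idx <- cbind(sample(3:38, 25, TRUE), sample(c(3:18, 23:38), 25, TRUE))
  noisy[idx] <- ifelse(runif(25) < 0.5, 0, 255)
  filt <- enhance(noisy, preproc_config(median_kernel = 3))
  # impulses are gone: all values near one of the two plateau levels
  lo <- filt[, 1:18]; hi <- filt[, 23:40]
  expect_lt(max(abs(lo - median(lo))), 10)
  expect_lt(max(abs(hi - median(hi))), 10)
  # edge position preserved within 1 px
  prof <- colMeans(filt)
  expect_lte(abs(which.max(diff(prof)) - 20), 1)
})

test_that("reflection removal masks compact bright blobs and inpaints them", {
  g <- matrix(120, 100, 100)
  rr <- matrix(1:100, 100, 100); cc <- t(rr)
  disk <- (rr - 50)^2 + (cc - 50)^2 <= 5^2
  g[disk] <- 255
  out <- remove_reflections(g)
  expect_gte(sum(out$mask & disk) / sum(disk), 0.95)
  expect_lt(sum(out$mask & !disk), 20)
  expect_lt(max(abs(out$image - 120)), 5)
  # unimodal image: negligible mask
  set.seed(1)
  noise <- matrix(rnorm(1e4, 120, 5), 100, 100)
  expect_lt(mean(remove_reflections(noise)$mask), 0.01)
  # flat zero image: unchanged
  z <- matrix(0, 30, 30)
  out0 <- remove_reflections(z)
  expect_false(any(out0$mask))
  expect_identical(out0$image, z)
})

test_that("reflection removal is idempotent within the inpainting zone", {
  g <- matrix(120, 100, 100)
  rr <- matrix(1:100, 100, 100); cc <- t(rr)
  g[(rr - 30)^2 + (cc - 60)^2 <= 4^2] <- 250
  first <- remove_reflections(g)
  second <- remove_reflections(first$image)
  expect_lt(mean(second$image != first$image), 0.001)
})

test_that("the full preprocessing pipeline runs in the fixed order", {
  eye <- eye_spec(220, 220, cornea_radius = 80)
  out <- render_eye(eye, stain_spec(
    seed = 1, reflection_spots = list(list(center = c(75, 110), radius = 7))))
  pp <- preprocess_image(out$image, preproc_config(median_kernel = 3))
  expect_identical(dim(pp$image), c(220L, 220L))
  expect_gt(sum(pp$reflection_mask), 20)   # the saturated spot was caught
  # masked pixels were pulled down toward the corneal background
  expect_lt(mean(pp$image[pp$reflection_mask]), 240)
})
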