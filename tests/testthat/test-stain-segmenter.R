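# naive geodesic reconstruction oracle: explicit per-pixel neighbourhood
# maxima, no package morphology
naive_reconstruct <- function(marker, mask_img) {
  cur <- pmin(marker, mask_img)
  nr <- nrow(cur); nc <- ncol(cur)
  repeat {
    nxt <- cur
    for (i in 1:nr) for (j in 1:nc) {
      rs <- max(1, i - 1):min(nr, i + 1); cs <- max(1, j - 1):min(nc, j + 1)
      nxt[i, j] <- min(max(cur[rs, cs]), mask_img[i, j])
    }
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

test_that("top-hat by reconstruction is zero on flat and smooth images", {
  flat <- matrix(80, 50, 50)
  expect_true(all(tophat_reconstruction(flat, 5) == 0))
  # a smooth ramp is restored by the reconstruction away from the border
  # where its maximum is clipped by the opening
  ramp <- matrix(seq(20, 180, length.out = 50), 50, 50)
  expect_lt(max(tophat_reconstruction(ramp, 5)[1:44, ]), 1e-6)
  expect_error(tophat_reconstruction(matrix(0, 10, 10), 8), "larger")
})

test_that("reconstruction matches a naive geodesic oracle", {
  set.seed(7)
  mask_img <- matrix(runif(400, 0, 100), 20, 20)
  marker <- pmax(mask_img - runif(400, 0, 50), 0)
  expect_equal(reconstruct_dilation(marker, mask_img),
               naive_reconstruct(marker, mask_img))
})

test_that("an isolated peak is returned at full contrast over background", {
  g <- flat_roi(60, 80, rbind(c(30, 40)), radius = 4, peak = 120, bg = 70)
  th <- tophat_reconstruction(g[, , 2], 10)
  expect_gt(th[30, 40], 100)            # peak minus background level
  expect_lt(max(th[1:10, 1:10]), 1e-6)  # background exactly removed
  expect_true(all(th >= 0))
})

test_that("detection is invariant to additive intensity offsets", {
  g <- flat_roi(60, 80, rbind(c(30, 25), c(35, 60)), radius = 4,
                peak = 130, bg = 40, noise = 2, seed = 3)
  mask <- matrix(TRUE, 60, 80)
  cfg <- segment_config(mask_margin = 0)
  a <- segment_stains(g, mask, cfg)
  g2 <- g; g2[, , 2] <- pmin(g2[, , 2] + 60, 255)
  b <- segment_stains(g2, mask, cfg)
  expect_identical(a$n, b$n)
  expect_equal(a$centroids, b$centroids, tolerance = 0.2)
})

test_that("disjoint dots are segmented one-to-one against ground truth", {
  centers <- rbind(c(20, 20), c(20, 60), c(20, 100), c(45, 30), c(45, 75),
                   c(45, 115), c(70, 50))
  g <- flat_roi(90, 140, centers, radius = 4, peak = 140, bg = 50,
                noise = 2, seed = 5)
  sm <- segment_stains(g, matrix(TRUE, 90, 140), segment_config(mask_margin = 0))
  expect_identical(sm$n, 7L)
  # each region overlaps its generating dot at IoU >= 0.5
  rr <- matrix(1:90, 90, 140); cc <- matrix(1:140, 90, 140, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    gt <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= 16
    ious <- vapply(seq_len(sm$n), function(k) {
      det <- sm$labels == k
      sum(det & gt) / sum(det | gt)
    }, numeric(1))
    expect_gte(max(ious), 0.5)
  }
})

test_that("overlapping dots merge into a single region", {
  g <- flat_roi(60, 80, rbind(c(30, 38), c(30, 44)), radius = 5,
                peak = 140, bg = 50)
  sm <- segment_stains(g, matrix(TRUE, 60, 80), segment_config(mask_margin = 0))
  expect_identical(sm$n, 1L)
})

test_that("stain-free input yields zero regions and empty masks error", {
  g <- flat_roi(60, 80, NULL, bg = 50, noise = 3, seed = 2)
  sm <- segment_stains(g, matrix(TRUE, 60, 80), segment_config(mask_margin = 0))
  expect_identical(sm$n, 0L)
  expect_error(segment_stains(g, matrix(FALSE, 60, 80)), "empty ROI")
})

test_that("stain maps keep counts, centroids and areas consistent", {
  m <- random_stain_mask(12, seed = 8)
  sm <- stain_map(m)
  expect_identical(sm$n, 12L)
  expect_identical(length(sm$areas), 12L)
  expect_identical(length(sm$perimeters), 12L)
  expect_identical(nrow(sm$centroids), 12L)
  expect_equal(sum(sm$areas), sum(m))
  for (i in seq_len(sm$n)) {
    idx <- which(sm$labels == i, arr.ind = TRUE)
    expect_gte(sm$centroids[i, 1], min(idx[, 1]))
    expect_lte(sm$centroids[i, 1], max(idx[, 1]))
    expect_gte(sm$centroids[i, 2], min(idx[, 2]))
    expect_lte(sm$centroids[i, 2], max(idx[, 2]))
  }
})
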