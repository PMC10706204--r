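test_that("the nine image forms have the canonical identities", {
  const <- matrix(100, 24, 30)
  forms <- make_forms(const)
  expect_length(forms, 9)
  expect_identical(vapply(forms, `[[`, "", "name"),
                   c("original", "log-sigma-1", "log-sigma-2", "log-sigma-3",
                     "wavelet-LL", "wavelet-LH", "wavelet-HL", "wavelet-HH",
                     "lbp"))
  for (k in 2:4) expect_lt(max(abs(forms[[k]]$pixels)), 1e-6)   # LoG of flat
  expect_equal(unique(as.vector(forms[[5]]$pixels)), 200)       # Haar LL = 2c
  for (k in 6:8) expect_lt(max(abs(forms[[k]]$pixels)), 1e-9)   # detail = 0
  expect_error(make_forms(matrix(0, 1, 5)), "2x2")
})

test_that("first-order features match closed forms", {
  const <- matrix(7, 10, 10)
  f <- first_order(const, matrix(TRUE, 10, 10))
  expect_length(f, 18)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Skewness"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  # two-value image
  two <- matrix(c(0, 255), 10, 10)
  f2 <- first_order(two, matrix(TRUE, 10, 10))
  expect_equal(unname(f2["Mean"]), 127.5)
  expect_equal(unname(f2["Variance"]), 127.5^2)
  expect_equal(unname(f2["RootMeanSquared"]), sqrt(mean(two^2)))
  # skewness of a right-skewed sample equals the direct moment formula
  set.seed(9)
  v <- rexp(400)
  m <- matrix(v, 20, 20)
  f3 <- first_order(m, matrix(TRUE, 20, 20))
  mu <- mean(v); s2 <- mean((v - mu)^2)
  expect_equal(unname(f3["Skewness"]), mean((v - mu)^3) / s2^1.5)
  expect_gt(f3["Skewness"], 0)
  expect_equal(unname(f3["Kurtosis"]), mean((v - mu)^4) / s2^2)
})

test_that("first-order features ignore mask pixel ordering", {
  set.seed(2)
  m <- matrix(runif(120, 0, 255), 10, 12)
  mask <- matrix(runif(120) < 0.7, 10, 12)
  f1 <- first_order(m, mask)
  f2 <- first_order(t(m), t(mask))
  expect_equal(f1, f2)
})

test_that("GLCM values match a hand-built co-occurrence table", {
  # 4x4 two-level image; hand-count horizontal co-occurrences
  img <- matrix(c(1, 1, 2, 2,
                  1, 1, 2, 2,
                  1, 2, 1, 2,
                  2, 2, 2, 1), 4, 4, byrow = TRUE) * 100
  mask <- matrix(TRUE, 4, 4)
  lev <- cfstopo:::discretize(img[mask], 2)
  P <- cfstopo:::glcm_matrix(lev, mask, 2, c(0L, 1L))
  # horizontal neighbour pairs, symmetric counts
  a <- matrix(lev, 4, 4)
  cnt <- matrix(0, 2, 2)
  for (i in 1:4) for (j in 1:3) {
    cnt[a[i, j], a[i, j + 1]] <- cnt[a[i, j], a[i, j + 1]] + 1
    cnt[a[i, j + 1], a[i, j]] <- cnt[a[i, j + 1], a[i, j]] + 1
  }
  expect_equal(P, cnt / sum(cnt))
  feats <- cfstopo:::glcm_features_one(P, 2)
  ii <- matrix(1:2, 2, 2); jj <- t(ii)
  expect_equal(unname(feats["Autocorrelation"]), sum(ii * jj * P))
  expect_equal(unname(feats["Contrast"]), sum((ii - jj)^2 * P))
  expect_equal(unname(feats["MaximumProbability"]), max(P))
})

test_that("checkerboard GLCM contrast is maximal for two-level images", {
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 255
  mask <- matrix(TRUE, 8, 8)
  lev <- cfstopo:::discretize(chk[mask], 2)
  P <- cfstopo:::glcm_matrix(lev, mask, 2, c(0L, 1L))
  f <- cfstopo:::glcm_features_one(P, 2)
  expect_equal(unname(f["Contrast"]), 1)  # all pairs differ by one level
})

test_that("single-level images give the defined degenerate limits", {
  const <- matrix(42, 12, 12)
  mask <- matrix(TRUE, 12, 12)
  f <- matrix_features(const, mask, 32)
  expect_length(f, 75)
  expect_false(anyNA(f))
  # GLRLM and GLSZM gray-level non-uniformity normalized = 1 at one level
  # (positions: GLCM 1-24, GLDM 25-38, GLRLM 39-54, GLSZM 55-70)
  expect_equal(unname(f[40]), 1)
  expect_equal(unname(f[56]), 1)
})

test_that("run-length and zone matrices count hand-checkable patterns", {
  # 1 row: levels 1 1 1 2 2 -> runs (1,3) and (2,2)
  img <- matrix(c(0, 0, 0, 255, 255), 1, 5)
  mask <- matrix(TRUE, 1, 5)
  lev <- cfstopo:::discretize(img[mask], 2)
  R <- cfstopo:::glrlm_matrix(lev, mask, 2, c(0L, 1L))
  expect_equal(R[1, 3], 1)
  expect_equal(R[2, 2], 1)
  expect_equal(sum(R), 2)
  # two separate zones of the same level
  z <- matrix(0, 5, 7)
  z[1:2, 1:2] <- 255; z[4:5, 5:6] <- 255
  f <- cfstopo:::glszm_features(cfstopo:::discretize(z[z > -1], 2),
                                matrix(TRUE, 5, 7), 2)
  # zones: one 27-px background zone and two 4-px bright zones
  expect_equal(unname(f["ZonePercentage"]), 3 / 35)
})

test_that("texture blocks have the contracted shape and anchored names", {
  set.seed(3)
  roi <- matrix(runif(30 * 40, 0, 255), 30, 40)
  mask <- matrix(TRUE, 30, 40)
  tb <- texture_block(roi, mask)
  expect_length(tb, 837)
  expect_false(anyNA(tb))
  d <- feature_dictionary()
  expect_identical(nrow(d), 974L)
  expect_match(d$definition[d$name == "texture-4-15"],
               "Skewness of log-sigma-3")
  expect_match(d$definition[d$name == "texture-4-79"],
               "GLSZM LargeAreaLowGrayLevelEmphasis of log-sigma-3")
  expect_match(d$definition[d$name == "morphology-5"], "MeanCircularity")
  expect_match(d$definition[d$name == "morphology-3"],
               "MeanPerimeterAreaRatio")
  expect_match(d$definition[d$name == "topology-14-5"],
               "diameter at dilation scale 56")
  expect_match(d$definition[d$name == "topology-2-1"],
               "number of subgraphs at dilation scale 8")
})

test_that("morphological features match exact pixel geometry", {
  # two 10x10 squares
  m <- matrix(FALSE, 40, 60)
  m[5:14, 5:14] <- TRUE; m[20:29, 35:44] <- TRUE
  mb <- morph_block(stain_map(m))
  expect_length(mb, 9)
  expect_equal(unname(mb["morphology-1"]), 100)  # mean area
  expect_equal(unname(mb["morphology-2"]), 200)  # total area
  expect_equal(unname(mb["morphology-9"]), 2)    # number
  expect_equal(unname(mb["morphology-8"]), 1)    # squares: aspect 1
  # a filled disk is nearly circular, an elongated bar is not
  rr <- matrix(1:60, 60, 60); cc <- t(rr)
  disk <- stain_map((rr - 30)^2 + (cc - 30)^2 <= 20^2)
  md <- morph_block(disk)
  expect_gt(md["morphology-5"], 0.85)
  expect_lt(md["morphology-5"], 1.15)
  bar <- matrix(FALSE, 30, 30); bar[10:12, 4:27] <- TRUE
  expect_equal(unname(morph_block(stain_map(bar))["morphology-8"]), 3 / 24)
  # empty map
  expect_true(all(morph_block(stain_map(matrix(FALSE, 10, 10))) == 0))
})

test_that("circularity stays near or below one for all regions", {
  for (seed in 1:3) {
    sm <- stain_map(random_stain_mask(8, seed = seed))
    mb <- morph_block(sm)
    expect_lte(mb["morphology-5"], 1.2)
  }
})
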