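test_that("OSS scoring follows the dot-count bands and modifier points", {
  expect_identical(oss_score(0), 0L)
  expect_identical(oss_score(1), 1L)
  expect_identical(oss_score(5), 1L)
  expect_identical(oss_score(6), 2L)
  expect_identical(oss_score(12), 2L)
  expect_identical(oss_score(30), 2L)
  expect_identical(oss_score(31), 3L)
  expect_identical(oss_score(200), 3L)
  expect_identical(oss_score(12, has_confluent = TRUE), 3L)
  expect_identical(oss_score(31, TRUE, TRUE, FALSE), 5L)
  expect_error(oss_score(-1), "non-negative")
})

test_that("OSS total is capped at 5 over every flag combination", {
  for (cnt in c(0, 3, 12, 31, 100))
    for (cf in c(FALSE, TRUE)) for (ce in c(FALSE, TRUE))
      for (fi in c(FALSE, TRUE)) {
        s <- oss_score(cnt, cf, ce, fi)
        expect_gte(s, 0); expect_lte(s, 5)
        base <- c(0, 1, 2, 3)[findInterval(cnt, c(0, 1, 6, 31))]
        expect_identical(s, as.integer(min(base + cf + ce + fi, 5)))
      }
})

test_that("rendering is deterministic and stain-free eyes score 0", {
  eye <- eye_spec(220, 220, cornea_radius = 80)
  st <- stain_spec(seed = 5)
  a <- render_eye(eye, st); b <- render_eye(eye, st)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$region_count, 0L)
  expect_identical(a$truth$oss_grade, 0L)
})

test_that("well-separated dots are counted and graded correctly", {
  eye <- eye_spec(220, 220, cornea_radius = 80)
  dots <- rbind(c(160, 90), c(160, 130), c(175, 110))
  out <- render_eye(eye, stain_spec(dot_centers = dots, dot_radii = 4,
                                    seed = 2))
  expect_identical(out$truth$region_count, 3L)
  expect_identical(out$truth$oss_grade, 1L)
  # label consistency and mask geometry
  expect_identical(out$truth$oss_grade,
                   oss_score(out$truth$region_count,
                             out$truth$has_confluent,
                             out$truth$has_central,
                             out$truth$has_filament))
  expect_true(all(out$truth$stain_mask[cbind(dots[, 1], dots[, 2])]))
})

test_that("stain geometry outside the cornea is rejected", {
  eye <- eye_spec(220, 220, cornea_radius = 80)
  expect_error(render_eye(eye, stain_spec(dot_centers = rbind(c(10, 10)),
                                          dot_radii = 4)),
               "outside the cornea")
})

test_that("central staining and confluent patches raise the grade", {
  eye <- eye_spec(220, 220, cornea_radius = 80)
  # one dot right below the pupil centre, inside 0.35 R
  out <- render_eye(eye, stain_spec(dot_centers = rbind(c(130, 110)),
                                    dot_radii = 4, seed = 1))
  expect_true(out$truth$has_central)
  expect_identical(out$truth$oss_grade, 2L)  # 1 dot + central point
  patch <- list(center = c(150, 110), radii = c(6, 14), angle = 0)
  out2 <- render_eye(eye, stain_spec(confluent_patches = list(patch),
                                     seed = 1))
  expect_true(out2$truth$has_confluent)
  expect_gte(sum(out2$truth$stain_mask), 120)
})

test_that("cohorts are stratified, labelled consistently, and reproducible", {
  co <- make_cohort(20, seed = 3, image_size = 220)
  g <- vapply(co, function(e) e$truth$oss_grade, integer(1))
  expect_identical(as.integer(table(factor(g, levels = 0:4))),
                   rep(4L, 5))
  for (e in co)
    expect_identical(e$truth$oss_grade,
                     oss_score(e$truth$region_count, e$truth$has_confluent,
                               e$truth$has_central, e$truth$has_filament))
  co2 <- make_cohort(20, seed = 3, image_size = 220)
  expect_identical(co[[7]]$image, co2[[7]]$image)
  co3 <- make_cohort(6, grade_mix = c(`0` = 1), seed = 1, image_size = 220)
  expect_true(all(vapply(co3, function(e) e$truth$region_count,
                         integer(1)) == 0L))
  expect_error(make_cohort(5, grade_mix = c(`7` = 1)), "grades")
  expect_error(make_cohort(5, grade_mix = c(`0` = 0.5, `1` = 0.2)),
               "sum to 1")
})

test_that("written cohorts round-trip through PNG and the manifest", {
  dir <- withr::local_tempdir()
  co <- make_cohort(3, grade_mix = c(`1` = 1), seed = 9, image_size = 180)
  man <- write_cohort(co, dir)
  expect_identical(nrow(man), 3L)
  expect_true(all(file.exists(file.path(dir, man$filename))))
  img <- read_eye_image(file.path(dir, man$filename[1]))
  expect_identical(dim(img), c(180L, 180L, 3L))
  # PNG quantizes to 1/255 steps
  expect_lt(max(abs(img - co[[1]]$image)), 0.51)
})
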