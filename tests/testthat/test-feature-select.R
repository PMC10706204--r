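# shared synthetic selection problem: grade-driven features plus noise
make_selection_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  y <- rep(0:4, length.out = n)
  x <- cbind(
    signal1 = y + rnorm(n, 0, 0.3),
    signal2 = 2 * y + rnorm(n, 0, 0.5),
    dup = NA,
    const = 5,
    matrix(rnorm(n * 10), n, 10,
           dimnames = list(NULL, sprintf("noise%02d", 1:10))))
  x[, "dup"] <- x[, "signal1"]
  nz <- normalize_features(x)
  list(x = nz$x, y = y)
}

test_that("the ANOVA filter keeps signal and drops constants and noise", {
  d <- make_selection_data()
  res <- anova_filter(d$x, d$y, alpha = 0.05)
  expect_true(all(c("signal1", "signal2", "dup") %in% res$retained))
  expect_false("const" %in% res$retained)
  # most pure-noise features are removed at alpha = 0.05
  noise_kept <- grepl("^noise", res$retained)
  expect_lt(mean(noise_kept), 0.5)
  expect_error(anova_filter(d$x, rep(0, nrow(d$x))), "2 classes")
  expect_error(anova_filter(d$x[1:6, ], c(0, 0, 1, 1, 2, 3)), "2 samples")
})

test_that("ANOVA false-positive rate is calibrated under the null", {
  set.seed(42)
  kept <- 0; total <- 0
  for (rep in 1:5) {
    x <- matrix(rnorm(200 * 40), 200, 40,
                dimnames = list(NULL, sprintf("n%02d", 1:40)))
    y <- rep(0:4, each = 40)
    res <- anova_filter(x, y, alpha = 0.05)
    kept <- kept + length(res$retained); total <- total + 40
  }
  expect_lt(kept / total, 0.12)  # ~5% expected
})

test_that("the redundancy filter collapses correlated features", {
  d <- make_selection_data()
  f <- anova_filter(d$x, d$y)$f
  kept <- pearson_redundancy_filter(d$x, c("signal1", "dup", "noise01"),
                                    f, threshold = 0.9)
  expect_identical(sum(kept %in% c("signal1", "dup")), 1L)
  expect_true("noise01" %in% kept)
  # a feature and its negation: exactly one survives
  x2 <- cbind(a = rnorm(100), b = NA)
  x2[, "b"] <- -x2[, "a"]
  expect_length(pearson_redundancy_filter(x2, c("a", "b"),
                                          c(a = 2, b = 1), 0.9), 1)
  # independent features both survive
  set.seed(3)
  x3 <- cbind(u = rnorm(200), v = rnorm(200))
  expect_length(pearson_redundancy_filter(x3, c("u", "v"),
                                          c(u = 2, v = 1), 0.9), 2)
})

test_that("backward elimination keeps the informative regressor", {
  set.seed(11)
  n <- 300
  f1 <- rnorm(n)
  y <- 2 * f1 + rnorm(n, 0, 0.5)
  x <- cbind(f1 = f1, matrix(rnorm(n * 10), n, 10,
                             dimnames = list(NULL, sprintf("n%02d", 1:10))))
  kept <- backward_elimination(x, y, p_out = 0.05)
  expect_true("f1" %in% kept)
  expect_lte(length(kept), 4)
  # all-noise design collapses to the floor
  set.seed(12)
  xn <- matrix(rnorm(200 * 8), 200, 8,
               dimnames = list(NULL, sprintf("n%d", 1:8)))
  expect_lte(length(backward_elimination(xn, rnorm(200), p_out = 0.05)), 3)
  # a single informative feature is returned unchanged
  expect_identical(backward_elimination(x[, "f1", drop = FALSE], y), "f1")
  # exact collinears are dropped before testing
  xc <- cbind(a = f1, b = f1, c = rnorm(n))
  keptc <- backward_elimination(xc, y, p_out = 0.05)
  expect_lte(sum(c("a", "b") %in% keptc), 1)
})

test_that("tree importance ranks separating features first", {
  set.seed(5)
  n <- 250
  y <- rep(0:4, each = 50)
  x <- cbind(perfect = y, flatline = 0,
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, sprintf("n%d", 1:6))))
  sig <- tree_importance(x, y, seed = 2)
  expect_s3_class(sig, "cfs_signature")
  expect_identical(sig$name[1], "perfect")
  expect_true(all(diff(sig$importance) <= 0))
  # a feature the tree cannot use carries zero importance
  expect_identical(sig$importance[sig$name == "flatline"], 0)
})

test_that("signature subsets respect their category filters", {
  sig <- data.frame(
    name = c("topology-1-1", "texture-1-5", "topology-2-3", "morphology-5",
             "topology-3-1", "texture-2-9", "topology-4-2", "topology-5-8",
             "morphology-1", "texture-3-3", "topology-6-6", "texture-4-15"),
    importance = seq(12, 1), rank = 1:12)
  class(sig) <- c("cfs_signature", class(sig))
  subs <- build_signatures(sig)
  expect_length(subs$A10, 10)
  expect_identical(subs$T5, c("topology-1-1", "topology-2-3", "topology-3-1",
                              "topology-4-2", "topology-5-8"))
  expect_false(any(grepl("^topology-", subs$NT5)))
  expect_false(any(grepl("^topology-", subs$NT10)))
  expect_warning(build_signatures(sig[1:3, ]), "only")
})

test_that("the cascade nests and keeps grade-driven features", {
  d <- make_selection_data(n = 400, seed = 7)
  sel <- select_features(d$x, d$y)
  expect_true(all(sel$prbf %in% sel$anova))
  expect_true(all(sel$backward %in% sel$prbf))
  expect_true(all(sel$signature$name %in% sel$backward))
  expect_true(any(c("signal1", "signal2", "dup") %in%
                    head(sel$signature$name, 2)))
})
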