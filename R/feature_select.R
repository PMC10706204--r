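#' Z-score normalization with frozen training statistics
#'
#' Centers and scales columns by training mean and standard deviation.
#' Zero-variance columns are mapped to 0 so the normalized table never
#' contains missing values.
#'
#' @param x numeric matrix (images x features).
#' @param stats optional list `(center, scale)` from a previous call; when
#'   supplied (e.g. for a test split) those statistics are reused.
#' @return list `(x, center, scale)`.
#' @export
normalize_features <- function(x, stats = NULL) {
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else {
    center <- stats$center; scale <- stats$scale
  }
  s <- ifelse(scale < 1e-12, 1, scale)
  z <- sweep(sweep(x, 2, center), 2, s, "/")
  z[, scale < 1e-12] <- 0
  list(x = z, center = center, scale = scale)
}

#' One-way ANOVA feature filter
#'
#' Retains features whose one-way F test across the grade classes is
#' significant at `alpha`. Constant features (zero between-class variance
#' or zero overall variance) are removed.
#'
#' @param x normalized feature matrix with column names.
#' @param y grade labels (>= 2 classes, each with >= 2 samples).
#' @param alpha significance level.
#' @return list `(retained, f, p)`; `f` and `p` are named vectors over all
#'   testable features.
#' @export
anova_filter <- function(x, y, alpha = 0.05) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  res <- apply(x, 2, function(v) {
    if (stats::sd(v) < 1e-12) return(c(NA_real_, 1))
    ft <- tryCatch(stats::oneway.test(v ~ y, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$statistic)) c(NA_real_, 1)
    else c(ft$statistic, ft$p.value)
  })
  f <- res[1, ]; p <- res[2, ]
  list(retained = colnames(x)[!is.na(f) & p < alpha], f = f, p = p)
}

#' Pearson redundancy-based filter (PRBF)
#'
#' Greedy scan over features in descending ANOVA-F order: a feature is
#' dropped when its absolute Pearson correlation with any already-kept
#' feature reaches the threshold.
#'
#' @param x normalized feature matrix.
#' @param names features to scan, or `NULL` for all columns.
#' @param f named F statistics used for ordering (ties broken by name).
#' @param threshold absolute-correlation cutoff.
#' @return character vector of retained feature names.
#' @export
pearson_redundancy_filter <- function(x, names = NULL, f = NULL,
                                      threshold = 0.9) {
  names <- names %||% colnames(x)
  ord <- if (is.null(f)) names
  else names[order(-f[names], names)]
  kept <- character(0)
  for (nm in ord) {
    if (!length(kept)) { kept <- nm; next }
    r <- suppressWarnings(abs(stats::cor(x[, nm], x[, kept, drop = FALSE])))
    r[is.na(r)] <- 0
    if (max(r) < threshold) kept <- c(kept, nm)
  }
  kept
}

#' Backward elimination on a linear model of the grade
#'
#' Treats the 0-4 grade as a numeric response, fits ordinary least squares
#' on the candidate features, and repeatedly removes the coefficient with
#' the largest p-value while it exceeds `p_out`, stopping when all
#' coefficients are significant or only two features remain. Exactly
#' collinear features (aliased coefficients) are dropped first.
#'
#' @param x normalized feature matrix.
#' @param y numeric grades.
#' @param names candidate feature names (default all columns).
#' @param p_out exit p-value threshold.
#' @return character vector of retained feature names.
#' @export
backward_elimination <- function(x, y, names = NULL, p_out = 0.05) {
  names <- names %||% colnames(x)
  cur <- names
  repeat {
    if (length(cur) <= 2) return(cur)
    df <- as.data.frame(x[, cur, drop = FALSE])
    safe <- sprintf("f%d", seq_along(cur))
    colnames(df) <- safe
    df$.y <- as.numeric(y)
    fit <- stats::lm(.y ~ ., data = df)
    co <- stats::coef(fit)[-1]
    if (anyNA(co)) {           # aliased: drop all exactly collinear terms
      cur <- cur[!is.na(co)]
      next
    }
    pv <- summary(fit)$coefficients[-1, 4]
    pv[!is.finite(pv)] <- 1   # saturated/unestimable: treat as removable
    if (all(pv < p_out)) return(cur)
    cur <- cur[-which.max(pv)]
  }
}

#' Gini-impurity feature importance from a decision tree
#'
#' Fits a CART classification tree (gini splitting) on the retained
#' features and ranks them by total impurity decrease; ties are broken by
#' canonical name order and unused features get importance 0.
#'
#' @param x normalized feature matrix.
#' @param y grade labels.
#' @param names candidate features.
#' @param seed RNG seed (CART is deterministic; the seed pins any
#'   tie-breaking in surrogate ordering).
#' @return data frame of class `cfs_signature`: `name`, `importance`,
#'   `rank`, ordered by rank.
#' @export
tree_importance <- function(x, y, names = NULL, seed = 1L) {
  names <- names %||% colnames(x)
  df <- as.data.frame(x[, names, drop = FALSE])
  safe <- sprintf("f%d", seq_along(names))
  colnames(df) <- safe
  df$.y <- factor(y)
  fit <- with_seed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(cp = 1e-4, minsplit = 5, xval = 0)))
  imp <- stats::setNames(numeric(length(names)), names)
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names[match(names(vi), safe)]] <- vi
  ord <- order(-imp, names(imp))
  out <- data.frame(name = names(imp)[ord], importance = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  class(out) <- c("cfs_signature", class(out))
  out
}

#' The four alternative signatures
#'
#' From a ranked signature: the overall top-10 (`A10`), the top-10
#' non-topological (`NT10`), the top-5 topological (`T5`) and the top-5
#' non-topological (`NT5`) features. When fewer features are available than
#' requested, all are taken with a warning.
#'
#' @param signature a [tree_importance()] ranking.
#' @return named list of character vectors.
#' @export
build_signatures <- function(signature) {
  nm <- signature$name
  topo <- grepl("^topology-", nm)
  take <- function(v, k, label) {
    if (length(v) < k) warning("only ", length(v), " features for ", label)
    utils::head(v, k)
  }
  list(A10 = take(nm, 10, "A10"),
       NT10 = take(nm[!topo], 10, "NT10"),
       T5 = take(nm[topo], 5, "T5"),
       NT5 = take(nm[!topo], 5, "NT5"))
}

#' The full four-step selection cascade
#'
#' ANOVA filter, Pearson redundancy filter, backward elimination, and
#' decision-tree gini importance ranking, run on (normalized) training
#' data only. Retained sets nest across stages.
#'
#' @param x normalized training feature matrix.
#' @param y training grades.
#' @param alpha ANOVA significance level.
#' @param cor_threshold PRBF cutoff.
#' @param p_out backward-elimination exit threshold.
#' @param seed tie-break seed for the tree.
#' @return list `(anova, prbf, backward, signature, subsets)` where
#'   `signature` is the ranked importance table and `subsets` the four
#'   signatures of [build_signatures()].
#' @export
select_features <- function(x, y, alpha = 0.05, cor_threshold = 0.9,
                            p_out = 0.05, seed = 1L) {
  an <- anova_filter(x, y, alpha)
  if (!length(an$retained)) stop("ANOVA filter retained no features")
  pr <- pearson_redundancy_filter(x, an$retained, an$f, cor_threshold)
  bw <- backward_elimination(x, y, pr, p_out)
  sig <- tree_importance(x, y, bw, seed)
  list(anova = an$retained, prbf = pr, backward = bw, signature = sig,
       subsets = build_signatures(sig))
}
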