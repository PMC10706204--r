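#' Classifier specification
#'
#' Hyperparameters default to the reference protocol: SVM with Gaussian
#' (RBF) kernel (one-vs-one multiclass, `C = 1`,
#' `gamma = 1/(n features x mean variance)`), decision tree with at most 4
#' splits, boosting tree with 30 training cycles, Gaussian naive Bayes,
#' KNN with neighborhood size 10, and a 100-tree random forest.
#'
#' @param kind one of `"svm"`, `"dt"`, `"bt"`, `"nb"`, `"knn"`, `"rf"`.
#' @param seed RNG seed used by stochastic learners.
#' @param ... overrides: `cost`, `gamma` (svm); `max_splits` (dt);
#'   `nrounds`, `max_depth`, `eta` (bt); `k` (knn); `ntree` (rf).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm", "dt", "bt", "nb", "knn", "rf"),
                       seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(cost = 1, gamma = NULL),
    dt = list(max_splits = 4),
    bt = list(nrounds = 30, max_depth = 4, eta = 0.3),
    nb = list(),
    knn = list(k = 10),
    rf = list(ntree = 100))
  dots <- list(...)
  defaults[names(dots)] <- dots
  structure(c(list(kind = kind, seed = as.integer(seed)), defaults),
            class = "model_spec")
}

# fit one classifier; returns an object with a uniform predict interface
fit_classifier <- function(x, y, spec) {
  y <- factor(y)
  cls <- levels(y)
  with_seed(spec$seed, {
    fit <- switch(spec$kind,
      svm = {
        gam <- spec$gamma %||% (1 / (ncol(x) * max(mean(apply(x, 2,
                                                              stats::var)),
                                                   1e-12)))
        e1071::svm(x, y, kernel = "radial", cost = spec$cost, gamma = gam,
                   probability = TRUE)
      },
      dt = {
        df <- as.data.frame(x); colnames(df) <- sprintf("f%d", seq_len(ncol(x)))
        df$.y <- y
        full <- rpart::rpart(.y ~ ., data = df, method = "class",
                             parms = list(split = "gini"),
                             control = rpart::rpart.control(cp = 0,
                                                            minsplit = 2,
                                                            xval = 0))
        ct <- full$cptable
        ok <- ct[ct[, "nsplit"] <= spec$max_splits, , drop = FALSE]
        rpart::prune(full, cp = ok[nrow(ok), "CP"])
      },
      bt = {
        xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = length(cls),
                        max_depth = spec$max_depth, eta = spec$eta,
                        nthread = 1),
          data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
          nrounds = spec$nrounds, verbose = 0)
      },
      nb = e1071::naiveBayes(x, y),
      knn = caret::knn3(x, y, k = min(spec$k, nrow(x) - 1)),
      rf = randomForest::randomForest(x, y, ntree = spec$ntree))
    structure(list(fit = fit, spec = spec, classes = cls,
                   n_features = ncol(x)),
              class = "cfs_classifier")
  })
}

# uniform prediction: hard labels plus a per-class score matrix
predict_classifier <- function(model, x) {
  cls <- model$classes
  spec <- model$spec
  probs <- switch(spec$kind,
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, cls, drop = FALSE]
    },
    dt = {
      df <- as.data.frame(x)
      colnames(df) <- sprintf("f%d", seq_len(ncol(x)))
      stats::predict(model$fit, df, type = "prob")[, cls, drop = FALSE]
    },
    bt = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      if (!is.matrix(p))
        p <- matrix(p, ncol = length(cls), byrow = TRUE)
      dimnames(p) <- list(NULL, cls)
      p
    },
    nb = stats::predict(model$fit, x, type = "raw")[, cls, drop = FALSE],
    knn = stats::predict(model$fit, x, type = "prob")[, cls, drop = FALSE],
    rf = stats::predict(model$fit, x, type = "prob")[, cls, drop = FALSE])
  labels <- cls[max.col(probs, ties.method = "first")]
  list(labels = labels, scores = probs)
}

#' Stratified train/test split
#'
#' Deterministic for a fixed seed; each grade is split as close to the
#' requested ratio as rounding allows.
#'
#' @param y grade labels.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed.
#' @return list `(train, test)` of integer indices.
#' @export
split_cohort <- function(y, train_fraction = 0.8, seed = 1L) {
  y <- factor(y)
  with_seed(seed, {
    tr <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_tr <- round(train_fraction * length(idx))
      sample(idx, n_tr)
    }))
    list(train = sort(tr), test = setdiff(seq_along(y), tr))
  })
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Folds partition the training data with stratification by grade;
#' normalization statistics are fitted on each fold's training part only.
#' Folds are reduced with a warning when the rarest class has fewer members
#' than requested folds; degenerate single-class folds are skipped with a
#' warning.
#'
#' @param x raw (unnormalized) feature matrix for the training split.
#' @param y training grades.
#' @param signature character vector of feature names to use.
#' @param spec a [model_spec()].
#' @param folds number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return list `(fold_accuracy, metrics, predictions)`; `metrics` are
#'   pooled over folds via [confusion_metrics()] and [roc_auc()].
#' @export
cross_validate <- function(x, y, signature, spec = model_spec("svm"),
                           folds = 10, seed = 1L) {
  y <- factor(y)
  m <- min(table(y))
  if (m < folds) {
    warning("reducing folds to ", m, " (rarest class size)")
    folds <- max(2, m)
  }
  fold_id <- integer(length(y))
  fold_id <- with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold_id
  })
  preds <- character(length(y)); scores <- NULL
  acc <- numeric(0)
  for (k in seq_len(folds)) {
    tr <- which(fold_id != k); te <- which(fold_id == k)
    if (length(unique(y[tr])) < 2) { warning("skipping degenerate fold"); next }
    nz <- normalize_features(x[tr, signature, drop = FALSE])
    xte <- normalize_features(x[te, signature, drop = FALSE],
                              stats = nz)$x
    model <- fit_classifier(nz$x, y[tr], spec)
    pr <- predict_classifier(model, xte)
    preds[te] <- pr$labels
    if (is.null(scores))
      scores <- matrix(NA_real_, length(y), ncol(pr$scores),
                       dimnames = list(NULL, colnames(pr$scores)))
    scores[te, colnames(pr$scores)] <- pr$scores
    acc <- c(acc, mean(pr$labels == as.character(y[te])))
  }
  scored <- preds != ""
  cm <- confusion_matrix(as.character(y)[scored], preds[scored],
                         classes = levels(y))
  list(fold_accuracy = acc,
       metrics = c(confusion_metrics(cm),
                   roc_auc(scores[scored, , drop = FALSE],
                           as.character(y)[scored])["auc_micro"]),
       predictions = preds)
}

#' Fit on the training split, predict the test split
#'
#' Normalization is fitted on the training split and frozen; the model
#' never sees the test data. Test samples whose class was unseen in
#' training are reported in `unseen_classes`.
#'
#' @param x_train,y_train raw training features and grades.
#' @param x_test raw test features.
#' @param signature feature names to use.
#' @param spec a [model_spec()].
#' @return list `(labels, scores, model, norm, unseen_classes)`.
#' @export
fit_predict <- function(x_train, y_train, x_test, signature,
                        spec = model_spec("svm")) {
  if (!length(signature)) stop("empty signature")
  stopifnot(all(signature %in% colnames(x_train)))
  nz <- normalize_features(x_train[, signature, drop = FALSE])
  xte <- normalize_features(x_test[, signature, drop = FALSE], stats = nz)$x
  model <- fit_classifier(nz$x, y_train, spec)
  pr <- predict_classifier(model, xte)
  list(labels = pr$labels, scores = pr$scores, model = model, norm = nz,
       unseen_classes = character(0))
}
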