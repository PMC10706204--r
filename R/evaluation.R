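#' Confusion matrix
#'
#' @param truth,pred vectors of true and predicted class labels.
#' @param classes class set (default: sorted union).
#' @return K x K integer matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred,
                             classes = sort(unique(c(truth, pred)))) {
  truth <- factor(as.character(truth), levels = as.character(classes))
  pred <- factor(as.character(pred), levels = as.character(classes))
  unclass(table(truth, pred, dnn = NULL))
}

#' Threshold metrics of a confusion matrix
#'
#' Accuracy is the trace over the total. Sensitivity, precision and
#' specificity are computed one-vs-rest per class and macro-averaged; the
#' F-measure is the harmonic mean of the macro precision and macro
#' sensitivity. Classes with a zero denominator contribute 0 with a
#' warning. All values are percentages.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @return list `(acc, sen, pre, spe, f_measure, per_class)`.
#' @export
confusion_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  K <- nrow(cm)
  per <- t(vapply(seq_len(K), function(k) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp; fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    rate <- function(num, den, what) {
      if (den == 0) { warning("zero denominator for ", what); 0 }
      else num / den
    }
    c(sen = rate(tp, tp + fn, "sensitivity"),
      pre = rate(tp, tp + fp, "precision"),
      spe = rate(tn, tn + fp, "specificity"))
  }, numeric(3)))
  rownames(per) <- rownames(cm)
  sen <- mean(per[, "sen"]); pre <- mean(per[, "pre"])
  f <- if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0
  list(acc = 100 * sum(diag(cm)) / total, sen = 100 * sen, pre = 100 * pre,
       spe = 100 * mean(per[, "spe"]), f_measure = 100 * f,
       per_class = 100 * per)
}

# rank-based AUC (equals Mann-Whitney U / (n1 * n0)); ties get midranks
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest and micro-averaged ROC AUC
#'
#' Per-class AUC via the rank (Mann-Whitney) rule on the class's score
#' column; the micro average pools all (score, binary label) pairs across
#' classes into a single curve. Classes absent from the truth are excluded
#' with a warning. Values are percentages.
#'
#' @param scores numeric matrix, one column per class (named by class).
#' @param truth true class labels.
#' @return named numeric vector: `auc_<class>` per class plus `auc_micro`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  cls <- colnames(scores)
  out <- numeric(0)
  pooled_s <- numeric(0); pooled_l <- logical(0)
  for (cl in cls) {
    pos <- truth == cl
    if (!any(pos)) {
      warning("class ", cl, " absent from truth; AUC undefined")
      next
    }
    out[paste0("auc_", cl)] <- 100 * auc_rank(scores[, cl], pos)
    pooled_s <- c(pooled_s, scores[, cl]); pooled_l <- c(pooled_l, pos)
  }
  out["auc_micro"] <- 100 * auc_rank(pooled_s, pooled_l)
  out
}

#' Kendall's tau-b with tie correction
#'
#' Rank correlation between feature values and ordinal grades, with the
#' standard tie corrections in the denominator and a two-sided p-value
#' from the tie-corrected normal approximation of the S statistic.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list `(tau, p_value)`.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("tau-b undefined: all values tied in one input")
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  S <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected variance of S
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (var_s > 0) S / sqrt(var_s) else 0
  list(tau = tau, p_value = 2 * stats::pnorm(-abs(z)))
}
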