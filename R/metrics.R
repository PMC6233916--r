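#' Penalised logistic regression on individual components
#'
#' Class-weighted L1-penalised logistic regression of the outcome on the
#' individual (log1-transformed) component values, with the penalty
#' selected by stratified inner cross-validated deviance — the same
#' selection rule as the JDINAC regression stage, so the two models
#' differ only in their features.
#'
#' @param x numeric matrix (participants x components), log1-transformed.
#' @param y binary outcome (0/1), both classes present.
#' @param penalty "1se" (default) or "min".
#' @param nfolds_inner inner CV folds, default 5.
#' @param class_weights inverse-class-frequency weights, default TRUE.
#' @return object of class `penalised_lr`: `a0`, `beta` (named), `lambda`.
#' @export
penalised_lr_fit <- function(x, y, penalty = c("1se", "min"),
                             nfolds_inner = 5, class_weights = TRUE) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (all(apply(x, 2, stats::sd) == 0)) stop("degenerate design: all components constant")
  w <- if (class_weights) inverse_class_weights(y) else rep(1, length(y))
  cvfit <- cv_l1_logistic(x, y, weights = w, nfolds = nfolds_inner,
                          penalty = penalty)
  structure(list(a0 = cvfit$a0,
                 beta = stats::setNames(cvfit$beta, colnames(x)),
                 lambda = cvfit$lambda),
            class = "penalised_lr")
}

#' @export
predict.penalised_lr <- function(object, newx, ...) {
  stats::plogis(object$a0 + drop(as.matrix(newx) %*% object$beta))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that
#' a random case outscores a random control (ties count one half).
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param prob scores (higher = more case-like).
#' @param y binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(prob, y) {
  y <- as.integer(y)
  stopifnot(length(prob) == length(y), all(y %in% 0:1))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes needed for AUC")
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs over all score thresholds, from (0, 0) to (1, 1),
#' monotone in both coordinates. Trapezoid integration of these points
#' equals [auc_rank()].
#'
#' @param prob scores; @param y binary labels.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(prob, y) {
  y <- as.integer(y)
  ord <- order(prob, decreasing = TRUE)
  ys <- y[ord]
  ps <- prob[ord]
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  last <- !duplicated(ps, fromLast = TRUE)   # one point per distinct threshold
  data.frame(fpr = c(0, fp[last] / max(sum(y == 0), 1)),
             tpr = c(0, tp[last] / max(sum(y == 1), 1)))
}

#' Trapezoid area under ROC points
#'
#' @param roc data.frame from [roc_points()].
#' @return area in `[0, 1]`.
#' @export
roc_trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Classification metrics from a confusion table
#'
#' Sensitivity, specificity, precision, accuracy and F1 from
#' true/false positive/negative counts. Precision with zero predicted
#' positives is defined as 0 (with a warning).
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return named list of metrics.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (tp + fp == 0) {
    warning("no predicted positives; precision set to 0")
    prec <- 0
  } else {
    prec <- tp / (tp + fp)
  }
  acc <- (tp + tn) / (tp + fn + tn + fp)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = acc, f1 = f1)
}

#' Model specification for the evaluation harness
#'
#' A model spec bundles a `fit(x, y)` closure and a
#' `predict(model, newx)` closure under a label, so the repeated-CV
#' harness can evaluate any classifier.
#'
#' @param fit function(x, y) -> model.
#' @param predict function(model, newx) -> probabilities.
#' @param label model name used in reports.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(fit, predict, label) {
  structure(list(fit = fit, predict = predict, label = label),
            class = "model_spec")
}

#' Built-in model spec: penalised logistic regression
#' @param ... passed to [penalised_lr_fit()].
#' @return a [model_spec()].
#' @export
penalised_lr_spec <- function(...) {
  model_spec(fit = function(x, y) penalised_lr_fit(x, y, ...),
             predict = function(model, newx) predict(model, newx),
             label = "penalised_lr")
}

#' Built-in model spec: JDINAC under outer cross-validation
#'
#' Wraps [jdinac_fit()] so the repeated-CV harness can measure genuinely
#' out-of-sample performance: the split-swap machinery runs inside each
#' training fold and held-out folds are scored with
#' [predict.jdinac_fit()]. This is the evaluation driver; the native
#' split-swap averaged probabilities remain the fitting-time diagnostic
#' and the source of the differential network.
#'
#' @param T split-swap repetitions inside each training fold (a smaller
#'   count than a standalone fit is usual here — prediction averaging over
#'   `2T` models stabilises quickly and the outer folds multiply cost).
#' @param seed seed for the inner splitting (the outer harness already
#'   controls fold randomness).
#' @param ... passed to [jdinac_fit()].
#' @return a [model_spec()].
#' @export
jdinac_spec <- function(T = 10, seed = 1L, ...) {
  model_spec(fit = function(x, y) jdinac_fit(x, y, T = T, seed = seed, ...),
             predict = function(model, newx) predict(model, newx),
             label = "jdinac")
}

#' Repeated stratified cross-validated evaluation
#'
#' Stratified K-fold cross-validation repeated with fresh shuffles;
#' per-participant out-of-fold probabilities are averaged over the
#' repetitions, and all metrics (threshold 0.5 by default) and the
#' rank-statistic AUC are computed from the averaged probabilities.
#'
#' @param spec a [model_spec()].
#' @param x feature matrix; @param y binary outcome.
#' @param folds number of folds, default 10; @param repetitions default 50.
#' @param threshold classification threshold on the averaged
#'   probabilities, default 0.5.
#' @param seed master seed; per-repetition shuffles derive from it.
#' @return list of class `performance_report`: metrics, `auc`, `roc`
#'   (curve points), `prob` (averaged), `confusion`, `protocol`.
#' @export
repeated_cv_evaluate <- function(spec, x, y, folds = 10, repetitions = 50,
                                 threshold = 0.5, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), folds >= 2, nrow(x) >= folds)
  y <- as.integer(y)
  n <- nrow(x)
  prob_sum <- numeric(n)
  for (r in seq_len(repetitions)) {
    set.seed(sub_seed(seed, r))
    foldid <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      test <- foldid == f
      model <- spec$fit(x[!test, , drop = FALSE], y[!test])
      prob_sum[test] <- prob_sum[test] + spec$predict(model, x[test, , drop = FALSE])
    }
  }
  prob <- prob_sum / repetitions
  performance_report(prob, y, threshold = threshold,
                     protocol = list(model = spec$label, folds = folds,
                                     repetitions = repetitions, seed = seed,
                                     mode = "averaged-probability thresholding"))
}

#' Performance report from probabilities
#'
#' @param prob probabilities; @param y labels; @param threshold cut,
#'   default 0.5; @param protocol descriptor list stored in the report.
#' @return `performance_report` list.
#' @export
performance_report <- function(prob, y, threshold = 0.5, protocol = list()) {
  y <- as.integer(y)
  pred <- as.integer(prob > threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  mets <- confusion_metrics(tp, fn, tn, fp)
  roc <- roc_points(prob, y)
  structure(c(mets, list(
    auc = auc_rank(prob, y), roc = roc, prob = prob,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    threshold = threshold, protocol = protocol
  )), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f | acc %.3f | sens %.3f | spec %.3f | prec %.3f | F1 %.3f\n",
              if (is.null(x$protocol$model)) "model" else x$protocol$model,
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Side-by-side comparison of two performance reports
#'
#' @param report_a,report_b `performance_report`s produced under the same
#'   protocol (folds/repetitions must match; model labels may differ).
#' @return data.frame with one row per metric: values and delta (b - a).
#' @export
compare_models <- function(report_a, report_b) {
  pa <- report_a$protocol; pb <- report_b$protocol
  if (!identical(pa[c("folds", "repetitions")], pb[c("folds", "repetitions")])) {
    stop("protocol mismatch: reports come from different CV protocols")
  }
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "precision", "f1")
  a <- vapply(metrics, function(mm) report_a[[mm]], numeric(1))
  b <- vapply(metrics, function(mm) report_b[[mm]], numeric(1))
  data.frame(metric = metrics,
             a = unname(a), b = unname(b), delta = unname(b - a),
             row.names = NULL)
}
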