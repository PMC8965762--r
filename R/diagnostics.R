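# Discriminative-feature screen (ROC AUC + log fold change) and the repeated
# equal-sampling LASSO logistic-regression diagnostic harness.

#' Rank-based ROC AUC of one feature
#'
#' `AUC = P(case value > control value) + 0.5 * P(tie)`, computed from the
#' rank-sum statistic with midrank tie handling — identical to exhaustive
#' pairwise win/tie counting.
#'
#' @param values_case,values_control numeric vectors.
#' @return AUC in \[0, 1\] (0.5 = no discrimination, > 0.5 = higher in
#'   cases).
#' @examples
#' feature_auc(c(3, 1), c(2, 0)) # 0.75
#' @export
feature_auc <- function(values_case, values_control) {
  n1 <- length(values_case)
  n0 <- length(values_control)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  r <- rank(c(values_case, values_control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Log fold change with pseudocount
#'
#' `ln((mean_case + eps) / (mean_control + eps))`; the pseudocount keeps
#' the statistic finite for features absent in one group and is set on the
#' relative-abundance scale.
#'
#' @param mean_case,mean_control group means (>= 0).
#' @param pseudocount additive epsilon (default 1e-4).
#' @return natural-log fold change (positive = higher in cases).
#' @export
log_fold_change <- function(mean_case, mean_control, pseudocount = 1e-4) {
  stopifnot(mean_case >= 0, mean_control >= 0, pseudocount > 0)
  log((mean_case + pseudocount) / (mean_control + pseudocount))
}

#' ROC marker screen over a usage matrix
#'
#' Per feature, the ROC AUC and log fold change between the two label
#' classes; features with `|lfc| >= lfc_min` and
#' `max(auc, 1 - auc) > auc_min` are retained as discriminative markers,
#' with direction taken from the sign of the fold change. Results are
#' sorted by discriminative power (`max(auc, 1 - auc)`) descending.
#'
#' @param matrix a [usage_matrix()].
#' @param labels per-row class label; `positive` names the case class.
#' @param positive label treated as the case class (default `"case"`).
#' @param lfc_min minimum absolute log fold change (default 0.25).
#' @param auc_min minimum one-sided AUC (default 0.7, strict `>`).
#' @param pseudocount passed to [log_fold_change()].
#' @return data.frame with feature, auc, lfc, direction for retained
#'   markers; all per-feature statistics in `attr(., "all_features")`.
#' @export
roc_marker_test <- function(matrix, labels, positive = "case",
                            lfc_min = 0.25, auc_min = 0.7,
                            pseudocount = 1e-4) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(matrix))
  classes <- unique(labels)
  if (length(classes) != 2) stop("labels must have exactly 2 classes")
  if (!positive %in% classes) stop("positive class '", positive,
                                   "' absent from labels")
  case <- labels == positive
  if (sum(case) < 2 || sum(!case) < 2) {
    stop("each class needs at least 2 samples")
  }
  auc <- apply(matrix, 2, function(v) feature_auc(v[case], v[!case]))
  lfc <- apply(matrix, 2, function(v) {
    log_fold_change(mean(v[case]), mean(v[!case]), pseudocount)
  })
  all_feat <- data.frame(feature = colnames(matrix), auc = unname(auc),
                         lfc = unname(lfc), stringsAsFactors = FALSE)
  power <- pmax(all_feat$auc, 1 - all_feat$auc)
  keep <- abs(all_feat$lfc) >= lfc_min & power > auc_min
  out <- all_feat[keep, , drop = FALSE]
  out$direction <- ifelse(out$lfc > 0, "up_in_case", "up_in_control")
  out <- out[order(-pmax(out$auc, 1 - out$auc)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_features") <- all_feat
  out
}

#' Equal-sampling train/test split
#'
#' Training cases are `ceil(train_fraction * n_case)` randomly drawn cases;
#' an equal number of controls is drawn without replacement so the training
#' set is balanced. Everything else — the remaining cases and all remaining
#' controls — forms the (typically imbalanced) test set. Set sizes depend
#' only on the cohort sizes and `train_fraction`, never on the seed.
#'
#' @param case_ids,control_ids sample id vectors.
#' @param train_fraction fraction of cases used for training (default 0.8).
#' @param seed integer seed for the draw.
#' @return list of class `split_plan`: `train_case`, `train_control`,
#'   `test_case`, `test_control`, `seed`.
#' @export
split_cohorts <- function(case_ids, control_ids, train_fraction = 0.8,
                          seed = 1) {
  n_case <- length(case_ids)
  if (n_case < 2) stop("need at least 2 cases")
  n_train <- as.integer(ceiling(train_fraction * n_case))
  if (n_train >= n_case) n_train <- n_case - 1L
  if (length(control_ids) < n_train) {
    stop("need at least ", n_train, " controls, got ", length(control_ids))
  }
  set.seed(seed)
  train_case <- sample(case_ids, n_train)
  train_control <- sample(control_ids, n_train)
  structure(list(
    train_case = train_case,
    train_control = train_control,
    test_case = setdiff(case_ids, train_case),
    test_control = setdiff(control_ids, train_control),
    seed = seed
  ), class = "split_plan")
}

#' Fit an L1-penalized logistic model with cross-validated lambda
#'
#' `cv.glmnet` with binomial deviance loss over its default descending
#' lambda path; features are standardized internally. Folds are stratified
#' by class so no fold is single-class. The model is reported at
#' `lambda.min` (minimum mean cross-validated deviance).
#'
#' @param x training feature matrix (samples x features).
#' @param y binary response (1 = case).
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return list of class `lasso_model`: `lambda_min`, `intercept`,
#'   `coefficients` (named vector of the nonzero ones), `n_folds`, `cvfit`.
#' @export
fit_lasso_cv <- function(x, y, n_folds = 10, seed = 1) {
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("training set must contain both classes")
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    foldid[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial",
                             type.measure = "deviance", foldid = foldid,
                             standardize = TRUE)
  beta <- stats::coef(cvfit, s = "lambda.min")
  b <- as.numeric(beta)
  names(b) <- rownames(beta)
  nz <- b[-1][b[-1] != 0]
  structure(list(lambda_min = cvfit$lambda.min, intercept = b[[1]],
                 coefficients = nz, n_folds = n_folds, cvfit = cvfit),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf("lasso_model: lambda.min = %.4g, %d nonzero coefficient(s)\n",
              x$lambda_min, length(x$coefficients)))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' Predicted class probabilities at `lambda.min`; AUC by the rank method
#' ([feature_auc()] on the scores) and threshold metrics at `threshold`.
#' With a single-class test set the AUC is NA but threshold metrics are
#' still reported.
#'
#' @param model a `lasso_model`.
#' @param x_test test feature matrix.
#' @param y_test binary response (1 = case).
#' @param threshold probability cut for calling a case (default 0.5).
#' @return list with `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `confusion` (TP/FP/TN/FN), `scores`.
#' @export
evaluate_model <- function(model, x_test, y_test, threshold = 0.5) {
  p <- as.numeric(stats::predict(model$cvfit, newx = x_test,
                                 s = "lambda.min", type = "response"))
  classification_metrics(p, y_test, threshold)
}

#' Threshold and ranking metrics of prediction scores
#'
#' @param scores predicted case probabilities (or any monotone score).
#' @param y_true binary truth (1 = case).
#' @param threshold score cut for calling a case.
#' @return list with `auc` (rank-based; NA on a single-class truth),
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `confusion`
#'   (TP/FP/TN/FN) and `scores`.
#' @export
classification_metrics <- function(scores, y_true, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(scores) == length(y_true))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  tn <- sum(pred == 0 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  auc <- if (length(unique(y_true)) == 2)
    feature_auc(scores[y_true == 1], scores[y_true == 0]) else NA_real_
  list(
    auc = auc,
    accuracy = (tp + tn) / length(y_true),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    scores = scores
  )
}

#' Repeated equal-sampling LASSO evaluation
#'
#' The full diagnostic harness: for each repeat, a fresh balanced
#' train/test split ([split_cohorts()], seed `base_seed + r`), a
#' cross-validated LASSO fit on the training set, and evaluation on the
#' held-out (imbalanced) test set. Reports per-repeat metrics, their
#' mean and sd, and how often each feature was selected (nonzero
#' coefficient) across repeats. A failing repeat is recorded and excluded
#' from aggregates.
#'
#' @param matrix a [usage_matrix()] over both cohorts.
#' @param labels per-row cohort label; `positive` marks cases.
#' @param positive case label (default `"case"`).
#' @param n_repeats number of repeats (default 100).
#' @param train_fraction passed to [split_cohorts()].
#' @param n_folds passed to [fit_lasso_cv()].
#' @param threshold passed to [evaluate_model()].
#' @param base_seed repeat `r` uses seed `base_seed + r`.
#' @return list of class `classifier_report`: `repeats` (per-repeat metric
#'   data.frame incl. seed and model size), `aggregate` (mean/sd per
#'   metric), `feature_frequency` (selection fraction per feature, selected
#'   features only), `failures`, `seeds`.
#' @export
repeated_evaluation <- function(matrix, labels, positive = "case",
                                n_repeats = 100, train_fraction = 0.8,
                                n_folds = 10, threshold = 0.5,
                                base_seed = 0) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(matrix))
  case_ids <- rownames(matrix)[labels == positive]
  control_ids <- rownames(matrix)[labels != positive]
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "precision")
  reps <- list()
  failures <- list()
  sel_count <- stats::setNames(numeric(ncol(matrix)), colnames(matrix))
  seeds <- base_seed + seq_len(n_repeats)
  for (r in seq_len(n_repeats)) {
    res <- tryCatch({
      plan <- split_cohorts(case_ids, control_ids, train_fraction,
                            seed = seeds[r])
      tr <- c(plan$train_case, plan$train_control)
      te <- c(plan$test_case, plan$test_control)
      y_tr <- as.integer(tr %in% case_ids)
      y_te <- as.integer(te %in% case_ids)
      fit <- fit_lasso_cv(matrix[tr, , drop = FALSE], y_tr,
                          n_folds = n_folds, seed = seeds[r])
      ev <- evaluate_model(fit, matrix[te, , drop = FALSE], y_te,
                           threshold = threshold)
      list(fit = fit, ev = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(repeat_index = r, seed = seeds[r],
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    sel <- names(res$fit$coefficients)
    sel_count[sel] <- sel_count[sel] + 1
    reps[[length(reps) + 1]] <- data.frame(
      repeat_index = r, seed = seeds[r],
      n_selected = length(sel), lambda_min = res$fit$lambda_min,
      auc = res$ev$auc, accuracy = res$ev$accuracy,
      sensitivity = res$ev$sensitivity, specificity = res$ev$specificity,
      precision = res$ev$precision, stringsAsFactors = FALSE)
  }
  reps <- if (length(reps)) do.call(rbind, reps) else NULL
  n_ok <- if (is.null(reps)) 0L else nrow(reps)
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m)
      if (n_ok) mean(reps[[m]], na.rm = TRUE) else NA_real_, numeric(1)),
    sd = vapply(metrics, function(m)
      if (n_ok >= 2) stats::sd(reps[[m]], na.rm = TRUE) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  freq <- sel_count[sel_count > 0] / max(n_ok, 1L)
  structure(list(
    repeats = reps, aggregate = aggregate,
    feature_frequency = sort(freq, decreasing = TRUE),
    failures = if (length(failures)) do.call(rbind, failures) else NULL,
    seeds = seeds, n_completed = n_ok
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: %d/%d repeats completed\n",
              x$n_completed, length(x$seeds)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.4f +/- %s\n", agg$metric[i], agg$mean[i],
                ifelse(is.na(agg$sd[i]), "NA", sprintf("%.4f", agg$sd[i]))))
  }
  invisible(x)
}
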