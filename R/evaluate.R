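#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, producing one
#' (FPR, TPR) point per distinct score plus the (0,0) and (1,1) ends, and
#' integrates the curve with the trapezoidal rule. With tied scores
#' grouped, the trapezoidal AUC equals the Mann-Whitney statistic with
#' half credit for ties:
#' `AUC = [ sum I(s+ > s-) + 0.5 * sum I(s+ = s-) ] / (n+ n-)`.
#'
#' @param truth logical or `"pain"`/`"no_pain"` vector; `TRUE`/`"pain"`
#'   is the positive class.
#' @param score numeric pain scores (higher = more pain-like).
#' @return list with `roc` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(truth, score) {
  y <- as_truth(truth)
  if (!any(y) || all(y)) stop_meshpain("both classes needed for a ROC curve")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- y[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  n_pos <- sum(y); n_neg <- sum(!y)
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- trapz(roc$fpr, roc$tpr)
  list(roc = roc, auc = auc)
}

as_truth <- function(truth) {
  if (is.logical(truth)) return(truth)
  truth == "pain"
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples the pooled predictions with replacement within each truth
#' class (so every replicate keeps the observed class balance), computes
#' the AUC of each replicate, and reports the percentile 95% interval.
#' Deterministic given the seed.
#'
#' @inheritParams roc_auc
#' @param replicates number of bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return list with `lo`, `hi`, `replicates`, and the replicate AUCs.
#' @export
bootstrap_auc_ci <- function(truth, score, replicates = 2000L, seed = 1L,
                             level = 0.95) {
  y <- as_truth(truth)
  pos <- which(y); neg <- which(!y)
  set.seed(seed)
  aucs <- vapply(seq_len(replicates), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    roc_auc(y[idx], score[idx])$auc
  }, numeric(1))
  qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lo = qs[1L], hi = qs[2L], replicates = replicates, aucs = aucs)
}

#' Choose an operating point on the pooled predictions
#'
#' The published deployment picks its decision threshold "to preference";
#' that is not an algorithm, so three explicit policies are offered:
#' `"youden"` (default) maximises Youden's J = sensitivity +
#' specificity - 1; `"fixed"` applies a caller-supplied threshold;
#' `"sens_floor"` maximises specificity subject to sensitivity >=
#' `min_sensitivity`. A window is called pain when `score >= threshold`.
#'
#' @inheritParams roc_auc
#' @param policy `"youden"`, `"fixed"` or `"sens_floor"`.
#' @param threshold threshold for `policy = "fixed"`.
#' @param min_sensitivity floor for `policy = "sens_floor"`.
#' @return list with `threshold`, `sensitivity`, `specificity`, and
#'   `confusion` — the 2 x 2 confusion matrix normalised per true class
#'   (rows `no_pain`/`pain` each sum to 1).
#' @export
operating_point <- function(truth, score,
                            policy = c("youden", "fixed", "sens_floor"),
                            threshold = 0.5, min_sensitivity = 0.8) {
  policy <- match.arg(policy)
  y <- as_truth(truth)
  cand <- sort(unique(score))
  metrics <- function(th) {
    pred <- score >= th
    c(sens = if (any(y)) mean(pred[y]) else NA_real_,
      spec = if (any(!y)) mean(!pred[!y]) else NA_real_)
  }
  th <- switch(policy,
    fixed = threshold,
    youden = {
      j <- vapply(cand, function(th) sum(metrics(th)) - 1, numeric(1))
      # on ties prefer the higher threshold (more specific call)
      cand[max(which(j == max(j)))]
    },
    sens_floor = {
      m <- vapply(cand, metrics, numeric(2))
      ok <- which(m["sens", ] >= min_sensitivity)
      if (!length(ok)) stop_meshpain("no threshold reaches sensitivity ",
                                     min_sensitivity)
      cand[ok[which.max(m["spec", ok])]]
    })
  m <- metrics(th)
  confusion <- rbind(no_pain = c(m[["spec"]], 1 - m[["spec"]]),
                     pain = c(1 - m[["sens"]], m[["sens"]]))
  colnames(confusion) <- c("pred_no_pain", "pred_pain")
  list(threshold = th, sensitivity = m[["sens"]], specificity = m[["spec"]],
       confusion = confusion)
}

#' Leave-one-subject-out cross-validated predictions
#'
#' For each subject in turn, a classifier is trained on all *other*
#' subjects' windows — balanced by [undersample()] with a fold-derived
#' seed, standardisation fitted on that balanced training fold only —
#' and that subject's windows are scored. Pooled over folds, every
#' retained window is scored exactly once by a model that never saw its
#' subject; the no-leakage property is asserted structurally on every
#' run.
#'
#' @param dataset a `pain_dataset` with at least two subjects and both
#'   classes.
#' @param config a [knn_config()].
#' @param features feature columns (default: the dataset's selection).
#' @return data.frame `subject_id, t_center, truth, score, fold`, one row
#'   per window of `dataset`.
#' @export
loso_cv <- function(dataset, config = knn_config(),
                    features = dataset_feature_columns(dataset)) {
  subjects <- sort(unique(dataset$subject_id))
  if (length(subjects) < 2L) stop_meshpain("LOSO needs at least 2 subjects")
  preds <- vector("list", length(subjects))
  for (f in seq_along(subjects)) {
    held <- subjects[f]
    train <- dataset[dataset$subject_id != held, , drop = FALSE]
    test <- dataset[dataset$subject_id == held, , drop = FALSE]
    if (held %in% train$subject_id) {
      stop_meshpain("leakage detected: held-out subject present in training fold")
    }
    bal <- undersample(train, seed = derive_seed(config$seed, f))
    k_eff <- min(config$k, nrow(bal))
    cfg <- config; cfg$k <- k_eff
    fit <- pain_knn(bal, features = features, config = cfg)
    preds[[f]] <- data.frame(subject_id = test$subject_id,
                             t_center = test$t_center,
                             truth = test$label,
                             score = predict(fit, test),
                             fold = f)
  }
  out <- do.call(rbind, preds)
  if (nrow(out) != nrow(dataset)) {
    stop_meshpain("pooled predictions must cover every window exactly once")
  }
  rownames(out) <- NULL
  out
}

#' Default hyperparameter grid
#'
#' Odd k from 1 to 21, both neighbour weightings, both metrics — a large
#' but desk-scale combination set.
#'
#' @return data.frame with columns `k`, `weighting`, `metric`.
#' @export
default_grid <- function() {
  expand.grid(k = seq(1L, 21L, by = 2L),
              weighting = c("uniform", "distance"),
              metric = c("euclidean", "manhattan"),
              stringsAsFactors = FALSE)
}

# F1 of the pain class at a fixed threshold.
f1_score <- function(truth, score, threshold = 0.5) {
  y <- as_truth(truth)
  pred <- score >= threshold
  tp <- sum(pred & y)
  if (tp == 0L) return(0)
  2 * tp / (2 * tp + sum(pred & !y) + sum(!pred & y))
}

#' Tune KNN hyperparameters by LOSO F1
#'
#' Evaluates every grid candidate with a full leave-one-subject-out pass
#' and scores it by the F1 of the pain class on the pooled predictions at
#' threshold 0.5. Ties are broken toward smaller k, then by grid row
#' order (weighting before metric). The per-fold undersampling seeds
#' derive only from `seed` and the fold index, so all candidates see
#' identical training subsets.
#'
#' @param dataset a `pain_dataset`.
#' @param grid candidate data.frame as from [default_grid()].
#' @param seed base seed.
#' @param standardize passed through to each candidate config.
#' @return list with `config` (the winning [knn_config()]), `f1`, and the
#'   full `results` table (grid + f1 column).
#' @export
tune_hyperparameters <- function(dataset, grid = default_grid(), seed = 1L,
                                 standardize = TRUE) {
  if (nrow(grid) == 0L) stop_meshpain("empty hyperparameter grid")
  f1 <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- knn_config(k = grid$k[i], weighting = grid$weighting[i],
                      metric = grid$metric[i], standardize = standardize,
                      seed = seed)
    p <- loso_cv(dataset, cfg)
    f1_score(p$truth, p$score, 0.5)
  }, numeric(1))
  results <- cbind(grid, f1 = f1)
  best <- order(-f1, grid$k, seq_len(nrow(grid)))[1L]
  list(config = knn_config(k = grid$k[best], weighting = grid$weighting[best],
                           metric = grid$metric[best],
                           standardize = standardize, seed = seed),
       f1 = f1[best], results = results)
}

#' Evaluate the pain classifier under the full published protocol
#'
#' Runs (optionally) hyperparameter tuning, the leave-one-subject-out
#' pass, the pooled ROC/AUC, the stratified bootstrap confidence
#' interval, and the operating-point selection, and returns everything
#' as one `pain_eval` object with `print`, `summary` and `plot` methods.
#'
#' @param dataset a `pain_dataset` (typically after [select_features()]).
#' @param config a [knn_config()]; ignored when `tune = TRUE`.
#' @param tune if `TRUE`, select the config by [tune_hyperparameters()]
#'   over `grid` first.
#' @param grid hyperparameter grid used when tuning.
#' @param replicates bootstrap replicate count (default 2000).
#' @param policy,threshold,min_sensitivity operating-point policy, see
#'   [operating_point()].
#' @param seed base seed for undersampling and the bootstrap.
#' @return an object of class `pain_eval`.
#' @export
loso_evaluate <- function(dataset, config = knn_config(), tune = FALSE,
                          grid = default_grid(), replicates = 2000L,
                          policy = "youden", threshold = 0.5,
                          min_sensitivity = 0.8, seed = 1L) {
  tuning <- NULL
  if (isTRUE(tune)) {
    tuning <- tune_hyperparameters(dataset, grid, seed = seed)
    config <- tuning$config
  } else {
    config$seed <- as.integer(seed)
  }
  preds <- loso_cv(dataset, config)
  ra <- roc_auc(preds$truth, preds$score)
  ci <- bootstrap_auc_ci(preds$truth, preds$score, replicates = replicates,
                         seed = derive_seed(seed, 999L))
  op <- operating_point(preds$truth, preds$score, policy = policy,
                        threshold = threshold,
                        min_sensitivity = min_sensitivity)
  structure(list(predictions = preds, roc = ra$roc, auc = ra$auc,
                 auc_ci = c(lo = ci$lo, hi = ci$hi),
                 replicates = ci$replicates,
                 operating_point = op, config = config, tuning = tuning,
                 n_windows = nrow(preds),
                 n_subjects = length(unique(preds$subject_id))),
            class = "pain_eval")
}

#' @export
print.pain_eval <- function(x, ...) {
  cat("Leave-one-subject-out evaluation of the KNN pain classifier\n")
  cat(sprintf("  %d windows, %d subjects, %d pain / %d no-pain\n",
              x$n_windows, x$n_subjects,
              sum(x$predictions$truth == "pain"),
              sum(x$predictions$truth == "no_pain")))
  cat(sprintf("  config: k=%d, %s weights, %s metric%s\n", x$config$k,
              x$config$weighting, x$config$metric,
              if (x$config$standardize) ", standardized" else ""))
  cat(sprintf("  AUC %.3f  (95%% CI %.3f-%.3f, %d stratified bootstrap replicates)\n",
              x$auc, x$auc_ci[["lo"]], x$auc_ci[["hi"]], x$replicates))
  op <- x$operating_point
  cat(sprintf("  operating point: threshold %.3f, sensitivity %.3f, specificity %.3f\n",
              op$threshold, op$sensitivity, op$specificity))
  invisible(x)
}

#' @export
summary.pain_eval <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix (rows = truth, normalised per class):\n")
  print(round(object$operating_point$confusion, 3))
  if (!is.null(object$tuning)) {
    cat(sprintf("\nTuning: best F1 %.3f over %d candidates\n",
                object$tuning$f1, nrow(object$tuning$results)))
  }
  invisible(object)
}

#' @export
plot.pain_eval <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("Pooled LOSO ROC, AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  op <- x$operating_point
  graphics::points(1 - op$specificity, op$sensitivity, pch = 19, col = "red3")
  invisible(x)
}

#' Write pooled predictions and ROC points as CSV
#'
#' @param eval a `pain_eval`.
#' @param predictions_path,roc_path output CSV paths (`NULL` to skip).
#' @return `eval`, invisibly.
#' @export
write_evaluation <- function(eval, predictions_path = NULL, roc_path = NULL) {
  if (!is.null(predictions_path)) {
    utils::write.csv(eval$predictions, predictions_path, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(roc_path)) {
    utils::write.csv(eval$roc, roc_path, row.names = FALSE, quote = FALSE)
  }
  invisible(eval)
}
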