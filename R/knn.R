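#' Balancing undersampling
#'
#' Before each training run, the majority class is randomly subsampled
#' without replacement so both classes contribute equally — pain windows
#' are rare (the study retained 22 pain vs 108 no-pain windows), and an
#' unbalanced KNN vote would be dominated by the majority. All minority
#' examples are kept.
#'
#' @param dataset a `pain_dataset` containing both classes.
#' @param seed integer seed controlling the majority draw; the same seed
#'   always selects the same subset.
#' @return the balanced subset, rows in original order.
#' @export
undersample <- function(dataset, seed = 1L) {
  tab <- table(factor(dataset$label, levels = c("no_pain", "pain")))
  if (any(tab == 0L)) stop_meshpain("both classes must be present to balance")
  n_min <- min(tab)
  minority <- names(tab)[which.min(tab)]
  keep <- which(dataset$label == minority)
  maj <- which(dataset$label != minority)
  set.seed(seed)
  keep <- sort(c(keep, sample(maj, n_min)))
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Model configuration for the KNN pain classifier
#'
#' @param k number of neighbours (positive integer).
#' @param weighting `"uniform"` (each neighbour one vote) or
#'   `"distance"` (votes weighted by 1/distance; exact matches dominate).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param standardize z-score each feature column using training-set mean
#'   and SD before distances are computed. On by default: the descriptor
#'   columns are meter-scale quantities of very different magnitudes, and
#'   unscaled distances would be dominated by the largest.
#' @param decision_threshold score threshold for the pain call, in
#'   `[0, 1]`.
#' @param seed base seed for the stochastic steps (undersampling,
#'   bootstrap).
#' @return a list of class `knn_config`.
#' @export
knn_config <- function(k = 5L, weighting = c("uniform", "distance"),
                       metric = c("euclidean", "manhattan"),
                       standardize = TRUE, decision_threshold = 0.5,
                       seed = 1L) {
  weighting <- match.arg(weighting)
  metric <- match.arg(metric)
  stopifnot(k >= 1L, decision_threshold >= 0, decision_threshold <= 1)
  structure(list(k = as.integer(k), weighting = weighting, metric = metric,
                 standardize = isTRUE(standardize),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "knn_config")
}

#' Fit the KNN pain classifier
#'
#' "Fitting" a KNN model stores the (optionally standardised) training
#' feature matrix and labels plus the configuration; prediction scores a
#' query as the (optionally distance-weighted) fraction of its k nearest
#' training windows that are pain windows.
#'
#' @param dataset a `pain_dataset` training set (typically balanced via
#'   [undersample()]).
#' @param features feature columns to use; defaults to the dataset's
#'   recorded selection (see [select_features()]).
#' @param config a [knn_config()].
#' @return an object of class `pain_knn` with `predict`, `print` and
#'   `coef`-style accessors.
#' @examples
#' d <- data.frame(subject_id = c("a", "a", "b", "b"), t_center = 1:4,
#'                 label = c("pain", "no_pain", "pain", "no_pain"),
#'                 facial_score = c(2L, 1L, 3L, 1L), coverage_s = 600,
#'                 AU4s1_area_around_mean = c(1, 0, 1.1, 0.1),
#'                 AU4s2_area_around_mean = c(1, 0, 0.9, -0.1))
#' class(d) <- c("pain_dataset", "data.frame")
#' fit <- pain_knn(d, config = knn_config(k = 1))
#' predict(fit, d[1, ])
#' @export
pain_knn <- function(dataset, features = dataset_feature_columns(dataset),
                     config = knn_config()) {
  if (nrow(dataset) == 0L) stop_meshpain("empty training set")
  if (config$k > nrow(dataset)) {
    stop_meshpain("k (", config$k, ") exceeds training size (", nrow(dataset), ")")
  }
  x <- as.matrix(dataset[features])
  storage.mode(x) <- "double"
  center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (config$standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1   # constant columns left unscaled
    x <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  }
  structure(list(x = x, y = dataset$label == "pain",
                 features = features, center = center, scale = scl,
                 config = config),
            class = "pain_knn")
}

#' @describeIn pain_knn score new windows; returns the pain score in
#'   `[0, 1]` for each row of `newdata`.
#' @param object a fitted `pain_knn`.
#' @param newdata a data.frame containing the model's feature columns.
#' @param ... unused.
#' @export
predict.pain_knn <- function(object, newdata, ...) {
  q <- as.matrix(newdata[object$features])
  storage.mode(q) <- "double"
  q <- sweep(sweep(q, 2L, object$center), 2L, object$scale, "/")
  vapply(seq_len(nrow(q)), function(i) {
    knn_score_one(object$x, object$y, q[i, ], object$config)
  }, numeric(1))
}

# Score one standardized query point: fraction (possibly 1/d-weighted)
# of the k nearest training rows that are pain. Neighbour ties in
# distance are broken by training-row order (stable).
knn_score_one <- function(x, y, q, config) {
  d <- if (config$metric == "euclidean") {
    sqrt(colSums((t(x) - q)^2))
  } else {
    colSums(abs(t(x) - q))
  }
  nn <- order(d)[seq_len(config$k)]
  if (config$weighting == "uniform") {
    return(mean(y[nn]))
  }
  dn <- d[nn]
  if (any(dn == 0)) return(mean(y[nn[dn == 0]]))  # exact matches dominate
  w <- 1 / dn
  sum(w * y[nn]) / sum(w)
}

#' @export
print.pain_knn <- function(x, ...) {
  cat(sprintf("<pain_knn> k=%d, %s weights, %s metric, %d training windows (%d pain)\n",
              x$config$k, x$config$weighting, x$config$metric,
              length(x$y), sum(x$y)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
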