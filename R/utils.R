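# Shared plumbing: stratified folds, generic train-data subsetting, and
# base-classifier factories used by the decision tree and cross-validation.

# Training data may be a list of SPD matrices (covariance classifiers) or a
# numeric matrix with one row per trial (feature-space classifiers).
.data_n <- function(data) if (is.list(data)) length(data) else nrow(data)

.data_subset <- function(data, idx) {
  if (is.list(data)) data[idx] else data[idx, , drop = FALSE]
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `folds` cross-validation folds, separately
#' within each class so fold class proportions match the data. If the
#' smallest class has fewer trials than `folds`, the fold count is reduced
#' with a warning.
#'
#' @param labels Class labels.
#' @param folds Requested fold count (`>= 2`).
#' @param seed Integer seed fixing the assignment.
#' @return Integer vector of fold ids in `1:folds` (attribute `"folds"`
#'   holds the effective count).
#' @export
stratified_folds <- function(labels, folds = 10L, seed = 1L) {
  labels <- as.factor(labels)
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  if (folds >= length(labels)) {      # leave-one-out: each trial its own fold
    return(structure(seq_along(labels), folds = length(labels)))
  }
  smallest <- min(table(labels))
  if (smallest < folds) {
    folds <- max(2L, as.integer(smallest))
    warning(sprintf("fold count reduced to %d (smallest class has %d trials)",
                    folds, smallest))
  }
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  structure(assign, folds = folds)
}

# Cross-validated accuracy of base_factory on (data, labels) with fixed folds.
.cv_accuracy <- function(data, labels, base_factory, folds, seed) {
  fold_id <- stratified_folds(labels, folds, seed)
  k <- attr(fold_id, "folds")
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold_id != f
    model <- base_factory(.data_subset(data, tr), labels[tr])
    pred <- predict(model, .data_subset(data, !tr))
    correct <- correct + sum(as.character(pred) == as.character(labels[!tr]))
  }
  correct / length(labels)
}

# ---- base-classifier factories -------------------------------------------

#' Base-classifier factories for the decision tree
#'
#' A factory is a function `(data, labels) -> fitted model` with a
#' `predict()` method; the decision tree and the OVR ranking are agnostic to
#' the family behind it. `mdrm_factory()` and `fgmdrm_factory()` expect a
#' list of SPD matrices, `knn_factory()` a feature matrix, and
#' `sjgda_knn_factory()` a tangent-feature matrix on which it fits the
#' SJGDA feature stack followed by KNN.
#'
#' @param config A [mean_config()].
#' @param r FGDA retained directions (`NULL` = `C - 1`).
#' @param k KNN neighbour count.
#' @param sjgda_args List of arguments passed on to [sjgda_fit()] (grid,
#'   kernel parameters, bins, seed, ...).
#' @param unlabelled Optional unlabelled feature matrix fed to the semi-JMI
#'   path of [sjgda_fit()].
#' @return A factory function with attribute `"kind"`.
#' @name base_factories
NULL

#' @rdname base_factories
#' @export
mdrm_factory <- function(config = mean_config()) {
  structure(function(data, labels) mdrm_fit(data, labels, config), kind = "mdrm")
}

#' @rdname base_factories
#' @export
fgmdrm_factory <- function(r = NULL, config = mean_config()) {
  structure(function(data, labels) fgmdrm_fit(data, labels, r = r, config = config),
            kind = "fgmdrm")
}

#' @rdname base_factories
#' @export
knn_factory <- function(k = 5L) {
  structure(function(data, labels) knn_fit(data, labels, k = k), kind = "knn")
}

#' @rdname base_factories
#' @export
sjgda_knn_factory <- function(k = 5L, sjgda_args = list(), unlabelled = NULL) {
  f <- function(data, labels) {
    sj <- do.call(sjgda_fit,
                  c(list(x = data, labels = labels, x_unlabelled = unlabelled),
                    sjgda_args))
    feats <- sjgda_transform(sj, data)
    structure(list(sjgda = sj, knn = knn_fit(feats, labels, k = k)),
              class = "sjgda_knn")
  }
  structure(f, kind = "sjgda_knn")
}

#' @export
predict.sjgda_knn <- function(object, newdata, ...) {
  predict(object$knn, sjgda_transform(object$sjgda, newdata))
}
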