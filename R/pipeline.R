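# End-to-end assemblies: Method 1 (band-pass -> SCM -> SSDT over FGMDRM
# nodes) and Method 2 (band-pass -> SCM -> tangent mapping -> per-node
# SJGDA -> SSDT over KNN nodes), plus stratified cross-validation.

#' Pipeline configuration
#'
#' Bundles every tunable of the two classification methods into one
#' serializable list (see [write_pipeline_config()]).
#'
#' @param method 1 (SSDT-FGMDRM) or 2 (SJGDA + SSDT-KNN).
#' @param tree Use the subject-specific decision tree (`TRUE`, default) or
#'   the flat multiclass base classifier (`FALSE`; the paper's baselines).
#' @param bandpass Apply the Butterworth band-pass before covariance
#'   estimation.
#' @param low,high,filter_order Band-pass parameters (defaults 8-30 Hz,
#'   order 5).
#' @param regularization SCM diagonal loading.
#' @param mean_tolerance,mean_max_iterations Karcher-mean settings.
#' @param folds,seed Node-ranking / internal CV settings.
#' @param final_scope Final-node class set, see [build_ssdt()].
#' @param r FGDA retained directions (method 1; `NULL` = `C - 1`).
#' @param k KNN neighbour count (method 2; default 5).
#' @param feature_scope `"per_node"` (default): the SJGDA stack is refit at
#'   every tree node on that node's own problem; `"global"`: one shared
#'   feature space.
#' @param bins,degree,coef0,kernel_scale,d,ridge,denominator,criterion
#'   SJGDA / GDA parameters, see [sjgda_fit()].
#' @param grid_cap Largest candidate length `m` (default 100, the
#'   22-channel cap; use 60 for 14-channel data).
#' @param grid_step Spacing of the length grid (default 5).
#' @param use_unlabelled Enable the semi-JMI path when unlabelled trials
#'   are supplied.
#' @param select_folds CV folds for length selection (default 10).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(method = 1L, tree = TRUE,
                            bandpass = TRUE, low = 8, high = 30, filter_order = 5L,
                            regularization = 0,
                            mean_tolerance = 1e-8, mean_max_iterations = 100L,
                            folds = 10L, seed = 1L, final_scope = "all",
                            r = NULL, k = 5L,
                            feature_scope = "per_node", bins = 8L,
                            degree = 2, coef0 = 1, kernel_scale = NULL,
                            d = 1L, ridge = 1e-2, denominator = "within",
                            criterion = "jmi", grid_cap = 100L, grid_step = 5L,
                            use_unlabelled = FALSE, select_folds = 10L) {
  stopifnot(method %in% c(1L, 2L))
  structure(as.list(environment()), class = "pipeline_config")
}

# Preprocess a list of epoched trials into SPD covariance matrices.
.trials_to_covs <- function(trials, fs, config) {
  lapply(trials, function(X) {
    if (isTRUE(config$bandpass)) {
      X <- eeg_bandpass(X, fs, config$low, config$high, config$filter_order)
    }
    compute_scm(X, regularization = config$regularization)
  })
}

.mean_cfg <- function(config) {
  mean_config(tolerance = config$mean_tolerance,
              max_iterations = config$mean_max_iterations)
}

.sjgda_args <- function(config, n_features) {
  cap <- min(config$grid_cap, n_features)
  grid <- unique(c(seq(min(config$grid_step, cap), cap, by = config$grid_step), cap))
  list(use_unlabelled = config$use_unlabelled, grid = grid,
       classifier_factory = knn_factory(config$k), bins = config$bins,
       d = config$d, degree = config$degree, coef0 = config$coef0,
       scale = config$kernel_scale, ridge = config$ridge,
       denominator = config$denominator, folds = config$select_folds,
       seed = config$seed, criterion = config$criterion)
}

#' Fit Method 1: SSDT-FGMDRM
#'
#' Band-pass filters each epoched trial, estimates spatial covariance
#' matrices, and trains the subject-specific decision tree whose nodes are
#' FGMDRM classifiers (binary one-vs-rest nodes for the most separable
#' classes, final multiclass node). With `tree = FALSE` in the config, the
#' flat multiclass FGMDRM baseline is fit instead.
#'
#' @param trials List of channels x samples matrices (epoched trials).
#' @param labels Class labels (`>= 3` classes for a nontrivial tree).
#' @param fs Sampling rate in Hz.
#' @param config A [pipeline_config()] with `method = 1`.
#' @return Object of class `riemi_method1`.
#' @export
method1_fit <- function(trials, labels, fs, config = pipeline_config(method = 1L)) {
  labels <- as.factor(labels)
  covs <- .trials_to_covs(trials, fs, config)
  factory <- fgmdrm_factory(r = config$r, config = .mean_cfg(config))
  model <- if (isTRUE(config$tree)) {
    build_ssdt(covs, labels, factory, folds = config$folds, seed = config$seed,
               final_scope = config$final_scope)
  } else {
    factory(covs, labels)
  }
  structure(list(model = model, fs = fs, config = config,
                 classes = levels(labels)),
            class = "riemi_method1")
}

#' @rdname method1_fit
#' @param object Fitted model.
#' @param newdata List of epoched trials.
#' @param ... Unused.
#' @export
predict.riemi_method1 <- function(object, newdata, ...) {
  covs <- .trials_to_covs(newdata, object$fs, object$config)
  p <- predict(object$model, covs)
  structure(as.character(p), node_id = attr(p, "node_id"))
}

#' Fit Method 2: SJGDA + SSDT-KNN
#'
#' Band-pass filters and covariance-estimates the trials, anchors the
#' tangent space at the Riemannian mean of the training covariances, maps
#' every trial to tangent coordinates, and trains the subject-specific
#' decision tree whose nodes each fit the SJGDA feature stack (semi-JMI
#' ranking, CV length selection, polynomial-kernel GDA) followed by KNN on
#' their own sub-problem. Unlabelled trials, when supplied, feed only the
#' semi-JMI ranking. `feature_scope = "global"` fits one shared SJGDA
#' space before the tree; `tree = FALSE` gives the flat multiclass
#' SJGDA-KNN baseline.
#'
#' @inheritParams method1_fit
#' @param unlabelled_trials Optional list of unlabelled epoched trials.
#' @param config A [pipeline_config()] with `method = 2`.
#' @return Object of class `riemi_method2`.
#' @export
method2_fit <- function(trials, labels, fs, unlabelled_trials = NULL,
                        config = pipeline_config(method = 2L)) {
  labels <- as.factor(labels)
  covs <- .trials_to_covs(trials, fs, config)
  reference <- riemannian_mean(covs, .mean_cfg(config))
  X <- tangent_features(covs, reference)
  Xu <- NULL
  if (!is.null(unlabelled_trials) && length(unlabelled_trials) > 0L) {
    covs_u <- .trials_to_covs(unlabelled_trials, fs, config)
    Xu <- tangent_features(covs_u, reference)
  }
  args <- .sjgda_args(config, ncol(X))
  sj_global <- NULL
  if (identical(config$feature_scope, "global")) {
    sj_global <- do.call(sjgda_fit,
                         c(list(x = X, labels = labels, x_unlabelled = Xu), args))
    feats <- sjgda_transform(sj_global, X)
    factory <- knn_factory(config$k)
    data <- feats
  } else {
    factory <- sjgda_knn_factory(k = config$k, sjgda_args = args, unlabelled = Xu)
    data <- X
  }
  model <- if (isTRUE(config$tree)) {
    build_ssdt(data, labels, factory, folds = config$folds, seed = config$seed,
               final_scope = config$final_scope)
  } else {
    factory(data, labels)
  }
  structure(list(model = model, reference = reference, sjgda = sj_global,
                 fs = fs, config = config, classes = levels(labels)),
            class = "riemi_method2")
}

#' @rdname method2_fit
#' @param object Fitted model.
#' @param newdata List of epoched trials.
#' @param ... Unused.
#' @export
predict.riemi_method2 <- function(object, newdata, ...) {
  covs <- .trials_to_covs(newdata, object$fs, object$config)
  X <- t(vapply(covs, function(P) tangent_vectorize(object$reference, P),
                numeric(nrow(object$reference) * (nrow(object$reference) + 1) / 2)))
  if (!is.null(object$sjgda)) X <- sjgda_transform(object$sjgda, X)
  p <- predict(object$model, X)
  structure(as.character(p), node_id = attr(p, "node_id"))
}

# Selected m per tree node of a fitted method-2 model (per-node scope).
.selected_m <- function(model) {
  if (!inherits(model$model, "ssdt")) {
    if (inherits(model$model, "sjgda_knn")) return(model$model$sjgda$m)
    if (!is.null(model$sjgda)) return(model$sjgda$m)
    return(NA_integer_)
  }
  vapply(model$model$nodes, function(nd) {
    if (inherits(nd$model, "sjgda_knn")) nd$model$sjgda$m else NA_integer_
  }, integer(1))
}

#' Stratified cross-validation of a pipeline
#'
#' Runs stratified k-fold cross-validation of Method 1 or Method 2 (per
#' `config$method`). All fitting — node ranking, feature ranking, length
#' selection, GDA, Riemannian means — happens inside each training fold
#' only; the held-out labels are used exclusively for scoring, so shuffling
#' them cannot change the fitted models.
#'
#' @param trials List of epoched trials.
#' @param labels Class labels.
#' @param fs Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @param folds Outer CV folds (default 10; `folds = length(trials)` gives
#'   leave-one-out).
#' @param seed Fold-assignment seed.
#' @param unlabelled_trials Optional unlabelled pool, passed to every
#'   training fold of method 2.
#' @return Object of class `mi_cv`: `per_fold` tibble (fold, n_test,
#'   accuracy, kappa), `confusion` matrix (true x predicted, aggregated),
#'   `mean_accuracy`, `mean_kappa`, `node_order` (per-fold ranking
#'   tibble), `selected_m`, `routing` (per-node decision counts), `folds`,
#'   `seed`, `config`.
#' @export
crossval <- function(trials, labels, fs, config = pipeline_config(),
                     folds = 10L, seed = 1L, unlabelled_trials = NULL) {
  labels <- as.factor(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  k <- attr(fold_id, "folds")
  lev <- levels(labels)
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(true = lev, pred = lev))
  per_fold <- vector("list", k)
  node_order <- list()
  routing <- integer(0)
  m_sel <- list()
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- if (config$method == 1L) {
      method1_fit(trials[tr], labels[tr], fs, config)
    } else {
      method2_fit(trials[tr], labels[tr], fs, unlabelled_trials, config)
    }
    pred <- predict(fit, trials[!tr])
    nid <- attr(pred, "node_id")
    if (!is.null(nid)) {
      tab <- table(nid)
      for (nm in names(tab)) {
        routing[nm] <- (if (nm %in% names(routing)) routing[nm] else 0L) + tab[[nm]]
      }
    }
    truth <- labels[!tr]
    confusion <- confusion + unclass(table(factor(truth, levels = lev),
                                           factor(as.character(pred), levels = lev)))
    per_fold[[f]] <- tibble::tibble(fold = f, n_test = sum(!tr),
                                    accuracy = accuracy_score(truth, pred),
                                    kappa = cohen_kappa(truth, pred))
    if (inherits(fit$model, "ssdt") && !is.null(fit$model$ranking)) {
      node_order[[f]] <- dplyr::mutate(fit$model$ranking, fold = f)
    }
    if (config$method == 2L) m_sel[[f]] <- .selected_m(fit)
  }
  per_fold <- dplyr::bind_rows(per_fold)
  structure(list(per_fold = per_fold,
                 confusion = confusion,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_kappa = mean(per_fold$kappa),
                 node_order = if (length(node_order)) dplyr::bind_rows(node_order) else NULL,
                 selected_m = m_sel,
                 routing = routing,
                 folds = k, seed = seed, config = config),
            class = "mi_cv")
}

#' @export
print.mi_cv <- function(x, ...) {
  cat(sprintf("<mi_cv> %d-fold stratified CV (method %d%s)\n", x$folds,
              x$config$method, if (isTRUE(x$config$tree)) ", SSDT" else ", flat"))
  cat(sprintf("  mean accuracy %.3f, mean kappa %.3f\n", x$mean_accuracy, x$mean_kappa))
  invisible(x)
}
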