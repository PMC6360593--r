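# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an OVR separability ranking
#'
#' @param x An `ovr_ranking` from [rank_ovr()].
#' @param ... Unused.
#' @return Tibble with `class`, `cv_accuracy`, `rank`.
#' @export
tidy.ovr_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("class", "cv_accuracy", "rank")])
}

#' Tidy a JMI feature ranking
#'
#' @param x A `jmi_ranking` from [jmi_rank()].
#' @param ... Unused.
#' @return Tibble with `feature`, `position`, `score`.
#' @export
tidy.jmi_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("feature", "position", "score")])
}

#' Tidy a fitted decision tree
#'
#' @param x An `ssdt` model.
#' @param ... Unused.
#' @return Tibble with one row per node: `node_id`, `kind`,
#'   `target_class`, `cv_accuracy`.
#' @export
tidy.ssdt <- function(x, ...) {
  purrr::map_dfr(x$nodes, function(nd) {
    tibble::tibble(node_id = nd$node_id, kind = nd$kind,
                   target_class = nd$target_class, cv_accuracy = nd$cv_accuracy)
  })
}

#' @rdname tidy.ssdt
#' @export
glance.ssdt <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes),
                 n_binary = sum(vapply(x$nodes, function(n) n$kind == "binary-ovr",
                                       logical(1))),
                 n_classes = length(x$classes),
                 base_kind = x$base_kind,
                 final_scope = x$final_scope)
}

#' Tidy a cross-validation report
#'
#' @param x An `mi_cv` report from [crossval()].
#' @param ... Unused.
#' @return Per-fold tibble (`fold`, `n_test`, `accuracy`, `kappa`).
#' @export
tidy.mi_cv <- function(x, ...) x$per_fold

#' @rdname tidy.mi_cv
#' @export
glance.mi_cv <- function(x, ...) {
  tibble::tibble(folds = x$folds, mean_accuracy = x$mean_accuracy,
                 mean_kappa = x$mean_kappa,
                 sd_accuracy = stats::sd(x$per_fold$accuracy),
                 method = x$config$method, tree = isTRUE(x$config$tree))
}

#' @rdname tidy.sjgda
#' @export
glance.sjgda <- function(x, ...) {
  tibble::tibble(m = x$m, d = x$gda$d, output_length = x$m + x$gda$d)
}

#' Tidy a fitted SJGDA feature stack
#'
#' @param x An `sjgda` model.
#' @param ... Unused.
#' @return The length-selection CV table (`m`, `cv_accuracy`).
#' @export
tidy.sjgda <- function(x, ...) x$length_cv

#' Plot per-fold cross-validation performance
#'
#' @param object An `mi_cv` report.
#' @param ... Unused.
#' @return A ggplot object: per-fold accuracy and kappa with mean lines.
#' @export
autoplot.mi_cv <- function(object, ...) {
  df <- tidyr_longer(object$per_fold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("Stratified %d-fold CV (method %d)",
                                  object$folds, object$config$method)) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_longer <- function(per_fold) {
  dplyr::bind_rows(
    tibble::tibble(fold = per_fold$fold, metric = "accuracy", value = per_fold$accuracy),
    tibble::tibble(fold = per_fold$fold, metric = "kappa", value = per_fold$kappa))
}

#' Plot an OVR separability ranking
#'
#' @param object An `ovr_ranking`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-class one-vs-rest CV accuracy.
#' @export
autoplot.ovr_ranking <- function(object, ...) {
  df <- tidy.ovr_ranking(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class, .data$rank),
                                   y = .data$cv_accuracy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "class (node order)", y = "OVR CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the SJGDA length-selection curve
#'
#' @param object An `sjgda` model.
#' @param ... Unused.
#' @return A ggplot of CV accuracy against retained feature count, with the
#'   selected length marked.
#' @export
autoplot.sjgda <- function(object, ...) {
  df <- object$length_cv
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$cv_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$m, linetype = "dashed") +
    ggplot2::labs(x = "retained ranked features m", y = "CV accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
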