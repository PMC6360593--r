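# Subject-specific decision tree (SSDT): one-vs-rest separability ranking,
# chained binary nodes for the most discriminative classes, and a final
# multiclass node that reclassifies everything the binary nodes passed down
# (including samples they failed to capture).

#' Rank classes by one-vs-rest cross-validated separability
#'
#' For each class `c`, estimates the stratified k-fold CV accuracy of the
#' base classifier on the binary problem `c` vs rest (all other classes
#' pooled, natural imbalance kept), and sorts classes by that accuracy.
#' This per-subject ranking decides the node order of the decision tree.
#'
#' @param data Training data: list of SPD matrices or feature matrix.
#' @param labels Class labels.
#' @param base_factory A factory from [base_factories].
#' @param folds CV folds (default 10).
#' @param seed Integer seed fixing fold assignment.
#' @return A tibble of class `ovr_ranking` with columns `class`,
#'   `cv_accuracy`, `rank`, sorted by decreasing accuracy (ties by class
#'   order).
#' @export
rank_ovr <- function(data, labels, base_factory, folds = 10L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  acc <- vapply(levels(labels), function(cl) {
    y_bin <- factor(ifelse(labels == cl, cl, ".rest"), levels = c(cl, ".rest"))
    .cv_accuracy(data, y_bin, base_factory, folds, seed)
  }, numeric(1))
  ord <- order(-acc, seq_along(acc))
  out <- tibble::tibble(class = levels(labels)[ord],
                        cv_accuracy = unname(acc[ord]),
                        rank = seq_along(ord))
  class(out) <- c("ovr_ranking", class(out))
  out
}

#' Build a subject-specific decision tree
#'
#' Constructs `max(C - 2, 0)` binary one-vs-rest nodes (2 for four classes,
#' 1 for three) ordered by the [rank_ovr()] separability ranking, followed
#' by one final multiclass node. Node `N.1` (top-ranked class vs rest) is
#' trained on all training data; each later binary node excludes the classes
#' targeted by earlier nodes from its training pool. By default the final
#' node is trained over all `C` classes so that samples misrouted past the
#' binary nodes can still be recovered; `final_scope = "remaining"`
#' restricts it to the classes no binary node targets. With `C = 2` the
#' tree degenerates to the base classifier (with a warning).
#'
#' @inheritParams rank_ovr
#' @param final_scope `"all"` (default) or `"remaining"`.
#' @return An object of class `ssdt`: list with `nodes` (each holding
#'   `node_id`, `kind`, `target_class`, `model`, `cv_accuracy`), `classes`,
#'   `ranking`, `base_kind`, `seed`.
#' @export
build_ssdt <- function(data, labels, base_factory, folds = 10L, seed = 1L,
                       final_scope = c("all", "remaining")) {
  final_scope <- match.arg(final_scope)
  labels <- droplevels(as.factor(labels))
  C <- nlevels(labels)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (C == 2L) warning("only 2 classes: SSDT degenerates to the base classifier")
  n_binary <- max(C - 2L, 0L)
  ranking <- if (C >= 3L) rank_ovr(data, labels, base_factory, folds, seed) else NULL
  nodes <- vector("list", n_binary + 1L)
  captured <- character(0)
  pool <- rep(TRUE, length(labels))
  for (j in seq_len(n_binary)) {
    target <- ranking$class[j]
    y_bin <- factor(ifelse(labels[pool] == target, target, ".rest"),
                    levels = c(target, ".rest"))
    model <- base_factory(.data_subset(data, pool), y_bin)
    nodes[[j]] <- list(node_id = j, kind = "binary-ovr", target_class = target,
                       model = model, cv_accuracy = ranking$cv_accuracy[j])
    captured <- c(captured, target)
    pool <- pool & labels != target
  }
  if (final_scope == "all") {
    fin_idx <- rep(TRUE, length(labels))
  } else {
    fin_idx <- !(labels %in% captured)
  }
  fin_labels <- droplevels(factor(labels[fin_idx], levels = levels(labels)))
  fin_model <- base_factory(.data_subset(data, fin_idx), fin_labels)
  nodes[[n_binary + 1L]] <- list(node_id = n_binary + 1L, kind = "final-multiclass",
                                 target_class = NA_character_, model = fin_model,
                                 cv_accuracy = NA_real_)
  structure(list(nodes = nodes, classes = levels(labels), ranking = ranking,
                 base_kind = attr(base_factory, "kind"), seed = seed,
                 final_scope = final_scope),
            class = "ssdt")
}

#' Predict with a subject-specific decision tree
#'
#' Each sample is routed through the nodes in order: a binary node returns
#' its target class if it claims the sample, otherwise passes it on; the
#' final node's multiclass decision is returned as-is. Routing is
#' deterministic given a fitted model.
#'
#' @param object Fitted [build_ssdt()] model.
#' @param newdata List of SPD matrices or feature matrix, matching the
#'   training representation.
#' @param ... Unused.
#' @return Character vector of predicted labels, with attribute
#'   `"node_id"` giving the node that decided each sample.
#' @export
predict.ssdt <- function(object, newdata, ...) {
  n <- .data_n(newdata)
  out <- character(n)
  decided_at <- integer(n)
  pending <- rep(TRUE, n)
  for (node in object$nodes) {
    if (!any(pending)) break
    sub <- .data_subset(newdata, pending)
    pred <- as.character(predict(node$model, sub))
    if (node$kind == "binary-ovr") {
      claimed <- pred == node$target_class
      idx <- which(pending)
      out[idx[claimed]] <- node$target_class
      decided_at[idx[claimed]] <- node$node_id
      pending[idx[claimed]] <- FALSE
    } else {
      out[pending] <- pred
      decided_at[pending] <- node$node_id
      pending[pending] <- FALSE
    }
  }
  structure(out, node_id = decided_at)
}
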