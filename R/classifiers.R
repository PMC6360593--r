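# Minimum-distance-to-Riemannian-mean classification, Fisher geodesic
# filtering, a plain k-nearest-neighbour classifier, and agreement metrics.

# ---- MDRM -----------------------------------------------------------------

#' Fit a minimum-distance-to-Riemannian-mean (MDRM) classifier
#'
#' Computes the Riemannian (Karcher) mean of the covariance matrices of each
#' class; prediction assigns a trial's covariance to the class with the
#' nearest mean under the affine-invariant distance.
#'
#' @param covs List of SPD matrices (one per trial).
#' @param labels Class labels, one per trial; at least 2 classes with at
#'   least 1 trial each.
#' @param config A [mean_config()] for the per-class means.
#' @return An object of class `mdrm` with elements `classes` and `means`.
#' @export
mdrm_fit <- function(covs, labels, config = mean_config()) {
  labels <- droplevels(as.factor(labels))
  if (length(covs) != length(labels)) stop("covs/labels length mismatch", call. = FALSE)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) == 0L)) stop("every class needs at least one trial", call. = FALSE)
  means <- lapply(levels(labels), function(cl) {
    riemannian_mean(covs[labels == cl], config)
  })
  names(means) <- levels(labels)
  structure(list(classes = levels(labels), means = means), class = "mdrm")
}

# Distances from one SPD matrix to each class mean of an mdrm-like model.
.mdrm_distances <- function(means, P) {
  vapply(means, function(M) riemannian_distance(M, P), numeric(1))
}

#' Predict with an MDRM model
#'
#' @param object Fitted [mdrm_fit()] model.
#' @param newdata A single SPD matrix or a list of SPD matrices.
#' @param type `"class"` for labels, `"distance"` for the full matrix of
#'   Riemannian distances to each class mean.
#' @param ... Unused.
#' @return A character vector of labels, or a trials-by-classes distance
#'   matrix. Distance ties are broken by class order (a message is emitted).
#' @export
predict.mdrm <- function(object, newdata, type = c("class", "distance"), ...) {
  type <- match.arg(type)
  covs <- if (is.matrix(newdata)) list(newdata) else newdata
  D <- t(vapply(covs, function(P) {
    .check_same_dim(object$means[[1L]], P)
    .mdrm_distances(object$means, P)
  }, numeric(length(object$classes))))
  colnames(D) <- object$classes
  if (type == "distance") return(D)
  idx <- apply(D, 1L, function(d) {
    w <- which(d == min(d))
    if (length(w) > 1L) message("predict.mdrm: distance tie broken by class order")
    w[1L]
  })
  object$classes[idx]
}

# ---- FGDA: Fisher geodesic discriminant analysis --------------------------

#' Fit Fisher geodesic discriminant filters on tangent vectors
#'
#' Tangent-space Fisher discriminant: between-class and within-class scatter
#' are formed on the tangent coordinate vectors (all anchored at a common
#' reference), and the filter basis spans the leading generalized
#' eigenvectors of (between, within), orthonormalized. A ridge
#' `1e-9 tr(S_W)/p` is added to the within-class scatter when it is
#' ill-conditioned.
#'
#' @param tangent_vectors Matrix, trials x `n(n+1)/2` tangent coordinates.
#' @param labels Class labels.
#' @param r Number of retained discriminant directions; defaults to
#'   `C - 1` for `C` classes, at most the tangent dimension.
#' @param reference The SPD anchor the vectors were computed at (stored for
#'   filtering; may be `NULL` when only the basis is needed).
#' @return An object of class `fgda` with orthonormal `basis`
#'   (`p x r`, `t(basis) %*% basis = I`), `r`, and `reference`.
#' @export
fgda_fit <- function(tangent_vectors, labels, r = NULL, reference = NULL) {
  X <- as.matrix(tangent_vectors)
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(X) == length(labels))
  C <- nlevels(labels)
  p <- ncol(X)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(r)) r <- min(C - 1L, p)
  if (r < 1L || r > p) stop("`r` out of range", call. = FALSE)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(labels)) {
    Xc <- X[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    Xcc <- sweep(Xc, 2L, mc)
    Sw <- Sw + crossprod(Xcc)
    Sb <- Sb + nrow(Xc) * tcrossprod(mc - mu)
  }
  ev_w <- eigen(.sym(Sw), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_w) <= 1e-10 * max(ev_w)) {
    Sw <- Sw + diag(1e-9 * sum(diag(Sw)) / p, p)
  }
  W <- .spd_isqrtm(Sw)
  e <- eigen(.sym(W %*% Sb %*% W), symmetric = TRUE)
  dirs <- W %*% e$vectors[, seq_len(r), drop = FALSE]
  basis <- qr.Q(qr(dirs))[, seq_len(r), drop = FALSE]
  structure(list(basis = basis, r = r, reference = reference,
                 eigenvalues = e$values[seq_len(r)]),
            class = "fgda")
}

#' Filter a covariance matrix through FGDA discriminant directions
#'
#' Maps `P` to the tangent space at the filter's reference, projects the
#' coordinates onto the discriminant subspace (`basis %*% t(basis)`), and
#' reconstructs an SPD matrix via the exponential map. With a full-rank
#' basis this is the identity (up to numerical error).
#'
#' @param filter A fitted [fgda_fit()] with a non-`NULL` reference.
#' @param P SPD matrix.
#' @return Filtered SPD matrix.
#' @export
fgda_filter <- function(filter, P) {
  if (is.null(filter$reference)) stop("filter has no reference point", call. = FALSE)
  s <- tangent_vectorize(filter$reference, P)
  s_proj <- as.numeric(filter$basis %*% crossprod(filter$basis, s))
  tangent_unvectorize(filter$reference, s_proj)
}

# ---- FGMDRM ---------------------------------------------------------------

#' Fit an FGMDRM classifier (FGDA filtering + MDRM)
#'
#' Anchors the tangent space at the Riemannian mean of all training
#' covariances, fits Fisher geodesic discriminant filters on their tangent
#' vectors, reconstructs filtered covariances, and fits MDRM on those.
#' Prediction filters the query covariance and applies MDRM.
#'
#' @inheritParams mdrm_fit
#' @param r Retained discriminant directions (default `C - 1`).
#' @return Object of class `fgmdrm` with elements `filter` and `mdrm`.
#' @export
fgmdrm_fit <- function(covs, labels, r = NULL, config = mean_config()) {
  labels <- as.factor(labels)
  reference <- riemannian_mean(covs, config)
  X <- tangent_features(covs, reference)
  filt <- fgda_fit(X, labels, r = r, reference = reference)
  filtered <- lapply(covs, function(P) fgda_filter(filt, P))
  structure(list(filter = filt, mdrm = mdrm_fit(filtered, labels, config)),
            class = "fgmdrm")
}

#' @rdname fgmdrm_fit
#' @inheritParams predict.mdrm
#' @export
predict.fgmdrm <- function(object, newdata, type = c("class", "distance"), ...) {
  covs <- if (is.matrix(newdata)) list(newdata) else newdata
  filtered <- lapply(covs, function(P) fgda_filter(object$filter, P))
  predict(object$mdrm, filtered, type = match.arg(type))
}

# ---- KNN ------------------------------------------------------------------

#' Fit a k-nearest-neighbour classifier
#'
#' Plain Euclidean KNN with majority vote. Vote ties are resolved by the
#' smallest summed distance among tied classes, then by label order.
#'
#' @param x Feature matrix, points x features.
#' @param labels Class labels.
#' @param k Positive odd neighbour count, at most `nrow(x)`; default 5.
#' @return Object of class `riemi_knn`.
#' @export
knn_fit <- function(x, labels, k = 5L) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(nrow(x) == length(labels))
  k <- as.integer(k)
  if (k > nrow(x)) {
    k <- nrow(x) - (1L - nrow(x) %% 2L)  # largest odd value <= n
    warning(sprintf("k reduced to %d (training set size)", k))
  }
  if (k %% 2L == 0L) stop("`k` must be odd", call. = FALSE)
  structure(list(points = x, labels = labels, k = k), class = "riemi_knn")
}

#' @rdname knn_fit
#' @param object Fitted `riemi_knn` model.
#' @param newdata Query matrix (or single vector).
#' @param ... Unused.
#' @export
predict.riemi_knn <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(object$points)) stop("feature dimension mismatch", call. = FALSE)
  lev <- levels(object$labels)
  apply(newdata, 1L, function(q) {
    d <- sqrt(colSums((t(object$points) - q)^2))
    nn <- order(d)[seq_len(object$k)]
    votes <- table(factor(object$labels[nn], levels = lev))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) sum(d[nn][object$labels[nn] == cl]), numeric(1))
      top <- top[sums == min(sums)]
    }
    top[1L]
  })
}

# ---- agreement metrics ----------------------------------------------------

#' Classification accuracy
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Fraction of agreeing positions.
#' @export
accuracy_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  mean(as.character(y_true) == as.character(y_pred))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` computed from the marginal products of the contingency
#' table. When both vectors are constant and identical (`p_e = 1`), kappa
#' is defined as 0 and a warning is emitted.
#'
#' @inheritParams accuracy_score
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  lev <- union(unique(as.character(y_true)), unique(as.character(y_pred)))
  a <- factor(as.character(y_true), levels = lev)
  b <- factor(as.character(y_pred), levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1) {
    warning("cohen_kappa: expected agreement is 1 (single class on both sides); returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}
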