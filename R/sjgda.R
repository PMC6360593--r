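# Tangent-space feature extraction: equal-frequency discretization,
# plug-in mutual information, (semi-supervised) joint-mutual-information
# feature ranking, CV-based length selection, polynomial-kernel generalized
# discriminant analysis, and the SJGDA concatenation [f_G | f_SJ].

# ---- discretization -------------------------------------------------------

#' Equal-frequency discretization of a feature table
#'
#' Fits per-feature equal-frequency bin edges on all available rows
#' (labelled and unlabelled alike) and returns integer bin codes. The map
#' is monotone; a constant feature collapses to a single bin with a
#' warning.
#'
#' @param x Numeric feature matrix, trials x features.
#' @param bins Number of bins (`>= 2`, default 8).
#' @return Object of class `riemi_discretizer`: list with integer matrix
#'   `codes` and per-feature `edges`.
#' @export
discretize_features <- function(x, bins = 8L) {
  x <- as.matrix(x)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  edges <- vector("list", ncol(x))
  codes <- matrix(1L, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    qs <- unique(stats::quantile(x[, j], probs = seq(0, 1, length.out = bins + 1L),
                                 names = FALSE))
    if (length(qs) < 2L) {
      warning(sprintf("feature %d is constant; single bin used", j))
      edges[[j]] <- qs
    } else {
      edges[[j]] <- qs
      codes[, j] <- as.integer(cut(x[, j], breaks = qs, include.lowest = TRUE))
    }
  }
  structure(list(codes = codes, edges = edges, bins = as.integer(bins)),
            class = "riemi_discretizer")
}

# ---- mutual information ---------------------------------------------------

# Entropy/MI from a joint probability matrix (rows = z states, cols = y states).
.mi_from_joint <- function(pj) {
  pz <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  val <- sum(pj[nz] * log2(pj[nz] / (pz[row(pj)[nz]] * py[col(pj)[nz]])))
  max(val, 0)
}

#' Plug-in mutual information between discrete variables (bits)
#'
#' Empirical mutual information `I(a; b)` from the joint frequency table.
#' For a joint pair on the first argument, pass a two-column matrix; the
#' pair is treated as one variable on the product alphabet (used by the JMI
#' score `I(X_k, X_j; Y)`).
#'
#' @param a Discrete vector, or a two-column matrix for a joint pair.
#' @param b Discrete vector of the same length.
#' @return Non-negative scalar in bits; `mutual_information(a, a)` equals
#'   the entropy `H(a)`.
#' @export
mutual_information <- function(a, b) {
  if (is.matrix(a)) {
    if (nrow(a) != length(b)) stop("length mismatch", call. = FALSE)
    a <- interaction(a[, 1L], a[, 2L], drop = TRUE)
  }
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  pj <- table(a, b) / length(b)
  .mi_from_joint(unclass(pj))
}

# Semi-supervised (MAR-C) mutual information between a discrete variable z
# (observed on all rows) and the label y (observed on labelled rows only).
# Class-conditionals p(z|y) come from labelled rows; class priors are
# re-estimated by EM on the unlabelled marginal under the class-prior-change
# assumption; the joint is reassembled as pi_y p(z|y).
.mi_semi <- function(z, y, labelled) {
  z <- as.integer(factor(z))
  yl <- factor(y[labelled])
  zl <- z[labelled]
  zu <- z[!labelled]
  K <- max(z); C <- nlevels(yl)
  cond <- matrix(0, K, C)            # p(z | y)
  for (c in seq_len(C)) {
    zc <- zl[as.integer(yl) == c]
    cond[, c] <- tabulate(zc, nbins = K) / max(length(zc), 1L)
  }
  prior <- as.numeric(table(yl)) / length(zl)
  if (length(zu) > 0L) {
    cnt_u <- tabulate(zu, nbins = K)
    for (it in seq_len(100L)) {
      # E-step: responsibilities per z state; M-step: reweighted priors.
      # Unlabelled states with zero likelihood under every class carry no
      # prior information and are dropped from the M-step.
      lik <- cond * rep(prior, each = K)        # K x C: pi_y p(z|y)
      tot <- rowSums(lik)
      ok <- tot > 0 & cnt_u > 0
      if (!any(ok)) break
      resp <- lik[ok, , drop = FALSE] / tot[ok]
      new_prior <- colSums(resp * cnt_u[ok]) / sum(cnt_u[ok])
      if (!all(is.finite(new_prior))) break
      converged <- max(abs(new_prior - prior)) < 1e-10
      prior <- new_prior
      if (converged) break
    }
  }
  joint <- cond * rep(prior, each = K)
  joint <- joint / sum(joint)
  .mi_from_joint(joint)
}

# ---- JMI ranking ----------------------------------------------------------

#' Rank features by (semi-supervised) joint mutual information
#'
#' Greedy forward selection: the first feature maximizes `I(X_k; Y)`;
#' thereafter each candidate is scored by
#' `sum over selected X_j of I(X_k, X_j; Y)` (the joint of the candidate and
#' an already selected feature with the label) and the argmax is appended,
#' until all features are ordered. Ties go to the lower feature index. With
#' `use_unlabelled = TRUE` and a non-empty unlabelled pool, every mutual
#' information term is estimated under the class-prior-change (MAR-C)
#' missingness model: class-conditional feature distributions come from
#' labelled rows, the class priors are re-estimated by EM on the unlabelled
#' marginal, and the joint is reassembled from the two. With an empty
#' unlabelled pool the supervised estimator is used, so the ordering
#' reduces exactly to plain JMI.
#'
#' A conditional variant (`criterion = "cmim"`, scoring
#' `sum I(X_k; Y | X_j)`) is available for comparison.
#'
#' @param x Labelled feature matrix, trials x features.
#' @param labels Class labels for the rows of `x`.
#' @param x_unlabelled Optional unlabelled feature matrix (same columns).
#' @param use_unlabelled Use the semi-supervised estimator when unlabelled
#'   rows are present.
#' @param bins Discretization bins (default 8).
#' @param criterion `"jmi"` (default) or `"cmim"`.
#' @return A tibble of class `jmi_ranking` with columns `feature`,
#'   `position`, `score` (the selection-time score).
#' @export
jmi_rank <- function(x, labels, x_unlabelled = NULL, use_unlabelled = FALSE,
                     bins = 8L, criterion = c("jmi", "cmim")) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 labelled classes", call. = FALSE)
  if (nrow(x) == 0L) stop("no labelled rows", call. = FALSE)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 features", call. = FALSE)
  n_lab <- nrow(x)
  all_x <- if (!is.null(x_unlabelled) && nrow(x_unlabelled) > 0L) {
    rbind(x, as.matrix(x_unlabelled))
  } else x
  disc <- discretize_features(all_x, bins = bins)
  codes <- disc$codes
  labelled <- seq_len(nrow(all_x)) <= n_lab
  semi <- use_unlabelled && any(!labelled)
  y <- labels

  mi_single <- function(j) {
    if (semi) .mi_semi(codes[, j], c(as.character(y), rep(NA, sum(!labelled))), labelled)
    else mutual_information(codes[labelled, j], y)
  }
  pair_code <- function(j, k) {
    (codes[, j] - 1L) * max(codes[, k]) + codes[, k]
  }
  mi_pair <- function(j, k) {
    z <- pair_code(j, k)
    if (semi) .mi_semi(z, c(as.character(y), rep(NA, sum(!labelled))), labelled)
    else mutual_information(z[labelled], y)
  }
  # conditional I(Xk; Y | Xj) = I((Xk,Xj); Y) - I(Xj; Y)
  relevance <- vapply(seq_len(p), mi_single, numeric(1))
  order_out <- integer(p); score_out <- numeric(p)
  first <- which.max(relevance)
  order_out[1L] <- first; score_out[1L] <- relevance[first]
  remaining <- setdiff(seq_len(p), first)
  cum <- numeric(p)       # cumulative JMI score over selected set
  for (pos in 2L:p) {
    last <- order_out[pos - 1L]
    for (k in remaining) {
      inc <- mi_pair(k, last)
      if (criterion == "cmim") inc <- inc - relevance[last]
      cum[k] <- cum[k] + inc
    }
    best <- remaining[which.max(cum[remaining])]
    order_out[pos] <- best; score_out[pos] <- cum[best]
    remaining <- setdiff(remaining, best)
  }
  out <- tibble::tibble(feature = order_out, position = seq_len(p), score = score_out)
  class(out) <- c("jmi_ranking", class(out))
  out
}

#' Select the feature-vector length by cross-validated accuracy
#'
#' For each candidate length `m` in `grid`, evaluates the stratified k-fold
#' CV accuracy of the classifier built on the top-`m` ranked features, and
#' returns the argmax (ties broken towards the smallest `m`). The paper's
#' per-dataset caps (first 100 ranked variables for 22-channel data, first
#' 60 for 14-channel data) enter through the grid.
#'
#' @param x Labelled feature matrix.
#' @param labels Class labels.
#' @param ranking A [jmi_rank()] result.
#' @param classifier_factory Factory from [base_factories] (e.g.
#'   `knn_factory(5)`).
#' @param grid Candidate lengths; values beyond `ncol(x)` are dropped with
#'   a warning.
#' @param folds CV folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Selected `m` (integer) with attribute `"cv"`: tibble of
#'   per-length CV accuracies.
#' @export
select_length <- function(x, labels, ranking, classifier_factory,
                          grid, folds = 10L, seed = 1L) {
  x <- as.matrix(x)
  if (length(grid) == 0L) stop("`grid` is empty", call. = FALSE)
  if (any(grid > ncol(x))) {
    warning("grid values beyond the feature count were dropped")
    grid <- grid[grid <= ncol(x)]
    if (length(grid) == 0L) stop("no admissible grid values", call. = FALSE)
  }
  grid <- sort(unique(as.integer(grid)))
  acc <- vapply(grid, function(m) {
    cols <- ranking$feature[seq_len(m)]
    .cv_accuracy(x[, cols, drop = FALSE], labels, classifier_factory, folds, seed)
  }, numeric(1))
  m <- grid[which.max(acc)]    # which.max -> first max -> smallest m on ties
  structure(as.integer(m), cv = tibble::tibble(m = grid, cv_accuracy = acc))
}

# ---- polynomial kernel and GDA -------------------------------------------

#' Polynomial kernel
#'
#' `k(x, y) = (scale * <x, y> + coef0)^degree`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param degree Polynomial degree (default 2).
#' @param coef0 Additive constant (default 1).
#' @param scale Inner-product scale; default `1 / length(x)`.
#' @return Scalar kernel value.
#' @export
poly_kernel <- function(x, y, degree = 2, coef0 = 1, scale = NULL) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (is.null(scale)) scale <- 1 / length(x)
  (scale * sum(x * y) + coef0)^degree
}

# Kernel matrix between row sets A and B.
.poly_K <- function(A, B, degree, coef0, scale) {
  (scale * tcrossprod(A, B) + coef0)^degree
}

#' Fit generalized discriminant analysis (kernel Fisher discriminant)
#'
#' Maximizes the ratio of between-class to within-class scatter in the
#' feature space induced by a polynomial kernel, via the centered kernel
#' matrix. Projection directions are expansions over the training points
#' (coefficients `alpha`); training projections are normalized to unit
#' pooled within-class variance per output dimension. The denominator can
#' be the within-class scatter (default, the standard kernel Fisher
#' discriminant) or the total scatter.
#'
#' @param x Labelled feature matrix (trials x features).
#' @param labels Class labels (`>= 2` classes).
#' @param d Output dimensionality (default 1, at most `C - 1`).
#' @param degree,coef0,scale Polynomial-kernel parameters; `scale`
#'   defaults to `1 / ncol(x)`.
#' @param ridge Regularization added to the scatter denominator; escalated
#'   tenfold up to `1e-2` if the eigenproblem yields non-finite results.
#' @param denominator `"within"` (default) or `"total"`.
#' @return Object of class `riemi_gda` with `support_points`, `alphas`
#'   (N x d), kernel parameters, and centering statistics.
#' @export
gda_fit <- function(x, labels, d = 1L, degree = 2, coef0 = 1, scale = NULL,
                    ridge = 1e-2, denominator = c("within", "total")) {
  denominator <- match.arg(denominator)
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  C <- nlevels(labels)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (d > C - 1L) stop("`d` must be <= C - 1", call. = FALSE)
  if (is.null(scale)) scale <- 1 / ncol(x)
  N <- nrow(x)
  K <- .poly_K(x, x, degree, coef0, scale)
  km_col <- colMeans(K); km_all <- mean(K)
  Kc <- K - matrix(km_col, N, N, byrow = FALSE) -
        matrix(km_col, N, N, byrow = TRUE) + km_all
  Kc <- .sym(Kc)
  # class-indicator block matrix B = sum_c (1/N_c) 1_c 1_c'
  B <- matrix(0, N, N)
  for (cl in levels(labels)) {
    idx <- labels == cl
    B[idx, idx] <- 1 / sum(idx)
  }
  Sb <- .sym(Kc %*% B %*% Kc)
  Sw <- .sym(Kc %*% (diag(N) - B) %*% Kc)
  den <- if (denominator == "within") Sw else Sw + Sb
  rid <- ridge
  repeat {
    den_r <- den + diag(rid * max(sum(diag(den)) / N, 1), N)
    W <- .spd_isqrtm(den_r)
    e <- eigen(.sym(W %*% Sb %*% W), symmetric = TRUE)
    alphas <- W %*% e$vectors[, seq_len(d), drop = FALSE]
    proj <- Kc %*% alphas
    if (all(is.finite(alphas)) && all(is.finite(proj))) break
    rid <- rid * 10
    if (rid > 1e-2) stop("GDA eigenproblem remained singular after ridge escalation",
                         call. = FALSE)
  }
  # normalize training projections to unit pooled within-class variance
  for (jd in seq_len(d)) {
    ss <- 0
    for (cl in levels(labels)) {
      pc <- proj[labels == cl, jd]
      ss <- ss + sum((pc - mean(pc))^2)
    }
    wvar <- ss / max(N - C, 1L)
    if (wvar > 1e-300) alphas[, jd] <- alphas[, jd] / sqrt(wvar)
  }
  structure(list(support_points = x, alphas = alphas, d = as.integer(d),
                 degree = degree, coef0 = coef0, scale = scale,
                 km_col = km_col, km_all = km_all, ridge = rid,
                 classes = levels(labels)),
            class = "riemi_gda")
}

#' Project new points through a fitted GDA model
#'
#' Evaluates `sum_j alpha_ij k(x_j, z)` per output dimension with the
#' training centering applied to the kernel evaluations.
#'
#' @param model Fitted [gda_fit()] model.
#' @param newdata Query matrix (or single vector).
#' @return Matrix, queries x `d`.
#' @export
gda_transform <- function(model, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != ncol(model$support_points)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  Kz <- .poly_K(newdata, model$support_points, model$degree, model$coef0, model$scale)
  Kzc <- Kz - rowMeans(Kz) -
         matrix(model$km_col, nrow(Kz), ncol(Kz), byrow = TRUE) + model$km_all
  Kzc %*% model$alphas
}

# ---- SJGDA ----------------------------------------------------------------

#' Fit the SJGDA feature stack
#'
#' The full tangent-space reduction: (1) rank all features by
#' (semi-supervised) joint mutual information; (2) select the retained
#' length `m` by cross-validated accuracy of a downstream classifier on the
#' top-`m` features; (3) fit polynomial-kernel GDA on those `m` features.
#' The transform of a feature vector is the concatenation
#' `[f_G | f_SJ]` of the `d`-dimensional GDA projection and the top-`m`
#' ranked raw features, total length `m + d`.
#'
#' @param x Labelled tangent-feature matrix.
#' @param labels Class labels.
#' @param x_unlabelled Optional unlabelled rows for the semi-JMI path.
#' @param use_unlabelled Enable the semi-supervised ranking estimator.
#' @param grid Candidate lengths for `m`; defaults to multiples of 5 up to
#'   `min(100, ncol(x))`.
#' @param classifier_factory CV classifier for length selection (default
#'   `knn_factory(5)`).
#' @param bins Discretization bins for the ranking.
#' @param d,degree,coef0,scale,ridge,denominator GDA parameters, see
#'   [gda_fit()].
#' @param folds,seed Length-selection CV settings.
#' @param criterion Ranking criterion, see [jmi_rank()].
#' @return Object of class `sjgda`: `ranking`, `m`, `gda`, `length_cv`.
#' @export
sjgda_fit <- function(x, labels, x_unlabelled = NULL, use_unlabelled = FALSE,
                      grid = NULL, classifier_factory = knn_factory(5L),
                      bins = 8L, d = 1L, degree = 2, coef0 = 1, scale = NULL,
                      ridge = 1e-2, denominator = "within",
                      folds = 10L, seed = 1L, criterion = "jmi") {
  x <- as.matrix(x)
  if (is.null(grid)) {
    cap <- min(100L, ncol(x))
    grid <- unique(c(seq(5L, cap, by = 5L), cap))
    grid <- grid[grid >= 1L]
  }
  ranking <- jmi_rank(x, labels, x_unlabelled = x_unlabelled,
                      use_unlabelled = use_unlabelled, bins = bins,
                      criterion = criterion)
  m <- select_length(x, labels, ranking, classifier_factory, grid,
                     folds = folds, seed = seed)
  cols <- ranking$feature[seq_len(m)]
  gda <- gda_fit(x[, cols, drop = FALSE], labels, d = d, degree = degree,
                 coef0 = coef0, scale = scale, ridge = ridge,
                 denominator = denominator)
  structure(list(ranking = ranking, m = as.integer(m), selected = cols,
                 gda = gda, length_cv = attr(m, "cv")),
            class = "sjgda")
}

#' @rdname sjgda_fit
#' @param model Fitted `sjgda` model.
#' @param newdata Feature matrix (full tangent dimensionality) or single
#'   vector.
#' @return Matrix, queries x `(m + d)`, laid out `[f_G | f_SJ]`.
#' @export
sjgda_transform <- function(model, newdata) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  xs <- newdata[, model$selected, drop = FALSE]
  cbind(gda_transform(model$gda, xs), xs)
}
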