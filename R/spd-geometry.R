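#' @importFrom stats rnorm quantile predict rWishart cor
#' @importFrom utils head
NULL

# ---- internal symmetric-eigen matrix functions ----------------------------

.sym <- function(M) (M + t(M)) / 2

# Apply a scalar function to the eigenvalues of a symmetric matrix.
# Eigenvalues are floored at `clip` times the largest one so that sqrt/log/
# inverse stay finite on nearly singular input.
.eig_apply <- function(P, fun, clip = 1e-12) {
  e <- eigen(.sym(P), symmetric = TRUE)
  floor_at <- clip * max(abs(e$values))
  vals <- pmax(e$values, floor_at)
  .sym(e$vectors %*% (fun(vals) * t(e$vectors)))
}

.spd_sqrtm  <- function(P) .eig_apply(P, sqrt)
.spd_isqrtm <- function(P) .eig_apply(P, function(v) 1 / sqrt(v))
.spd_logm   <- function(P) .eig_apply(P, log)

# exp of a general symmetric matrix (eigenvalues may be negative; no clipping)
.sym_expm <- function(S) {
  e <- eigen(.sym(S), symmetric = TRUE)
  .sym(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

.fnorm <- function(M) sqrt(sum(M * M))

.check_spd <- function(P, arg = "P", tol = 1e-10) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  }
  if (!all(is.finite(P))) stop(sprintf("`%s` has non-finite entries", arg), call. = FALSE)
  asym <- .fnorm(P - t(P)) / max(.fnorm(P), .Machine$double.xmin)
  if (asym > tol) {
    stop(sprintf("`%s` is not symmetric (relative asymmetry %.3g)", arg, asym), call. = FALSE)
  }
  ev <- eigen(.sym(P), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("`%s` is not positive definite (min eigenvalue %.3g)", arg, min(ev)),
         call. = FALSE)
  }
  invisible(TRUE)
}

.check_same_dim <- function(P1, P2) {
  if (!identical(dim(P1), dim(P2))) stop("matrices have mismatched dimensions", call. = FALSE)
  invisible(TRUE)
}

# ---- covariance estimation ------------------------------------------------

#' Spatial covariance matrix of one EEG trial
#'
#' Estimates the spatial covariance matrix (SCM) of an epoched trial,
#' `X %*% t(X) / (Ts - 1)` for a zero-mean channels-by-samples matrix `X`.
#' If the result is numerically rank deficient (smallest eigenvalue below
#' `1e-10` times the largest), shrinkage towards the scaled identity
#' `(1 - gamma) P + gamma (tr(P)/n) I` is applied with the smallest
#' `gamma` in `{1e-6, 1e-4, 1e-2}` that restores conditioning, and a
#' message is emitted.
#'
#' @param trial Numeric matrix, channels x samples (`n x Ts`, `Ts >= n + 1`
#'   recommended so the SCM can be full rank).
#' @param regularization Non-negative ridge added to the diagonal.
#' @return A symmetric positive-definite `n x n` matrix.
#' @export
compute_scm <- function(trial, regularization = 0) {
  if (!is.matrix(trial) || !all(is.finite(trial))) {
    stop("`trial` must be a finite numeric matrix", call. = FALSE)
  }
  if (regularization < 0) stop("`regularization` must be >= 0", call. = FALSE)
  n  <- nrow(trial)
  ts <- ncol(trial)
  if (ts < 2L) stop("trial needs at least 2 samples", call. = FALSE)
  P <- tcrossprod(trial) / (ts - 1)
  if (regularization > 0) P <- P + diag(regularization, n)
  ev <- eigen(.sym(P), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev) || max(ev) == 0) {
    for (gamma in c(1e-6, 1e-4, 1e-2)) {
      Ps <- (1 - gamma) * P + gamma * (sum(diag(P)) / n) * diag(n)
      ev <- eigen(.sym(Ps), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 1e-10 * max(ev) && min(ev) > 0) {
        message(sprintf("compute_scm: rank-deficient SCM, shrinkage gamma = %g applied", gamma))
        return(.sym(Ps))
      }
    }
    stop("degenerate trial: covariance not positive definite after shrinkage",
         call. = FALSE)
  }
  .sym(P)
}

# ---- affine-invariant geometry -------------------------------------------

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta_R(P1, P2) = ||log(P1^{-1} P2)||_F = sqrt(sum_i log^2 lambda_i)`
#' where `lambda_i` are the generalized eigenvalues of `(P2, P1)`. The
#' distance is symmetric in its arguments and invariant under congruence
#' `P -> W P W'` for any invertible `W`.
#'
#' @param P1,P2 SPD matrices of the same dimension.
#' @return Non-negative scalar.
#' @export
riemannian_distance <- function(P1, P2) {
  .check_spd(P1, "P1"); .check_spd(P2, "P2"); .check_same_dim(P1, P2)
  W <- .spd_isqrtm(P1)
  ev <- eigen(.sym(W %*% P2 %*% W), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, .Machine$double.xmin)
  sqrt(sum(log(ev)^2))
}

#' Exponential map on the SPD manifold
#'
#' Maps a symmetric tangent matrix `S` at base point `P` back to the
#' manifold: `P^{1/2} exp(P^{-1/2} S P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param S Symmetric matrix (tangent vector at `P`), same dimension.
#' @return An SPD matrix.
#' @export
spd_exp_map <- function(P, S) {
  .check_spd(P, "P"); .check_same_dim(P, S)
  if (.fnorm(S - t(S)) > 1e-8 * max(.fnorm(S), 1)) {
    stop("`S` must be symmetric", call. = FALSE)
  }
  Ph <- .spd_sqrtm(P); Pi <- .spd_isqrtm(P)
  .sym(Ph %*% .sym_expm(Pi %*% .sym(S) %*% Pi) %*% Ph)
}

#' Logarithmic map on the SPD manifold
#'
#' Inverse of [spd_exp_map()]: the tangent matrix at `P` pointing to `Pi`,
#' `P^{1/2} log(P^{-1/2} Pi P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param Pi SPD matrix to map, same dimension.
#' @return A symmetric matrix.
#' @export
spd_log_map <- function(P, Pi) {
  .check_spd(P, "P"); .check_spd(Pi, "Pi"); .check_same_dim(P, Pi)
  Ph <- .spd_sqrtm(P); Pw <- .spd_isqrtm(P)
  .sym(Ph %*% .spd_logm(Pw %*% Pi %*% Pw) %*% Ph)
}

#' Convergence settings for the Karcher mean
#'
#' @param tolerance Stop when the Frobenius norm of the mean tangent
#'   displacement falls below `tolerance` times the mean Frobenius norm of
#'   the inputs.
#' @param max_iterations Maximum Karcher-flow iterations.
#' @param step Step size in `(0, 1]`.
#' @return A list of class `mean_config`.
#' @export
mean_config <- function(tolerance = 1e-8, max_iterations = 100L, step = 1) {
  stopifnot(tolerance > 0, max_iterations >= 1, step > 0, step <= 1)
  structure(list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
                 step = step), class = "mean_config")
}

#' Riemannian (Karcher) mean of SPD matrices
#'
#' The geometric mean in the Riemannian sense: the SPD matrix minimizing
#' the sum of squared affine-invariant distances to the inputs. Computed by
#' the Karcher flow `M <- M^{1/2} exp(step * mean_i log(M^{-1/2} P_i
#' M^{-1/2})) M^{1/2}` initialized at the arithmetic mean.
#'
#' @param matrices List of SPD matrices of common dimension.
#' @param config A [mean_config()].
#' @return The mean SPD matrix, with attribute `"iterations"`.
#' @export
riemannian_mean <- function(matrices, config = mean_config()) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a non-empty list of SPD matrices", call. = FALSE)
  }
  for (i in seq_along(matrices)) .check_spd(matrices[[i]], sprintf("matrices[[%d]]", i))
  if (length(matrices) == 1L) return(matrices[[1L]])
  scale <- mean(vapply(matrices, .fnorm, numeric(1)))
  M <- .sym(Reduce(`+`, matrices) / length(matrices))
  for (iter in seq_len(config$max_iterations)) {
    Mh <- .spd_sqrtm(M); Mw <- .spd_isqrtm(M)
    Tm <- matrix(0, nrow(M), ncol(M))
    for (P in matrices) Tm <- Tm + .spd_logm(Mw %*% P %*% Mw)
    Tm <- Tm / length(matrices)
    resid <- .fnorm(Mh %*% Tm %*% Mh)   # mean ambient tangent displacement
    if (resid <= config$tolerance * scale) {
      attr(M, "iterations") <- iter - 1L
      return(M)
    }
    M <- .sym(Mh %*% .sym_expm(config$step * Tm) %*% Mh)
  }
  cond <- structure(
    class = c("riemi_mean_convergence_error", "error", "condition"),
    list(message = sprintf(
      "Karcher mean did not converge in %d iterations (residual %.3g, tolerance %.3g)",
      config$max_iterations, resid, config$tolerance * scale),
      call = sys.call(-1), last_iterate = M, residual = resid))
  stop(cond)
}

# ---- tangent-space vectorization -----------------------------------------

#' Half-vectorize a symmetric matrix (isometric weighting)
#'
#' Row-major scan of the upper triangle; diagonal entries unscaled,
#' off-diagonal entries multiplied by `sqrt(2)` so that the Euclidean norm
#' of the vector equals the Frobenius norm of the matrix.
#'
#' @param S Symmetric `n x n` matrix.
#' @return Numeric vector of length `n (n + 1) / 2`.
#' @export
upper_vectorize <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("`S` must be square", call. = FALSE)
  if (.fnorm(S - t(S)) > 1e-8 * max(.fnorm(S), 1)) {
    stop("`S` must be symmetric", call. = FALSE)
  }
  n <- nrow(S)
  out <- numeric(n * (n + 1) / 2)
  k <- 1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      out[k] <- if (i == j) S[i, j] else sqrt(2) * S[i, j]
      k <- k + 1L
    }
  }
  out
}

#' Invert [upper_vectorize()]
#'
#' @param v Numeric vector of length `n (n + 1) / 2`.
#' @param n Matrix dimension.
#' @return Symmetric `n x n` matrix.
#' @export
upper_unvectorize <- function(v, n) {
  if (length(v) != n * (n + 1) / 2) {
    stop(sprintf("length(v) = %d incompatible with n = %d", length(v), n), call. = FALSE)
  }
  S <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      val <- if (i == j) v[k] else v[k] / sqrt(2)
      S[i, j] <- val; S[j, i] <- val
      k <- k + 1L
    }
  }
  S
}

#' Map an SPD matrix to the tangent space at a reference point
#'
#' Computes `upper(log(ref^{-1/2} Pi ref^{-1/2}))`: the whitened log-map
#' coordinates of `Pi` at `reference`, half-vectorized with the isometric
#' `sqrt(2)` weighting. The Euclidean norm of the result equals
#' `riemannian_distance(reference, Pi)`, which is what makes Euclidean
#' classifiers in the tangent plane meaningful.
#'
#' @param reference SPD anchor (typically the Riemannian mean of the
#'   training set).
#' @param Pi SPD matrix to map.
#' @return Numeric vector of length `n (n + 1) / 2`.
#' @export
tangent_vectorize <- function(reference, Pi) {
  .check_spd(reference, "reference"); .check_spd(Pi, "Pi")
  .check_same_dim(reference, Pi)
  W <- .spd_isqrtm(reference)
  upper_vectorize(.spd_logm(W %*% Pi %*% W))
}

#' Reconstruct an SPD matrix from tangent coordinates
#'
#' Inverse of [tangent_vectorize()]: `ref^{1/2} exp(unvec(v)) ref^{1/2}`.
#'
#' @param reference SPD anchor.
#' @param v Tangent coordinate vector of length `n (n + 1) / 2`.
#' @return An SPD matrix.
#' @export
tangent_unvectorize <- function(reference, v) {
  .check_spd(reference, "reference")
  n <- nrow(reference)
  Ph <- .spd_sqrtm(reference)
  .sym(Ph %*% .sym_expm(upper_unvectorize(v, n)) %*% Ph)
}

#' Tangent-space feature matrix for a set of covariance matrices
#'
#' Convenience wrapper: maps every matrix in `covs` to the tangent space at
#' `reference` and stacks the coordinate vectors as rows.
#'
#' @param covs List of SPD matrices.
#' @param reference SPD anchor; defaults to the Riemannian mean of `covs`.
#' @return Matrix with `length(covs)` rows and `n (n + 1) / 2` columns, with
#'   attribute `"reference"`.
#' @export
tangent_features <- function(covs, reference = NULL) {
  if (is.null(reference)) reference <- riemannian_mean(covs)
  W <- .spd_isqrtm(reference)
  X <- t(vapply(covs, function(P) upper_vectorize(.spd_logm(W %*% P %*% W)),
                numeric(nrow(reference) * (nrow(reference) + 1) / 2)))
  attr(X, "reference") <- reference
  X
}
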