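# Shared fixtures: random SPD draws and small synthetic sets, all built in
# code with explicit seeds.

rand_spd <- function(n, scale = 1) {
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n + diag(scale, n)
}

rand_sym <- function(n) {
  A <- matrix(rnorm(n * n), n, n)
  (A + t(A)) / 2
}

# Fast covariance-only two-class draw: SPD matrices scattered around two
# class centers by congruence with near-identity factors.
two_class_covs <- function(n = 4, per_class = 15, spread = 0.1, gap = 1.5,
                           seed = 1) {
  withr::with_seed(seed, {
    base <- rand_spd(n)
    u <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
    centers <- list(base, base + gap * tcrossprod(u))
    covs <- list(); y <- character(0)
    for (c in 1:2) {
      for (i in seq_len(per_class)) {
        W <- diag(n) + spread * matrix(rnorm(n * n), n, n)
        covs[[length(covs) + 1L]] <- W %*% centers[[c]] %*% t(W)
        y <- c(y, sprintf("C%d", c))
      }
    }
    list(covs = covs, labels = factor(y), centers = centers)
  })
}

fnorm <- function(M) sqrt(sum(M^2))
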