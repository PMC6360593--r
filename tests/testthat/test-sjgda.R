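# Feature stack: discretization, mutual information, JMI ranking, length
# selection, polynomial kernel, GDA, and the SJGDA concatenation.

test_that("equal-frequency discretization balances bin counts", {
  d <- discretize_features(matrix(1:100, 100, 1), bins = 4)
  expect_equal(as.numeric(table(d$codes)), rep(25, 4))
  expect_warning(dc <- discretize_features(matrix(1, 50, 1), bins = 4), "constant")
  expect_true(all(dc$codes == 1L))
  withr::with_seed(1, x <- matrix(rnorm(800), 800, 1))
  dg <- discretize_features(x, bins = 8)
  counts <- as.numeric(table(dg$codes))
  expect_lte(max(counts) - min(counts), 1)
  # monotone map
  ord <- order(x[, 1])
  expect_true(all(diff(dg$codes[ord, 1]) >= 0))
})

test_that("mutual information: independence, self-information, hand oracle", {
  withr::with_seed(4, {
    a <- sample(0:1, 100000, replace = TRUE)
    b <- sample(0:1, 100000, replace = TRUE)
  })
  expect_lte(mutual_information(a, b), 0.01)
  z <- rep(c(1, 2, 2, 3), 25)
  H <- -sum(c(0.25, 0.5, 0.25) * log2(c(0.25, 0.5, 0.25)))
  expect_equal(mutual_information(z, z), H, tolerance = 1e-12)
  # 3x3 joint counts [[2,1,0],[1,3,1],[0,1,3]]: hand-computed plug-in MI
  a3 <- rep(1:3, times = c(3, 5, 4))
  b3 <- c(1, 1, 2,  1, 2, 2, 2, 3,  2, 3, 3, 3)
  expect_equal(mutual_information(a3, b3), 0.483355754981688, tolerance = 1e-12)
  expect_equal(mutual_information(a3, b3), mutual_information(b3, a3))
})

test_that("mutual information matches exact enumeration on tiny joint tables", {
  # all 2- and 3-symbol label assignments for up to 6 rows
  for (n in 3:6) {
    withr::with_seed(n, {
      for (rep in 1:20) {
        a <- sample(1:3, n, replace = TRUE)
        b <- sample(1:2, n, replace = TRUE)
        # direct enumeration of the empirical joint
        mi <- 0
        for (ia in unique(a)) for (ib in unique(b)) {
          p <- mean(a == ia & b == ib)
          if (p > 0) mi <- mi + p * log2(p / (mean(a == ia) * mean(b == ib)))
        }
        expect_equal(mutual_information(a, b), max(mi, 0), tolerance = 1e-12)
        expect_lte(mutual_information(a, b),
                   min(mutual_information(a, a), mutual_information(b, b)) + 1e-12)
      }
    })
  }
})

test_that("jmi_rank puts a planted relevant feature first", {
  withr::with_seed(6, {
    y <- factor(sample(c("a", "b"), 2000, replace = TRUE))
    X <- matrix(rnorm(2000 * 6), 2000, 6)
    X[, 4] <- as.numeric(y) + rnorm(2000, sd = 0.1)
  })
  r <- jmi_rank(X, y)
  expect_equal(r$feature[1], 4L)
})

test_that("jmi_rank matches exhaustive evaluation of the greedy criterion", {
  # independent oracle: re-evaluate the greedy recursion from scratch with
  # plain table()-based MI, including duplicated + complementary features
  withr::with_seed(66, {
    n <- 500
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    f1 <- as.numeric(y) + rnorm(n, sd = 0.5)
    X <- cbind(f1, f1 + rnorm(n, sd = 0.01), rnorm(n),
               as.numeric(y) * rnorm(n, sd = 1) + rnorm(n, sd = 0.3),
               rnorm(n), 0.5 * f1 + rnorm(n, sd = 0.8))
    colnames(X) <- NULL
  })
  r <- jmi_rank(X, y, bins = 4)
  codes <- discretize_features(X, bins = 4)$codes
  mi_tab <- function(z, y) {
    p <- table(z, y) / length(y)
    pz <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pz[i] * py[j]))
    }
    max(s, 0)
  }
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(k) mi_tab(codes[, k], y), numeric(1))
  sel <- which.max(rel)
  remaining <- setdiff(seq_len(p), sel)
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(k) {
      sum(vapply(sel, function(j) {
        mi_tab(paste(codes[, k], codes[, j]), y)
      }, numeric(1)))
    }, numeric(1))
    best <- remaining[which.max(scores)]
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
  }
  expect_equal(r$feature, sel)
})

test_that("semi-supervised path with empty unlabelled pool reduces to plain JMI", {
  withr::with_seed(7, {
    y <- factor(sample(c("a", "b", "c"), 300, replace = TRUE))
    X <- matrix(rnorm(300 * 5), 300, 5)
    X[, 2] <- X[, 2] + as.numeric(y)
  })
  r_plain <- jmi_rank(X, y, use_unlabelled = FALSE)
  r_semi <- jmi_rank(X, y, x_unlabelled = NULL, use_unlabelled = TRUE)
  expect_identical(r_plain$feature, r_semi$feature)
  expect_identical(r_plain$score, r_semi$score)
})

test_that("semi-supervised ranking still finds planted structure with unlabelled rows", {
  withr::with_seed(31, {
    y <- factor(sample(c("a", "b"), 400, replace = TRUE))
    X <- matrix(rnorm(400 * 5), 400, 5)
    X[, 3] <- X[, 3] + 2 * as.numeric(y)
    yu <- factor(sample(c("a", "b"), 200, replace = TRUE, prob = c(0.8, 0.2)))
    Xu <- matrix(rnorm(200 * 5), 200, 5)
    Xu[, 3] <- Xu[, 3] + 2 * as.numeric(yu)   # class-prior-change pool
  })
  r <- jmi_rank(X, y, x_unlabelled = Xu, use_unlabelled = TRUE)
  expect_equal(r$feature[1], 3L)
})

test_that("select_length recovers a planted dimensionality and honors ties", {
  withr::with_seed(8, {
    n <- 300
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 1:5] <- X[, 1:5] + 0.8 * (as.numeric(y) - 1.5)   # 5 informative
  })
  r <- jmi_rank(X, y)
  m <- select_length(X, y, r, knn_factory(5), grid = 1:20, folds = 5, seed = 8)
  expect_gte(m, 5L); expect_lte(m, 10L)
  cv <- attr(m, "cv")
  plateau <- max(cv$cv_accuracy)
  expect_gte(cv$cv_accuracy[cv$m == m], plateau - 0.02)
  # degenerate grids
  expect_equal(as.integer(select_length(X, y, r, knn_factory(5), grid = 20,
                                        folds = 3, seed = 1)), 20L)
  # all-noise features: flat accuracy, smallest grid value wins the tie
  withr::with_seed(9, Xn <- matrix(rnorm(200 * 10), 200, 10))
  yn <- factor(rep(c("a", "b"), each = 100))
  rn <- jmi_rank(Xn, yn)
  mn <- select_length(Xn, yn, rn, knn_factory(5), grid = c(2, 5, 8),
                      folds = 4, seed = 2)
  cvn <- attr(mn, "cv")
  expect_lte(max(cvn$cv_accuracy) - min(cvn$cv_accuracy), 0.15)
  expect_warning(select_length(Xn, yn, rn, knn_factory(5), grid = c(5, 40),
                               folds = 3, seed = 1), "dropped")
})

test_that("polynomial kernel matches its explicit feature map", {
  x <- c(1, 2); y <- c(3, -1)
  expect_equal(poly_kernel(x, y, degree = 1, coef0 = 0, scale = 1), sum(x * y))
  expect_equal(poly_kernel(rep(0, 4), rep(0, 4), degree = 7, coef0 = 1), 1)
  # degree-2 explicit map: [x_i x_j products, sqrt(2 c) x_i, c] with scale s
  withr::with_seed(12, { x <- rnorm(3); y <- rnorm(3) })
  s <- 1 / 3; c0 <- 1
  phi <- function(v) {
    q <- sqrt(s) * v
    c(as.numeric(outer(q, q)), sqrt(2 * c0) * q, sqrt(c0))
  }
  expect_equal(poly_kernel(x, y, degree = 2, coef0 = c0, scale = s),
               sum(phi(x) * phi(y)), tolerance = 1e-10)
})

test_that("gda separates linearly separable classes and flips sign under label swap", {
  withr::with_seed(14, {
    X <- matrix(rnorm(60 * 3, sd = 0.3), 60, 3)
    X[31:60, 1] <- X[31:60, 1] + 5
    y <- factor(rep(c("a", "b"), each = 30))
  })
  g <- gda_fit(X, y, degree = 1, coef0 = 0, scale = 1)
  proj <- gda_transform(g, X)
  # zero overlap: every class-a projection precedes every class-b projection
  expect_lt(max(proj[1:30, 1]), min(proj[31:60, 1]))
  g2 <- gda_fit(X, factor(y, levels = c("b", "a")), degree = 1, coef0 = 0, scale = 1)
  proj2 <- gda_transform(g2, X)
  expect_equal(abs(cor(proj[, 1], proj2[, 1])), 1, tolerance = 1e-6)
})

test_that("degree-2 kernel untangles XOR data where degree-1 cannot", {
  withr::with_seed(16, {
    n <- 40
    centers <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
    X <- centers[rep(1:4, each = n), ] + matrix(rnorm(4 * n * 2, sd = 0.2), 4 * n, 2)
    y <- factor(rep(c("same", "same", "diff", "diff"), each = n))
  })
  overlap <- function(p) {
    lo <- max(min(p[y == "same"]), min(p[y == "diff"]))
    hi <- min(max(p[y == "same"]), max(p[y == "diff"]))
    if (hi < lo) return(0)
    mean(p >= lo & p <= hi)
  }
  p2 <- gda_transform(gda_fit(X, y, degree = 2), X)[, 1]
  p1 <- gda_transform(gda_fit(X, y, degree = 1), X)[, 1]
  expect_lte(overlap(p2), 0.05)
  expect_gt(overlap(p1), 0.5)
})

test_that("gda_transform matches a naive double-loop kernel sum", {
  withr::with_seed(18, {
    X <- matrix(rnorm(40 * 4), 40, 4)
    y <- factor(rep(c("a", "b"), each = 20))
    Q <- matrix(rnorm(50 * 4), 50, 4)
  })
  g <- gda_fit(X, y, degree = 2, coef0 = 1, scale = 0.25)
  out <- gda_transform(g, Q)
  # training points project to the fitted values
  expect_equal(gda_transform(g, X[7, ]), gda_transform(g, X)[7, , drop = FALSE],
               tolerance = 1e-12)
  N <- nrow(X)
  kern <- function(u, v) (0.25 * sum(u * v) + 1)^2
  Ktr <- outer(seq_len(N), seq_len(N),
               Vectorize(function(i, j) kern(X[i, ], X[j, ])))
  for (q in 1:50) {
    kq <- vapply(seq_len(N), function(j) kern(Q[q, ], X[j, ]), numeric(1))
    kqc <- kq - mean(kq) - colMeans(Ktr) + mean(Ktr)
    expect_equal(out[q, 1], sum(kqc * g$alphas[, 1]), tolerance = 1e-10)
  }
})

test_that("gda projections are permutation invariant up to sign", {
  withr::with_seed(19, {
    X <- matrix(rnorm(30 * 3), 30, 3)
    X[16:30, 2] <- X[16:30, 2] + 2
    y <- factor(rep(c("a", "b"), each = 15))
    perm <- sample(30)
  })
  g1 <- gda_fit(X, y)
  g2 <- gda_fit(X[perm, ], y[perm])
  p1 <- gda_transform(g1, X)[, 1]
  p2 <- gda_transform(g2, X)[, 1]
  expect_lt(min(max(abs(p1 - p2)), max(abs(p1 + p2))), 1e-8)
})

test_that("sjgda: output layout, determinism, and duplicate-point consistency", {
  withr::with_seed(20, {
    X <- matrix(rnorm(120 * 15), 120, 15)
    X[, c(2, 9)] <- X[, c(2, 9)] + (as.numeric(factor(rep(c("a", "b"), each = 60))))
    y <- factor(rep(c("a", "b"), each = 60))
  })
  s1 <- sjgda_fit(X, y, grid = c(5, 10), folds = 4, seed = 3)
  expect_equal(ncol(sjgda_transform(s1, X)), s1$m + 1L)
  s2 <- sjgda_fit(X, y, grid = c(5, 10), folds = 4, seed = 3)
  expect_identical(sjgda_transform(s1, X), sjgda_transform(s2, X))
  # duplicated training point maps identically
  expect_equal(sjgda_transform(s1, X[3, ]), sjgda_transform(s1, X[3, ]))
  gl <- glance(s1)
  expect_equal(gl$output_length, s1$m + 1L)
})
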