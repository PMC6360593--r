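# MDRM, FGDA filtering, FGMDRM, KNN, and agreement metrics.

test_that("mdrm_fit recovers trivial class means", {
  withr::with_seed(1, { P <- rand_spd(3); Q <- rand_spd(3) })
  m <- mdrm_fit(list(P, Q), c("a", "b"))
  expect_equal(m$means$a, P, ignore_attr = TRUE)
  expect_equal(m$means$b, Q, ignore_attr = TRUE)
  m2 <- mdrm_fit(list(P, P, P, Q), c("a", "a", "a", "b"))
  expect_equal(m2$means$a, P, tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(mdrm_fit(list(P, Q), c("a", "a")), "2 classes")
})

test_that("mdrm class means match an independent Karcher flow", {
  dat <- two_class_covs(n = 4, per_class = 8, seed = 7)
  m <- mdrm_fit(dat$covs, dat$labels)
  # brute-force oracle: plain fixed-point iteration written out here
  for (cl in levels(dat$labels)) {
    mats <- dat$covs[dat$labels == cl]
    M <- Reduce(`+`, mats) / length(mats)
    for (it in 1:200) {
      e <- eigen(M, symmetric = TRUE)
      Mh <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
      Mw <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
      Tm <- matrix(0, 4, 4)
      for (P in mats) {
        C <- Mw %*% P %*% Mw
        ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
        Tm <- Tm + ec$vectors %*% diag(log(ec$values)) %*% t(ec$vectors)
      }
      Tm <- Tm / length(mats)
      if (fnorm(Tm) < 1e-12) break
      eT <- eigen((Tm + t(Tm)) / 2, symmetric = TRUE)
      M <- Mh %*% (eT$vectors %*% diag(exp(eT$values)) %*% t(eT$vectors)) %*% Mh
      M <- (M + t(M)) / 2
    }
    expect_equal(unclass(m$means[[cl]]), M, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("mdrm prediction: nearest mean, tie rule, congruence invariance", {
  withr::with_seed(2, { P <- rand_spd(3); Q <- rand_spd(3) })
  m <- mdrm_fit(list(P, Q), c("a", "b"))
  expect_equal(predict(m, P), "a")
  D <- predict(m, P, type = "distance")
  expect_equal(D[1, "a"], 0, tolerance = 1e-8, ignore_attr = TRUE)
  # equidistant tie -> first class in label order
  mt <- mdrm_fit(list(diag(c(2, 1)), diag(c(1, 2))), c("a", "b"))
  expect_message(p <- predict(mt, diag(2)), "tie")
  expect_equal(p, "a")
  # congruence applied to both model and query leaves decisions unchanged
  withr::with_seed(3, {
    dat <- two_class_covs(n = 3, per_class = 6, seed = 5)
    W <- matrix(rnorm(9), 3, 3)
    m1 <- mdrm_fit(dat$covs, dat$labels)
    m2 <- mdrm_fit(lapply(dat$covs, function(P) W %*% P %*% t(W)), dat$labels)
    q <- rand_spd(3)
    expect_equal(predict(m1, q), predict(m2, W %*% q %*% t(W)))
    expect_lt(max(abs(predict(m1, q, type = "distance") -
                      predict(m2, W %*% q %*% t(W), type = "distance"))), 1e-6)
  })
})

test_that("mdrm separates strongly separated synthetic classes", {
  cfg <- generator_config(n_channels = 6, trials_per_class = 30, classes = 2,
                          separation = 5, noise_df = 200, seed = 11,
                          trial_seconds = 1)
  dat <- generate_trials(cfg)
  covs <- lapply(dat$trials, compute_scm)
  acc <- riemi:::.cv_accuracy(covs, dat$labels, mdrm_factory(), folds = 5, seed = 1)
  expect_gte(acc, 0.95)
})

test_that("fgda finds axis-aligned discriminant directions", {
  withr::with_seed(10, {
    X <- matrix(rnorm(400 * 5, sd = 0.1), 400, 5)
    X[201:400, 2] <- X[201:400, 2] + 4      # classes differ only on axis 2
    y <- rep(c("a", "b"), each = 200)
  })
  f <- fgda_fit(X, y)
  expect_equal(f$r, 1L)
  expect_gte(abs(f$basis[2, 1]), 0.99)
  expect_equal(crossprod(f$basis), diag(1), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fgda leading eigenvalue collapses under label shuffling", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    X[21:40, 1] <- X[21:40, 1] + 3
    y <- rep(c("a", "b"), each = 20)
    ev_true <- fgda_fit(X, y)$eigenvalues[1]
    ev_perm <- replicate(20, fgda_fit(X, sample(y))$eigenvalues[1])
  })
  # structure present: observed eigenvalue far above every permuted one
  expect_gt(ev_true, max(ev_perm))
  # no structure: shuffled-label eigenvalue within the permuted null spread
  withr::with_seed(3, {
    ev_null <- fgda_fit(X, sample(sample(y)))$eigenvalues[1]
  })
  expect_lte(ev_null, max(ev_perm) * 1.5)
})

test_that("fgda_filter is a projector: identity at full rank, zero residual at r = 1", {
  dat <- two_class_covs(n = 3, per_class = 6, seed = 9)
  ref <- riemannian_mean(dat$covs)
  X <- tangent_features(dat$covs, ref)
  full <- fgda_fit(X, dat$labels, r = 6, reference = ref)
  P <- dat$covs[[4]]
  expect_equal(fgda_filter(full, P), P, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fgda_filter(full, ref), unclass(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
  f1 <- fgda_fit(X, dat$labels, r = 1, reference = ref)
  filt <- lapply(dat$covs, function(P) fgda_filter(f1, P))
  Xf <- tangent_features(filt, ref)
  resid <- Xf - Xf %*% f1$basis %*% t(f1$basis)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("fgmdrm with full r reproduces plain MDRM decisions", {
  dat <- two_class_covs(n = 3, per_class = 10, seed = 4)
  fg <- fgmdrm_fit(dat$covs, dat$labels, r = 6)
  md <- mdrm_fit(dat$covs, dat$labels)
  withr::with_seed(21, queries <- lapply(1:20, function(i) rand_spd(3)))
  expect_equal(predict(fg, queries), predict(md, queries))
})

test_that("fgmdrm does not degrade relative to MDRM on a 4-class problem", {
  cfg <- generator_config(n_channels = 6, trials_per_class = 40, classes = 4,
                          separation = 2, noise_df = 100, seed = 5,
                          trial_seconds = 1)
  dat <- generate_trials(cfg)
  covs <- lapply(dat$trials, compute_scm)
  tr <- rep(c(TRUE, FALSE), length.out = length(covs))  # alternate split
  fg <- fgmdrm_fit(covs[tr], dat$labels[tr])
  md <- mdrm_fit(covs[tr], dat$labels[tr])
  acc_fg <- accuracy_score(dat$labels[!tr], predict(fg, covs[!tr]))
  acc_md <- accuracy_score(dat$labels[!tr], predict(md, covs[!tr]))
  expect_gte(acc_fg, acc_md - 0.02)
})

test_that("knn: exact memorisation, margin case, brute-force agreement", {
  X <- matrix(c(0, 0, 1, 1, 10, 10), 3, 2, byrow = TRUE)
  m1 <- knn_fit(X, c("a", "a", "b"), k = 1)
  expect_equal(predict(m1, X[3, ]), "b")
  # two clusters at +-10 on one axis
  Xc <- rbind(matrix(c(-10, -10.5, -9.5), 3, 2), matrix(c(10, 10.5, 9.5), 3, 2))
  mc <- knn_fit(Xc, rep(c("neg", "pos"), each = 3), k = 3)
  expect_equal(predict(mc, c(9, 9)), "pos")
  expect_error(knn_fit(X, c("a", "a", "b"), k = 2), "odd")
  expect_error(knn_fit(X[0, , drop = FALSE], character(0)), "empty")
  # exhaustive-scan reference on random Gaussian data
  withr::with_seed(15, {
    Xtr <- matrix(rnorm(80 * 3), 80, 3)
    ytr <- factor(rep(c("a", "b"), each = 40))
    Xq <- matrix(rnorm(100 * 3), 100, 3)
  })
  model <- knn_fit(Xtr, ytr, k = 5)
  pred <- predict(model, Xq)
  for (i in 1:100) {
    d <- sqrt(colSums((t(Xtr) - Xq[i, ])^2))
    nn <- order(d)[1:5]
    votes <- sort(table(ytr[nn]), decreasing = TRUE)
    expected <- names(votes)[1]
    if (length(votes) > 1 && votes[1] == votes[2]) {
      sums <- tapply(d[nn], ytr[nn], sum)
      expected <- names(which.min(sums))
    }
    expect_equal(pred[i], expected)
  }
})

test_that("cohen_kappa: perfect, chance-level, hand-computed, symmetry", {
  y <- rep(c("a", "b", "c", "d"), each = 5)
  expect_equal(cohen_kappa(y, y), 1.0)
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "B", "B")), 0.5)
  withr::with_seed(1, {
    yt <- sample(1:4, 10000, replace = TRUE)
    yp <- sample(1:4, 10000, replace = TRUE)
  })
  expect_lte(abs(cohen_kappa(yt, yp)), 0.05)
  # relabeling both vectors consistently leaves kappa unchanged
  map <- c(a = "z", b = "y", c = "x", d = "w")
  yp2 <- rep(c("b", "a", "c", "d"), each = 5)
  expect_equal(cohen_kappa(y, yp2), cohen_kappa(map[y], map[yp2]))
  expect_warning(k0 <- cohen_kappa(c("a", "a"), c("a", "a")), "single class")
  expect_equal(k0, 0)
  expect_equal(accuracy_score(c(1, 2, 3), c(1, 2, 4)), 2 / 3)
})
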