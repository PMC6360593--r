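# Synthetic motor-imagery-like EEG trials whose class identity is carried by
# the spatial covariance matrix. The generator is the test bed standing in
# for real recordings: it emulates band-limited zero-mean multichannel
# trials with controllable between-class covariance separation, per-trial
# covariance jitter, and an optional unlabelled pool.

#' Configuration of the synthetic trial generator
#'
#' @param n_channels EEG channels (`>= 2`).
#' @param fs Sampling rate in Hz.
#' @param trial_seconds Epoch length in seconds (default 2, the paper's
#'   post-cue window).
#' @param classes Number of classes `C`.
#' @param trials_per_class Trials per class.
#' @param separation Scale of the class-specific rank-2 covariance
#'   perturbations; 0 makes all classes identically distributed. A vector
#'   of length `C` gives per-class scales (e.g. two well-separated and two
#'   overlapping classes).
#' @param noise_df Wishart degrees of freedom of the trial-to-trial
#'   covariance jitter; `Inf` disables jitter.
#' @param unlabelled_fraction Fraction of each class moved to the
#'   unlabelled pool (`0 <= f < 1`).
#' @param seed Integer seed; the whole draw is reproducible from it.
#' @param band Band-pass edges in Hz applied to the trials.
#' @param ar_rho Channel correlation decay of the base Toeplitz covariance.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_channels = 8L, fs = 250, trial_seconds = 2,
                             classes = 4L, trials_per_class = 100L,
                             separation = 1, noise_df = 200,
                             unlabelled_fraction = 0, seed = 1L,
                             band = c(8, 30), ar_rho = 0.3) {
  stopifnot(n_channels >= 2L, fs > 0, trial_seconds > 0, classes >= 1L,
            trials_per_class >= 1L, all(separation >= 0), noise_df > 0,
            unlabelled_fraction >= 0, unlabelled_fraction < 1)
  if (!length(separation) %in% c(1L, classes)) {
    stop("`separation` must be a scalar or one value per class", call. = FALSE)
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 trial_seconds = trial_seconds, classes = as.integer(classes),
                 trials_per_class = as.integer(trials_per_class),
                 separation = separation, noise_df = noise_df,
                 unlabelled_fraction = unlabelled_fraction,
                 seed = as.integer(seed), band = band, ar_rho = ar_rho),
            class = "generator_config")
}

#' Per-class ground-truth covariance matrices
#'
#' Builds a Toeplitz-correlated base covariance `Sigma0[i, j] =
#' ar_rho^|i - j|` and adds to each class a rank-2 positive semidefinite
#' perturbation `separation_c (u_c u_c' + v_c v_c')` with class-specific
#' orthonormal directions (mimicking class-specific spatial power
#' patterns). With `separation = 0` all classes share `Sigma0`.
#'
#' @param config A [generator_config()].
#' @return List of `C` SPD matrices.
#' @export
make_class_covariances <- function(config) {
  n <- config$n_channels; C <- config$classes
  sep <- rep_len(config$separation, C)
  sigma0 <- config$ar_rho^abs(outer(seq_len(n), seq_len(n), `-`))
  withr::with_seed(config$seed + 1000L, {
    dirs <- if (2L * C <= n) {
      Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
      lapply(seq_len(C), function(c) Q[, c(2L * c - 1L, 2L * c)])
    } else {
      lapply(seq_len(C), function(c) {
        qr.Q(qr(matrix(rnorm(n * 2L), n, 2L)))
      })
    }
  })
  lapply(seq_len(C), function(c) {
    U <- dirs[[c]]
    .sym(sigma0 + sep[c] * tcrossprod(U))
  })
}

#' Generate synthetic covariance-coded EEG trials
#'
#' For each trial of class `c` a trial covariance is drawn from a Wishart
#' distribution centered on the class covariance (`df = noise_df`), then
#' `Ts` i.i.d. zero-mean Gaussian samples are drawn with it and band-pass
#' filtered ([eeg_bandpass()]); the filtered data are rescaled by the
#' filter's white-noise power gain so the spatial covariance scale is
#' preserved. A per-class uniformly chosen `unlabelled_fraction` of trials
#' is moved to the unlabelled pool. Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Object of class `mi_trials`: list with `trials` (list of
#'   channels x `Ts` matrices), `labels` (factor, `NA` for unlabelled),
#'   `true_labels` (factor, complete), `fs`, `class_covariances`, `config`.
#' @export
generate_trials <- function(config) {
  n <- config$n_channels
  ts <- round(config$trial_seconds * config$fs)
  C <- config$classes
  cls_cov <- make_class_covariances(config)
  gain <- .bandpass_power_gain(config$fs, config$band[1], config$band[2])
  trials <- list(); y <- character(0)
  withr::with_seed(config$seed, {
    for (c in seq_len(C)) {
      for (t in seq_len(config$trials_per_class)) {
        Ct <- if (is.finite(config$noise_df)) {
          stats::rWishart(1L, config$noise_df, cls_cov[[c]] / config$noise_df)[, , 1L]
        } else cls_cov[[c]]
        X <- t(chol(.sym(Ct))) %*% matrix(rnorm(n * ts), n, ts)
        X <- eeg_bandpass(X, config$fs, config$band[1], config$band[2]) / sqrt(gain)
        trials[[length(trials) + 1L]] <- X
        y <- c(y, sprintf("C%d", c))
      }
    }
    y <- factor(y)
    labels <- y
    if (config$unlabelled_fraction > 0) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        hide <- sample(idx, floor(config$unlabelled_fraction * length(idx)))
        labels[hide] <- NA
      }
    }
  })
  structure(list(trials = trials, labels = labels, true_labels = y,
                 fs = config$fs, class_covariances = cls_cov, config = config),
            class = "mi_trials")
}

#' @export
print.mi_trials <- function(x, ...) {
  cat(sprintf("<mi_trials> %d trials, %d channels x %d samples, %d classes (%d unlabelled)\n",
              length(x$trials), nrow(x$trials[[1L]]), ncol(x$trials[[1L]]),
              nlevels(x$true_labels), sum(is.na(x$labels))))
  invisible(x)
}

#' Split a trial set into labelled and unlabelled parts
#'
#' @param x An `mi_trials` object.
#' @return List with `trials`, `labels` (labelled rows only) and
#'   `unlabelled_trials`.
#' @export
split_labelled <- function(x) {
  lab <- !is.na(x$labels)
  list(trials = x$trials[lab], labels = droplevels(x$labels[lab]),
       unlabelled_trials = x$trials[!lab])
}
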