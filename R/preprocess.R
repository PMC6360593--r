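# Band-pass filtering and cue-locked epoch extraction.

#' Butterworth band-pass filter for multichannel EEG
#'
#' Applies a Butterworth band-pass (prototype order `order`, default the
#' 5th-order 8-30 Hz motor-imagery band) to every channel. By default the
#' filter is run forward and backward (zero phase); `zero_phase = FALSE`
#' gives the causal single pass.
#'
#' @param x Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz (`0 < low < high < fs/2`).
#' @param order Butterworth prototype order (default 5).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return Filtered matrix of the same shape.
#' @export
eeg_bandpass <- function(x, fs, low = 8, high = 30, order = 5L, zero_phase = TRUE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop(sprintf("band [%g, %g] Hz infeasible at fs = %g Hz", low, high, fs),
         call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- x
  for (ch in seq_len(nrow(x))) {
    out[ch, ] <- if (zero_phase) signal::filtfilt(bf, x[ch, ])
                 else as.numeric(signal::filter(bf, x[ch, ]))
  }
  out
}

# White-noise power gain of the zero-phase band-pass (|H|^4 averaged over
# frequency); used by the synthetic generator to preserve covariance scale.
.bandpass_power_gain <- function(fs, low = 8, high = 30, order = 5L,
                                 zero_phase = TRUE, n_grid = 8192L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  H <- signal::freqz(bf, n = n_grid)$h
  pow <- if (zero_phase) abs(H)^4 else abs(H)^2
  mean(pow)
}

#' Extract cue-locked epochs from a continuous recording
#'
#' For each cue, returns the samples in the half-open window
#' `[cue + round(start * fs), cue + round(end * fs))` where `cue` is the
#' 0-based sample index of the event (so `Ts = round(end*fs) -
#' round(start*fs)`; with the defaults and `fs = 250` this is the paper's
#' 2 s / 500-sample epoch 0.5-2.5 s after the cue). Windows extending past
#' the recording are skipped with a message.
#'
#' @param x Continuous recording, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param cues Integer vector of 0-based cue sample indices.
#' @param start,end Window edges in seconds after the cue
#'   (`start < end`; defaults 0.5 and 2.5).
#' @return List of channels x `Ts` matrices, one per retained cue, with
#'   attribute `"kept"` giving the indices of cues that produced epochs.
#' @export
eeg_epoch <- function(x, fs, cues, start = 0.5, end = 2.5) {
  if (!is.matrix(x)) stop("`x` must be a channels x samples matrix", call. = FALSE)
  if (start >= end) stop("empty epoch window: `start` must be < `end`", call. = FALSE)
  i0 <- round(start * fs); i1 <- round(end * fs)
  ts <- i1 - i0
  out <- list(); kept <- integer(0)
  for (ci in seq_along(cues)) {
    a <- cues[ci] + i0   # 0-based first sample
    b <- cues[ci] + i1   # 0-based one-past-last
    if (a < 0 || b > ncol(x)) {
      message(sprintf("eeg_epoch: cue %d window [%d, %d) out of range; skipped",
                      ci, a, b))
      next
    }
    out[[length(out) + 1L]] <- x[, (a + 1L):b, drop = FALSE]
    kept <- c(kept, ci)
  }
  attr(out, "kept") <- kept
  attr(out, "Ts") <- ts
  out
}
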