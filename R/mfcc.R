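#' @name mfcc
#' @title Mel-frequency cepstral coefficients of signal frames
#'
#' @description
#' HTK-style MFCC recipe: first-order pre-emphasis, Hamming window,
#' magnitude FFT, a bank of 26 triangular mel filters spanning 0 Hz to
#' Nyquist applied to the power spectrum, floored log energies, and an
#' orthonormal DCT-II of which coefficients 1..12 are kept (the overall
#' energy term c0 is dropped). Dropping c0 makes the retained
#' coefficients invariant to a uniform gain applied to the waveform,
#' which keeps the model focused on spectral shape rather than recording
#' level.
#'
#' @param frames frame matrix from [frameSignal()] (one frame per column).
#' @param frame single numeric frame vector.
#' @param cfg a [pipelineConfig()]; uses `sample_rate`, `preemphasis`,
#'   `n_mel`, `n_mfcc`, `log_floor`.
#' @return `mfccFrames()`: an `n_frames` x `n_mfcc` matrix (columns
#'   `mfcc01`..`mfcc12`); `mfccFrame()`: a length-`n_mfcc` vector.
NULL

melScale <- function(f) 2595 * log10(1 + f / 700)
melScaleInv <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' @param n_fft FFT length (frame length in samples).
#' @param sample_rate sampling frequency in Hz.
#' @param n_mel number of triangular filters between 0 Hz and Nyquist.
#' @return An `n_mel` x `(n_fft/2 + 1)` weight matrix acting on the
#'   one-sided power spectrum.
#' @export
melFilterbank <- function(n_fft, sample_rate, n_mel = 26L) {
  n_bins <- n_fft %/% 2L + 1L
  bin_freq <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  edges <- melScaleInv(seq(0, melScale(sample_rate / 2), length.out = n_mel + 2L))
  fb <- matrix(0, nrow = n_mel, ncol = n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_freq - lo) / (mid - lo)
    down <- (hi - bin_freq) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II basis rows k = 1..n_mfcc over n_mel points (c0 excluded).
dctBasis <- function(n_mfcc, n_mel) {
  k <- seq_len(n_mfcc)
  m <- seq_len(n_mel)
  sqrt(2 / n_mel) * cos(pi * outer(k, (m - 0.5)) / n_mel)
}

#' @rdname mfcc
#' @export
mfccFrames <- function(frames, cfg = pipelineConfig()) {
  if (!is.matrix(frames)) frames <- matrix(frames, ncol = 1L)
  F <- nrow(frames)
  if (F < 2L) stop("frame length must be at least 2 samples", call. = FALSE)

  pre <- cfg$preemphasis
  emph <- frames
  emph[-1L, ] <- frames[-1L, , drop = FALSE] - pre * frames[-F, , drop = FALSE]
  emph[1L, ] <- frames[1L, ] * (1 - pre)

  window <- 0.54 - 0.46 * cos(2 * pi * (seq_len(F) - 1L) / (F - 1L))
  spec <- stats::mvfft(emph * window)
  power <- Mod(spec[seq_len(F %/% 2L + 1L), , drop = FALSE])^2

  fb <- melFilterbank(F, cfg$sample_rate, cfg$n_mel)
  log_energy <- log(pmax(fb %*% power, cfg$log_floor))
  coefs <- t(dctBasis(cfg$n_mfcc, cfg$n_mel) %*% log_energy)
  if (any(!is.finite(coefs)))
    stop("non-finite MFCC produced; check input samples", call. = FALSE)
  colnames(coefs) <- sprintf("mfcc%02d", seq_len(cfg$n_mfcc))
  coefs
}

#' @rdname mfcc
#' @export
mfccFrame <- function(frame, cfg = pipelineConfig()) {
  drop(mfccFrames(matrix(as.numeric(frame), ncol = 1L), cfg))
}
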