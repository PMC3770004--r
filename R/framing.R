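#' Cut a recording into overlapping frames
#'
#' Frames tile the signal from its first sample with a hop of
#' `frame_length * (1 - overlap)` samples; a trailing stretch shorter than
#' one frame is discarded rather than zero-padded, so no synthetic silence
#' enters the spectral analysis. With the default 2048-sample frame at
#' 44.1 kHz the frame duration is 46.4 ms and the hop 1024 samples.
#'
#' @param rec an `AudioRecording`, or a bare numeric sample vector.
#' @param cfg a [pipelineConfig()]; only `frame_length` and `overlap` are
#'   used.
#' @return A `frame_length` x `n_frames` numeric matrix, one frame per
#'   column, with the zero-based start sample of each frame in attribute
#'   `"starts"`.
#' @export
#' @examples
#' frames <- frameSignal(sin(2 * pi * 220 * (0:8191) / 44100) * 10000,
#'                       pipelineConfig())
#' ncol(frames)
frameSignal <- function(rec, cfg = pipelineConfig()) {
  x <- if (inherits(rec, "AudioRecording")) as.numeric(rec$samples) else as.numeric(rec)
  F <- cfg$frame_length
  H <- frameHop(cfg)
  L <- length(x)
  if (L < F)
    stop("recording too short: ", L, " samples < one frame window (", F,
         ")", call. = FALSE)
  n <- (L - F) %/% H + 1L
  starts <- (seq_len(n) - 1L) * H
  idx <- outer(seq_len(F), starts, `+`)
  frames <- matrix(x[idx], nrow = F, ncol = n)
  attr(frames, "starts") <- starts
  frames
}

#' Frame hop in samples
#' @inheritParams frameSignal
#' @return Integer hop length, `frame_length * (1 - overlap)` rounded.
#' @export
frameHop <- function(cfg = pipelineConfig()) {
  H <- as.integer(round(cfg$frame_length * (1 - cfg$overlap)))
  if (H < 1L) stop("overlap too large: hop would be < 1 sample", call. = FALSE)
  H
}

#' Frame duration in milliseconds
#' @inheritParams frameSignal
#' @return Frame length divided by sampling rate, in ms.
#' @export
frameDurationMs <- function(cfg = pipelineConfig()) {
  cfg$frame_length / cfg$sample_rate * 1000
}

#' Select valid (speech) frames by energy gating
#'
#' A frame is valid when its RMS amplitude clears both an adaptive
#' threshold — half the `vad_quantile` quantile of all frame RMS values —
#' and an absolute floor (`vad_floor` times 16-bit full scale). The
#' factor of one half leaves a margin below the quantile so that a
#' recording with uniform energy (every frame equally loud) is entirely
#' valid, while silent stretches, whose RMS sits orders of magnitude
#' lower, are still dropped.
#'
#' @param frames frame matrix from [frameSignal()].
#' @param cfg a [pipelineConfig()]; uses `vad_quantile` and `vad_floor`.
#' @param full_scale amplitude corresponding to digital full scale.
#' @return Logical vector, one entry per frame.
#' @export
detectValidFrames <- function(frames, cfg = pipelineConfig(),
                              full_scale = 32767) {
  if (ncol(frames) < 1L) stop("no frames supplied", call. = FALSE)
  rms <- sqrt(colMeans(frames^2))
  threshold <- max(0.5 * stats::quantile(rms, cfg$vad_quantile, names = FALSE),
                   cfg$vad_floor * full_scale)
  mask <- rms >= threshold
  if (sum(mask) < 2L)
    stop("insufficient speech: fewer than 2 valid frames detected",
         call. = FALSE)
  mask
}
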