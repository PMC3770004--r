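#' Append the relative time position to frame features
#'
#' The i-th of N valid frames (0-indexed) receives
#' `ts = i / (N - 1)`: the first valid frame of the sentence is at 0, the
#' last at 1, and positions are linear in between. `ts` anchors each
#' feature vector to the part of the sentence it came from, which is what
#' lets mixture components specialize along the time axis.
#'
#' @param features an `N` x 12 matrix of per-frame MFCCs (valid frames
#'   only, in temporal order).
#' @return An `N` x 13 matrix with an added final `ts` column.
#' @export
#' @examples
#' attachTs(matrix(0, nrow = 5, ncol = 12))[, "ts"]
attachTs <- function(features) {
  if (!is.matrix(features)) stop("features must be a matrix", call. = FALSE)
  n <- nrow(features)
  if (n < 2L)
    stop("insufficient speech: need at least 2 valid frames to place ts",
         call. = FALSE)
  ts <- (seq_len(n) - 1L) / (n - 1L)
  out <- cbind(features, ts = ts)
  if (is.null(colnames(features)))
    colnames(out) <- c(sprintf("mfcc%02d", seq_len(ncol(features))), "ts")
  out
}

#' Construct a recording feature object
#'
#' @param y an `N` x 13 matrix: 12 MFCC columns plus a final `ts` column
#'   that is non-decreasing with first value 0 and last value 1.
#' @param subject_id,gender,age subject metadata.
#' @param standardized logical; whether the MFCC columns have been
#'   age-standardized.
#' @return An object of class `RecordingFeatures`.
#' @export
recordingFeatures <- function(y, subject_id = NA_character_,
                              gender = NA_character_, age = NA_real_,
                              standardized = FALSE) {
  if (!is.matrix(y) || nrow(y) < 2L)
    stop("y must be a matrix with at least 2 rows", call. = FALSE)
  if (any(!is.finite(y))) stop("y contains non-finite values", call. = FALSE)
  ts <- y[, ncol(y)]
  if (is.unsorted(ts) || abs(ts[1L]) > 1e-12 || abs(ts[length(ts)] - 1) > 1e-12)
    stop("ts column must be non-decreasing from 0 to 1", call. = FALSE)
  obj <- list(y = y, subject_id = as.character(subject_id),
              gender = as.character(gender), age = as.numeric(age),
              n_valid_frames = nrow(y), standardized = isTRUE(standardized))
  class(obj) <- "RecordingFeatures"
  obj
}

#' @export
print.RecordingFeatures <- function(x, ...) {
  cat(sprintf("RecordingFeatures: %d valid frames x %d features%s\n",
              x$n_valid_frames, ncol(x$y),
              if (x$standardized) " (age-standardized)" else ""))
  cat(sprintf("  subject %s, %s, age %s\n", x$subject_id, x$gender,
              format(x$age)))
  invisible(x)
}

#' Extract the frame feature sequence of a recording
#'
#' Runs the full feature front end: framing, energy-based valid-frame
#' selection, per-frame MFCCs, and attachment of the relative time
#' position. The result is the 13-dimensional feature sequence that the
#' mixture models are trained on and score. Recordings whose sampling
#' rate differs from the configured one are rejected (the method is tied
#' to its acquisition protocol; no resampling is attempted).
#'
#' @param rec an `AudioRecording` from [readWav()].
#' @param cfg a [pipelineConfig()].
#' @return A `RecordingFeatures` object (not yet age-standardized).
#' @export
extractFeatures <- function(rec, cfg = pipelineConfig()) {
  stopifnot(inherits(rec, "AudioRecording"))
  if (rec$sample_rate != cfg$sample_rate)
    stop("recording sampled at ", rec$sample_rate, " Hz but the pipeline ",
         "expects ", cfg$sample_rate, " Hz; resampling is not supported",
         call. = FALSE)
  frames <- frameSignal(rec, cfg)
  mask <- detectValidFrames(frames, cfg)
  feats <- mfccFrames(frames[, mask, drop = FALSE], cfg)
  recordingFeatures(attachTs(feats), subject_id = rec$subject_id,
                    gender = rec$gender, age = rec$age)
}

#' Write extracted features to CSV for inspection
#'
#' One row per valid frame with columns `subject_id`, `frame_index`,
#' `ts`, `mfcc01`..`mfcc12`.
#'
#' @param features a `RecordingFeatures` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeaturesCsv <- function(features, path) {
  stopifnot(inherits(features, "RecordingFeatures"))
  y <- features$y
  k <- ncol(y) - 1L
  df <- data.frame(subject_id = features$subject_id,
                   frame_index = seq_len(nrow(y)),
                   ts = y[, "ts"],
                   y[, seq_len(k), drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
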