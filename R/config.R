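#' Pipeline configuration
#'
#' Bundles every tunable parameter of the feature extraction, model
#' training and classification pipeline. The defaults reproduce the
#' reference settings of the method: 2048-sample frames (46.4 ms at
#' 44.1 kHz) with 50\% overlap, 12 MFCCs from a 26-filter mel bank,
#' 15 Gaussian components per model, and a \eqn{\pm 5}-year age
#' standardization window.
#'
#' @param sample_rate expected sampling frequency in Hz; recordings at any
#'   other rate are rejected, never resampled.
#' @param frame_length frame window length in samples.
#' @param overlap fraction of overlap between neighboring frames, in
#'   `[0, 1)`; `0.5` gives a 1024-sample hop at the default frame length.
#' @param vad_quantile quantile of the per-frame RMS energies used as the
#'   speech/non-speech gate, in `[0, 1)`.
#' @param vad_floor absolute RMS floor for the gate, as a fraction of
#'   16-bit full scale. Frames must clear both the quantile and the floor.
#' @param preemphasis first-order pre-emphasis coefficient.
#' @param n_mel number of triangular mel filters (0 Hz to Nyquist).
#' @param n_mfcc number of cepstral coefficients kept (c1..c12; c0 dropped).
#' @param log_floor floor applied to mel filter energies before the log.
#' @param age_halfwidth half-width, in years, of the moving age window used
#'   to standardize coefficients.
#' @param M number of Gaussian components per mixture model.
#' @param covariance `"diagonal"` (default) or `"full"` component
#'   covariance structure.
#' @param em_tol EM stopping tolerance on the change in mean
#'   log-likelihood per frame.
#' @param em_max_iter maximum number of EM iterations.
#' @param var_floor lower bound for covariance diagonal entries.
#' @param seed integer seed for the (rare) deterministic re-seeding of
#'   collapsed components.
#' @param classes constitution class labels, in fixed decision order; this
#'   order also breaks likelihood ties.
#'
#' @return An object of class `PipelineConfig` (a validated list).
#' @seealso [loadConfig()], [configFingerprint()]
#' @export
#' @examples
#' cfg <- pipelineConfig()
#' cfg$frame_length / cfg$sample_rate * 1000  # frame duration, ms
pipelineConfig <- function(sample_rate = 44100,
                           frame_length = 2048L,
                           overlap = 0.5,
                           vad_quantile = 0.1,
                           vad_floor = 1e-4,
                           preemphasis = 0.97,
                           n_mel = 26L,
                           n_mfcc = 12L,
                           log_floor = 1e-10,
                           age_halfwidth = 5,
                           M = 15L,
                           covariance = c("diagonal", "full"),
                           em_tol = 1e-6,
                           em_max_iter = 200L,
                           var_floor = 1e-6,
                           seed = 0L,
                           classes = c("TE", "SE", "SY")) {
  covariance <- match.arg(covariance)
  cfg <- list(
    sample_rate = as.numeric(sample_rate),
    frame_length = as.integer(frame_length),
    overlap = as.numeric(overlap),
    vad_quantile = as.numeric(vad_quantile),
    vad_floor = as.numeric(vad_floor),
    preemphasis = as.numeric(preemphasis),
    n_mel = as.integer(n_mel),
    n_mfcc = as.integer(n_mfcc),
    log_floor = as.numeric(log_floor),
    age_halfwidth = as.numeric(age_halfwidth),
    M = as.integer(M),
    covariance = covariance,
    em_tol = as.numeric(em_tol),
    em_max_iter = as.integer(em_max_iter),
    var_floor = as.numeric(var_floor),
    seed = as.integer(seed),
    classes = as.character(classes)
  )
  class(cfg) <- "PipelineConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (!is.finite(cfg$sample_rate) || cfg$sample_rate <= 0)
    fail("sample_rate must be a positive number")
  if (is.na(cfg$frame_length) || cfg$frame_length < 2L)
    fail("frame_length must be at least 2 samples")
  if (!is.finite(cfg$overlap) || cfg$overlap < 0 || cfg$overlap >= 1)
    fail("overlap must lie in [0, 1)")
  if (!is.finite(cfg$vad_quantile) || cfg$vad_quantile < 0 || cfg$vad_quantile >= 1)
    fail("vad_quantile must lie in [0, 1)")
  if (!is.finite(cfg$vad_floor) || cfg$vad_floor < 0)
    fail("vad_floor must be non-negative")
  if (!is.finite(cfg$preemphasis) || cfg$preemphasis < 0 || cfg$preemphasis >= 1)
    fail("preemphasis must lie in [0, 1)")
  if (is.na(cfg$n_mel) || cfg$n_mel < cfg$n_mfcc + 1L)
    fail("n_mel must exceed n_mfcc")
  if (is.na(cfg$n_mfcc) || cfg$n_mfcc < 1L)
    fail("n_mfcc must be at least 1")
  if (!is.finite(cfg$log_floor) || cfg$log_floor <= 0)
    fail("log_floor must be positive")
  if (!is.finite(cfg$age_halfwidth) || cfg$age_halfwidth < 0)
    fail("age_halfwidth must be non-negative")
  if (is.na(cfg$M) || cfg$M < 1L)
    fail("M must be at least 1")
  if (!is.finite(cfg$em_tol) || cfg$em_tol <= 0)
    fail("em_tol must be positive")
  if (is.na(cfg$em_max_iter) || cfg$em_max_iter < 1L)
    fail("em_max_iter must be at least 1")
  if (!is.finite(cfg$var_floor) || cfg$var_floor <= 0)
    fail("var_floor must be positive")
  if (length(cfg$classes) < 2L || anyDuplicated(cfg$classes))
    fail("classes must be at least two distinct labels")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Unknown keys are rejected with an explicit message; missing keys fall
#' back to the defaults of [pipelineConfig()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top level is
#'   a mapping of [pipelineConfig()] argument names to values.
#' @return A `PipelineConfig` object.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  values <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be YAML or JSON, got .", ext, call. = FALSE)
  }
  if (is.null(values)) values <- list()
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(values), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, values)
}

#' Fingerprint of the feature-affecting configuration
#'
#' A model bank is only applicable to features extracted under the exact
#' frame/MFCC/standardization settings it was trained with. The
#' fingerprint is a canonical string of those settings; it is stored in
#' the bank and compared at classification time.
#'
#' @param cfg a `PipelineConfig`.
#' @return A single character string.
#' @export
configFingerprint <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  keys <- c("sample_rate", "frame_length", "overlap", "vad_quantile",
            "vad_floor", "preemphasis", "n_mel", "n_mfcc", "log_floor",
            "age_halfwidth")
  paste(vapply(keys, function(k) {
    paste0(k, "=", format(cfg[[k]], digits = 17, scientific = FALSE))
  }, character(1)), collapse = ";")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  frames     : %d samples (%.1f ms at %g Hz), %.0f%% overlap\n",
              x$frame_length, x$frame_length / x$sample_rate * 1000,
              x$sample_rate, x$overlap * 100))
  cat(sprintf("  features   : %d MFCCs (%d mel filters) + ts\n",
              x$n_mfcc, x$n_mel))
  cat(sprintf("  model      : M = %d, %s covariance\n", x$M, x$covariance))
  cat(sprintf("  age window : +/- %g years\n", x$age_halfwidth))
  cat(sprintf("  classes    : %s\n", paste(x$classes, collapse = " < ")))
  invisible(x)
}
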