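#' Train the full model bank
#'
#' Fits the age standardizer on all training recordings, standardizes
#' them, pools frames per (gender, class) group — both sentence takes of
#' a subject, when present, contribute — and fits one mixture model per
#' group. A complete bank for a gender holds one model per class; a
#' gender's recordings may be absent, in which case that gender simply
#' cannot be classified.
#'
#' @param recordings list of unstandardized `RecordingFeatures` with
#'   gender and age metadata.
#' @param labels character vector of constitution labels, one per
#'   recording, each one of `cfg$classes`.
#' @param cfg a [pipelineConfig()].
#' @return An object of class `ModelBank`: per-(gender, class) mixture
#'   models, the shared `AgeStandardizer`, the class order and the
#'   feature-configuration fingerprint.
#' @export
fitModelBank <- function(recordings, labels, cfg = pipelineConfig()) {
  stopifnot(length(recordings) == length(labels), length(recordings) >= 1L)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), cfg$classes)
  if (length(bad) > 0L)
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)

  std <- fitAgeStandardizer(recordings, cfg$age_halfwidth)
  standardized <- lapply(recordings, standardizeFeatures, std = std)
  genders <- vapply(standardized, function(r) r$gender, character(1))

  models <- list()
  for (g in unique(genders)) {
    present <- intersect(cfg$classes, labels[genders == g])
    if (!setequal(present, cfg$classes))
      warning("gender '", g, "' is missing class(es) ",
              paste(setdiff(cfg$classes, present), collapse = ", "),
              "; that gender cannot be classified", call. = FALSE)
    models[[g]] <- list()
    for (cls in present) {
      group <- standardized[genders == g & labels == cls]
      models[[g]][[cls]] <- fitGmm(group, cfg)
      models[[g]][[cls]]$n_subjects <-
        length(unique(vapply(group, function(r) r$subject_id, character(1))))
    }
  }

  bank <- list(schema_version = 1L, models = models, standardizer = std,
               classes = cfg$classes, config = cfg,
               fingerprint = configFingerprint(cfg))
  class(bank) <- "ModelBank"
  bank
}

#' @export
print.ModelBank <- function(x, ...) {
  cat("ModelBank (schema", x$schema_version, ")\n")
  for (g in names(x$models))
    cat(sprintf("  %s: %s\n", g, paste(names(x$models[[g]]), collapse = ", ")))
  cat("  classes:", paste(x$classes, collapse = " < "), "\n")
  invisible(x)
}

bankModelsFor <- function(bank, gender) {
  models <- bank$models[[gender]]
  if (is.null(models))
    stop("model bank has no models for gender '", gender, "'", call. = FALSE)
  missing <- setdiff(bank$classes, names(models))
  if (length(missing) > 0L)
    stop("model bank for gender '", gender, "' is missing class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  models[bank$classes]
}

#' Classify a recording by maximum normalized likelihood
#'
#' Standardizes the recording with the bank's age standardizer (unless
#' it already is), sums the per-frame mixture log-densities under each
#' class model to get per-class total log-likelihoods, and normalizes
#' across classes in the log domain: `pi_k = exp(L_k - logsumexp(L))`.
#' The predicted class is the arg-max of `pi`; exact ties are broken by
#' the fixed class order with a warning. With three classes the decision
#' confidence `max_k pi_k` is always at least 1/3.
#'
#' @param features a `RecordingFeatures` object.
#' @param bank a `ModelBank` covering the recording's gender.
#' @return An object of class `DiagnosisResult`: `posterior` (named
#'   probability vector), `predicted`, `confidence`, `loglik` (named
#'   per-class total log-likelihoods), `n_frames`.
#' @export
classifyRecording <- function(features, bank) {
  stopifnot(inherits(features, "RecordingFeatures"),
            inherits(bank, "ModelBank"))
  models <- bankModelsFor(bank, features$gender)
  if (!isTRUE(features$standardized))
    features <- standardizeFeatures(features, bank$standardizer)
  if (features$n_valid_frames < 1L)
    stop("insufficient speech: no valid frames to classify", call. = FALSE)

  L <- vapply(models, function(m) sum(mixtureLogPdf(features$y, m)),
              numeric(1))
  posterior <- exp(L - logSumExp(L))
  posterior <- posterior / sum(posterior)
  top <- which(posterior >= max(posterior) - 1e-12)
  if (length(top) > 1L)
    warning("likelihood tie between classes ",
            paste(bank$classes[top], collapse = ", "),
            "; picking the first in class order", call. = FALSE)
  h <- bank$classes[top[1L]]
  res <- list(posterior = posterior, predicted = h,
              confidence = unname(max(posterior)), loglik = L,
              subject_id = features$subject_id, n_frames = features$n_valid_frames)
  class(res) <- "DiagnosisResult"
  res
}

#' @export
print.DiagnosisResult <- function(x, ...) {
  cat("DiagnosisResult:", x$predicted,
      sprintf("(confidence %.3f)\n", x$confidence))
  print(round(x$posterior, 4))
  invisible(x)
}

gmmToJsonList <- function(gmm) {
  out <- list(weights = gmm$weights, means = gmm$means,
              covariance = gmm$covariance,
              n_frames = gmm$n_frames, n_subjects = gmm$n_subjects,
              em_iterations = gmm$em_iterations,
              final_log_likelihood = gmm$final_log_likelihood)
  if (identical(gmm$covariance, "full")) {
    out$covs <- lapply(seq_len(dim(gmm$covs)[3L]), function(j) gmm$covs[, , j])
  } else {
    out$vars <- gmm$vars
  }
  out
}

gmmFromJsonList <- function(x) {
  means <- as.matrix(x$means)
  full <- identical(x$covariance, "full")
  d <- ncol(means)
  covs <- NULL
  vars <- NULL
  if (full) {
    covs <- array(0, dim = c(d, d, length(x$covs)))
    for (j in seq_along(x$covs)) covs[, , j] <- as.matrix(x$covs[[j]])
    vars <- t(apply(covs, 3L, diag))
  } else {
    vars <- as.matrix(x$vars)
  }
  newGmm(as.numeric(x$weights), means, vars, covs, x$covariance,
         meta = list(n_frames = x$n_frames, n_subjects = x$n_subjects,
                     em_iterations = x$em_iterations,
                     final_log_likelihood = x$final_log_likelihood))
}

#' Save or load a model bank as JSON
#'
#' Parameters are written at full double precision so that a loaded bank
#' reproduces classification posteriors exactly. A `schema_version`
#' field is checked on load.
#'
#' @param bank a `ModelBank`.
#' @param path JSON file path.
#' @return `saveModelBank()` returns `path` invisibly; `loadModelBank()`
#'   returns the reconstructed `ModelBank`.
#' @export
saveModelBank <- function(bank, path) {
  stopifnot(inherits(bank, "ModelBank"))
  payload <- list(
    schema_version = bank$schema_version,
    fingerprint = bank$fingerprint,
    classes = bank$classes,
    config = unclass(bank$config),
    standardizer = list(halfwidth = bank$standardizer$halfwidth,
                        tables = bank$standardizer$tables),
    models = lapply(bank$models, function(g) lapply(g, gmmToJsonList))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelBank
#' @export
loadModelBank <- function(path) {
  if (!file.exists(path)) stop("model bank not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("failed to parse model bank JSON: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(payload$schema_version) || payload$schema_version != 1L)
    stop("unsupported model bank schema version: ",
         format(payload$schema_version), call. = FALSE)

  std <- list(tables = lapply(payload$standardizer$tables, function(tab)
    list(ages = as.numeric(tab$ages), mean = as.matrix(tab$mean),
         sd = as.matrix(tab$sd))),
    halfwidth = payload$standardizer$halfwidth)
  class(std) <- "AgeStandardizer"

  cfg_args <- payload$config
  cfg <- do.call(pipelineConfig, cfg_args)

  models <- lapply(payload$models, function(g) lapply(g, gmmFromJsonList))

  bank <- list(schema_version = 1L, models = models, standardizer = std,
               classes = as.character(payload$classes), config = cfg,
               fingerprint = payload$fingerprint)
  class(bank) <- "ModelBank"
  bank
}
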