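#' Per-subject diagnostic stability
#'
#' Summarizes repeated classifications of one subject. The majority
#' class is the modal prediction (ties broken by class order, with a
#' warning); repeatability is the percentage of tests agreeing with it.
#' The decision confidence of each test is its maximum normalized class
#' probability, and its mean and sample standard deviation (denominator
#' `R - 1`) complete the stability picture: a stable diagnosis shows
#' high repeatability and a low confidence SD.
#'
#' @param results list of `DiagnosisResult` from repeated tests of the
#'   same subject against the same bank.
#' @param classes class order used for tie-breaking.
#' @return An object of class `SubjectStability`: `subject_id`,
#'   `n_tests`, `majority_class`, `repeatability` (percent),
#'   `probability_mean`, `probability_sd`.
#' @export
subjectStability <- function(results, classes = c("TE", "SE", "SY")) {
  if (length(results) < 1L) stop("no test results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "DiagnosisResult")))
  decisions <- vapply(results, function(r) r$predicted, character(1))
  confidences <- vapply(results, function(r) r$confidence, numeric(1))
  counts <- table(factor(decisions, levels = classes))
  top <- which(counts == max(counts))
  if (length(top) > 1L)
    warning("majority tie between classes ",
            paste(names(counts)[top], collapse = ", "),
            "; picking the first in class order", call. = FALSE)
  majority <- names(counts)[top[1L]]
  R <- length(results)
  out <- list(subject_id = results[[1L]]$subject_id, n_tests = R,
              majority_class = majority,
              repeatability = 100 * sum(decisions == majority) / R,
              probability_mean = mean(confidences),
              probability_sd = if (R > 1L) stats::sd(confidences) else NA_real_)
  class(out) <- "SubjectStability"
  out
}

#' @export
print.SubjectStability <- function(x, ...) {
  cat(sprintf("SubjectStability %s: %s in %.1f%% of %d tests, confidence %.3f +/- %.3f\n",
              x$subject_id, x$majority_class, x$repeatability, x$n_tests,
              x$probability_mean, x$probability_sd))
  invisible(x)
}

#' Aggregate per-subject stability rows into a report
#'
#' Builds the cross-subject stability table: one row per subject plus an
#' `Average` row holding the unweighted arithmetic mean of each column.
#' All values are kept at full precision; [formatStabilityReport()]
#' applies the conventional display rounding (repeatability to 1
#' decimal, probabilities to 3).
#'
#' @param rows list of `SubjectStability` objects, or a data frame with
#'   columns `subject`, `repeatability_pct`, `prob_mean`, `prob_sd`.
#' @return A `RepeatabilityReport`: a data frame of the same columns
#'   whose last row is the `Average`.
#' @export
aggregateReport <- function(rows) {
  df <- if (is.data.frame(rows)) {
    needed <- c("subject", "repeatability_pct", "prob_mean", "prob_sd")
    missing <- setdiff(needed, names(rows))
    if (length(missing) > 0L)
      stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
    rows[needed]
  } else {
    stopifnot(length(rows) >= 1L,
              all(vapply(rows, inherits, logical(1), "SubjectStability")))
    data.frame(subject = vapply(rows, function(r) r$subject_id, character(1)),
               repeatability_pct = vapply(rows, function(r) r$repeatability, numeric(1)),
               prob_mean = vapply(rows, function(r) r$probability_mean, numeric(1)),
               prob_sd = vapply(rows, function(r) r$probability_sd, numeric(1)))
  }
  if (nrow(df) < 1L) stop("no stability rows supplied", call. = FALSE)
  avg <- data.frame(subject = "Average",
                    repeatability_pct = mean(df$repeatability_pct),
                    prob_mean = mean(df$prob_mean),
                    prob_sd = mean(df$prob_sd))
  out <- rbind(df, avg)
  rownames(out) <- NULL
  class(out) <- c("RepeatabilityReport", "data.frame")
  out
}

#' @rdname aggregateReport
#' @param report a `RepeatabilityReport`.
#' @export
formatStabilityReport <- function(report) {
  stopifnot(inherits(report, "RepeatabilityReport"))
  data.frame(subject = report$subject,
             repeatability_pct = round(report$repeatability_pct, 1),
             prob_mean = round(report$prob_mean, 3),
             prob_sd = round(report$prob_sd, 3))
}

#' @export
print.RepeatabilityReport <- function(x, ...) {
  print(formatStabilityReport(x))
  invisible(x)
}

#' Classification accuracy against expert labels
#'
#' @param results list of `DiagnosisResult`.
#' @param truth character vector of true class labels, one per result.
#' @param genders optional character vector of genders, one per result;
#'   when given, per-gender accuracies are reported too.
#' @return A list with `overall` (percent) and, when genders are given,
#'   `by_gender` (named percent vector), plus counts.
#' @export
diagnosisAccuracy <- function(results, truth, genders = NULL) {
  stopifnot(length(results) == length(truth), length(results) >= 1L)
  predicted <- vapply(results, function(r) r$predicted, character(1))
  correct <- predicted == as.character(truth)
  out <- list(overall = 100 * mean(correct), n = length(correct))
  if (!is.null(genders)) {
    stopifnot(length(genders) == length(results))
    out$by_gender <- vapply(split(correct, genders),
                            function(z) 100 * mean(z), numeric(1))
  }
  out
}

#' Per-subject stability of the features themselves
#'
#' For each subject with repeated recordings, the sample standard
#' deviation across recordings of the per-recording mean of each
#' (standardized) MFCC. Low values indicate that the sentence features
#' are intrinsically stable for a speaker, independent of any
#' classifier.
#'
#' @param repeated named list: one entry per subject, each a list of at
#'   least two `RecordingFeatures` of that subject.
#' @return A data frame with one row per subject and one column per
#'   MFCC.
#' @export
featureStabilityTable <- function(repeated) {
  stopifnot(length(repeated) >= 1L)
  rows <- lapply(names(repeated), function(subj) {
    recs <- repeated[[subj]]
    if (length(recs) < 2L)
      stop("subject '", subj, "' needs at least 2 recordings", call. = FALSE)
    k <- ncol(recs[[1L]]$y) - 1L
    means <- t(vapply(recs, function(r) colMeans(r$y[, seq_len(k), drop = FALSE]),
                      numeric(k)))
    sds <- apply(means, 2L, stats::sd)
    data.frame(subject = subj, t(sds), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reference stability table
#'
#' Per-subject stability values (repeatability percent, confidence mean
#' and SD over 50 repeated tests of each of 10 subjects) as published
#' for two voice diagnosis methods: the earlier baseline built on
#' averaged vowel-and-sentence features, and the frame-level sentence
#' GMM method this package implements. Shipped as reference constants
#' for comparison and for exercising [aggregateReport()]; the baseline
#' method itself is out of scope and is never recomputed here.
#'
#' @return A data frame with columns `subject`, `method`
#'   (`"averaged_baseline"` or `"frame_gmm"`), `repeatability_pct`,
#'   `prob_mean`, `prob_sd`.
#' @export
referenceStabilityTable <- function() {
  path <- system.file("extdata", "stability_reference.csv",
                      package = "scvoice", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
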