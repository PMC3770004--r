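#' Fit the moving age-window standardizer
#'
#' Voice spectra drift with age, so raw MFCCs confound constitution with
#' age. Each coefficient is therefore z-scored against statistics local
#' to the speaker's age: for every gender, coefficient and integer age
#' `a` present in the training set, the mean and standard deviation are
#' computed over all frame values pooled across training subjects whose
#' age lies within `a +/- halfwidth` years. Frames are the pooling unit
#' because frames are the analysis unit throughout the pipeline.
#'
#' @param recordings list of `RecordingFeatures` (unstandardized) with
#'   gender and age metadata.
#' @param halfwidth age window half-width in years.
#' @return An object of class `AgeStandardizer`: per-gender tables of
#'   window means and SDs indexed by integer age.
#' @export
fitAgeStandardizer <- function(recordings, halfwidth = 5) {
  stopifnot(length(recordings) >= 1L)
  genders <- vapply(recordings, function(r) r$gender, character(1))
  ages <- vapply(recordings, function(r) r$age, numeric(1))
  if (any(is.na(genders)) || any(is.na(ages)))
    stop("every training recording needs gender and age metadata",
         call. = FALSE)
  if (any(vapply(recordings, function(r) isTRUE(r$standardized), logical(1))))
    stop("training recordings are already standardized", call. = FALSE)

  tables <- list()
  for (g in unique(genders)) {
    idx <- which(genders == g)
    g_ages <- round(ages[idx])
    cover <- sort(unique(g_ages))
    k <- ncol(recordings[[idx[1L]]]$y) - 1L
    mean_tab <- matrix(NA_real_, nrow = length(cover), ncol = k)
    sd_tab <- matrix(NA_real_, nrow = length(cover), ncol = k)
    for (ai in seq_along(cover)) {
      a <- cover[ai]
      in_window <- idx[abs(g_ages - a) <= halfwidth]
      if (length(in_window) < 2L)
        stop("standardizer fit failed: fewer than 2 ", g,
             " training subjects within +/-", halfwidth, " years of age ", a,
             call. = FALSE)
      pooled <- do.call(rbind, lapply(recordings[in_window],
                                      function(r) r$y[, seq_len(k), drop = FALSE]))
      mu <- colMeans(pooled)
      sig <- apply(pooled, 2L, stats::sd)
      bad <- which(!is.finite(sig) | sig <= 0)
      if (length(bad) > 0L)
        stop("standardizer fit failed: zero variance for ", g, ", age ", a,
             ", coefficient ", bad[1L], call. = FALSE)
      mean_tab[ai, ] <- mu
      sd_tab[ai, ] <- sig
    }
    tables[[g]] <- list(ages = cover, mean = mean_tab, sd = sd_tab)
  }
  std <- list(tables = tables, halfwidth = halfwidth)
  class(std) <- "AgeStandardizer"
  std
}

#' @export
print.AgeStandardizer <- function(x, ...) {
  cat(sprintf("AgeStandardizer: +/- %g year window\n", x$halfwidth))
  for (g in names(x$tables))
    cat(sprintf("  %s: ages %d-%d (%d covered)\n", g,
                min(x$tables[[g]]$ages), max(x$tables[[g]]$ages),
                length(x$tables[[g]]$ages)))
  invisible(x)
}

lookupAgeRow <- function(std, gender, age) {
  tab <- std$tables[[gender]]
  if (is.null(tab))
    stop("standardizer has no table for gender '", gender, "'", call. = FALSE)
  if (is.na(age)) stop("recording has no age metadata", call. = FALSE)
  # Out-of-range or uncovered ages clamp to the nearest covered age.
  which.min(abs(tab$ages - round(age)))
}

#' Age-standardize (or invert) a recording's MFCCs
#'
#' Each MFCC value is replaced by `(value - mean) / sd` using the window
#' statistics at the nearest covered integer age for the recording's
#' gender; `ts` is left untouched. `destandardizeFeatures()` applies the
#' exact inverse map.
#'
#' @param features a `RecordingFeatures` object.
#' @param std a fitted `AgeStandardizer`.
#' @return A `RecordingFeatures` object with transformed MFCC columns.
#' @export
standardizeFeatures <- function(features, std) {
  stopifnot(inherits(features, "RecordingFeatures"),
            inherits(std, "AgeStandardizer"))
  if (isTRUE(features$standardized))
    stop("features are already standardized", call. = FALSE)
  row <- lookupAgeRow(std, features$gender, features$age)
  tab <- std$tables[[features$gender]]
  k <- ncol(features$y) - 1L
  y <- features$y
  y[, seq_len(k)] <- sweep(sweep(y[, seq_len(k), drop = FALSE], 2L,
                                 tab$mean[row, ]), 2L, tab$sd[row, ], `/`)
  out <- features
  out$y <- y
  out$standardized <- TRUE
  out
}

#' @rdname standardizeFeatures
#' @export
destandardizeFeatures <- function(features, std) {
  stopifnot(inherits(features, "RecordingFeatures"),
            inherits(std, "AgeStandardizer"))
  if (!isTRUE(features$standardized))
    stop("features are not standardized", call. = FALSE)
  row <- lookupAgeRow(std, features$gender, features$age)
  tab <- std$tables[[features$gender]]
  k <- ncol(features$y) - 1L
  y <- features$y
  y[, seq_len(k)] <- sweep(sweep(y[, seq_len(k), drop = FALSE], 2L,
                                 tab$sd[row, ], `*`), 2L, tab$mean[row, ], `+`)
  out <- features
  out$y <- y
  out$standardized <- FALSE
  out
}
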