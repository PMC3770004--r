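#' Synthetic class generators
#'
#' Builds one generator per (gender, class) pair, each describing a known
#' 13-dimensional mixture over (12 pseudo-MFCC features, time position):
#' `M_true` components with strictly increasing time centers spanning
#' `[0, 1]`, equal weights, unit feature variances, and class mean
#' vectors displaced from a common base by `separation` along mutually
#' orthogonal directions of feature space. `separation = 0` makes the
#' three classes of a gender statistically identical (chance-level
#' classification); a separation of several feature SDs makes them
#' essentially separable. Each generator also carries the acoustic
#' parameters used by [synthSentenceWav()]: a class-dependent fundamental
#' frequency (lowest for the baritone TE type, highest for the
#' high-pitched SY type, scaled up for female voices) and a spectral
#' tilt.
#'
#' These generators exist because the clinical recordings are not
#' public: they emulate the statistical structure the method assumes, at
#' feature level for exact oracles and at waveform level to exercise the
#' audio front end. No claim of clinical realism is made.
#'
#' @param separation displacement of each class mean from the common
#'   base, in feature-SD units.
#' @param seed integer seed; the same seed always yields identical
#'   generators.
#' @param M_true number of mixture components per generator.
#' @param intra_sd SD of the within-subject, per-recording feature noise.
#' @param subject_sd SD of the per-subject mean offset.
#' @param classes class labels.
#' @return Nested list `gens[[gender]][[class]]` of `ClassGenerator`
#'   objects.
#' @export
makeClassGenerators <- function(separation = 3, seed = 0, M_true = 5L,
                                intra_sd = 0.3, subject_sd = 0.5,
                                classes = c("TE", "SE", "SY")) {
  stopifnot(separation >= 0, M_true >= 1L, length(classes) == 3L)
  withr::with_seed(as.integer(seed), {
    directions <- qr.Q(qr(matrix(stats::rnorm(12L * 3L), 12L, 3L)))
    base_f0 <- c(110, 150, 210)  # TE low baritone, SE middle, SY high-pitched
    tilt <- c(0.7, 0.5, 0.25)    # heavier lowpass = darker timbre
    ts_mean <- (seq_len(M_true) - 0.5) / M_true
    ts_sd <- rep(0.6 / M_true, M_true)
    # Mild component-specific structure so the mixture is not a single blob.
    comp_shift <- matrix(stats::rnorm(M_true * 12L, sd = 0.5), M_true, 12L)
    gens <- list()
    for (g in c("male", "female")) {
      base <- rep(0, 12L)
      if (g == "female") base[1L] <- base[1L] + 1
      gens[[g]] <- list()
      for (k in seq_along(classes)) {
        mu_class <- base + separation * directions[, k]
        means <- sweep(comp_shift, 2L, mu_class, `+`)
        gen <- list(sc_class = classes[k], gender = g, M_true = M_true,
                    weights = rep(1 / M_true, M_true),
                    means = means,
                    vars = matrix(1, M_true, 12L),
                    ts_mean = ts_mean, ts_sd = ts_sd,
                    intra_sd = intra_sd, subject_sd = subject_sd,
                    f0 = base_f0[k] * if (g == "female") 1.6 else 1,
                    tilt = tilt[k])
        class(gen) <- "ClassGenerator"
        gens[[g]][[classes[k]]] <- gen
      }
    }
    gens
  })
}

#' @export
print.ClassGenerator <- function(x, ...) {
  cat(sprintf("ClassGenerator: %s %s, %d components, f0 %g Hz\n",
              x$gender, x$sc_class, x$M_true, x$f0))
  invisible(x)
}

#' Draw a per-subject feature offset
#'
#' @param gen a `ClassGenerator`.
#' @param seed integer seed.
#' @return A length-12 offset vector with SD `gen$subject_sd`.
#' @export
sampleSubjectOffset <- function(gen, seed) {
  withr::with_seed(as.integer(seed),
                   stats::rnorm(12L, sd = gen$subject_sd))
}

# P(component | ts) for every row of a ts grid: proportional to
# w_j * N(ts | ts_mean_j, ts_sd_j^2).
conditionalComponentProbs <- function(gen, ts) {
  dens <- vapply(seq_len(gen$M_true), function(j) {
    gen$weights[j] * stats::dnorm(ts, gen$ts_mean[j], gen$ts_sd[j])
  }, numeric(length(ts)))
  dens <- matrix(dens, nrow = length(ts))
  dens / rowSums(dens)
}

#' Sample a frame feature sequence from a class generator
#'
#' Time positions are the deterministic grid `i / (n_frames - 1)`. For
#' each frame a component is drawn with probability proportional to
#' `w_j * N(ts | ts_mean_j, ts_sd_j^2)` — the generator's conditional
#' component law given the frame's position — and the 12 features are
#' drawn from that component's Gaussian, shifted by the subject offset,
#' plus within-subject noise of SD `gen$intra_sd`.
#'
#' @param gen a `ClassGenerator`.
#' @param n_frames number of frames (at least 2); sentence recordings
#'   typically carry well over a hundred valid frames.
#' @param subject_offset length-12 per-subject mean shift (default none).
#' @param seed integer seed.
#' @param subject_id,age metadata for the resulting object.
#' @return A `RecordingFeatures` object; the sampled component index per
#'   frame is kept in element `components`.
#' @export
sampleRecordingFeatures <- function(gen, n_frames = 150L,
                                    subject_offset = rep(0, 12L),
                                    seed = 0L, subject_id = "synthetic",
                                    age = 35) {
  stopifnot(inherits(gen, "ClassGenerator"), n_frames >= 2L,
            length(subject_offset) == 12L)
  withr::with_seed(as.integer(seed), {
    ts <- (seq_len(n_frames) - 1L) / (n_frames - 1L)
    probs <- conditionalComponentProbs(gen, ts)
    comp <- vapply(seq_len(n_frames), function(i) {
      sample.int(gen$M_true, 1L, prob = probs[i, ])
    }, integer(1))
    x <- gen$means[comp, , drop = FALSE] +
      matrix(stats::rnorm(n_frames * 12L), n_frames, 12L) *
        sqrt(gen$vars[comp, , drop = FALSE]) +
      matrix(stats::rnorm(n_frames * 12L, sd = gen$intra_sd), n_frames, 12L)
    x <- sweep(x, 2L, subject_offset, `+`)
    colnames(x) <- sprintf("mfcc%02d", seq_len(12L))
    out <- recordingFeatures(cbind(x, ts = ts), subject_id = subject_id,
                             gender = gen$gender, age = age)
    out$components <- comp
    out
  })
}

#' Synthesize a sentence-like waveform
#'
#' Writes (or returns) a mono 16-bit 44.1 kHz recording made of voiced
#' segments separated by short pauses. Each voiced segment is a sawtooth
#' source at the generator's class-dependent fundamental frequency (with
#' a slight declination and per-segment jitter), shaped by a one-pole
#' spectral-tilt filter and two formant resonators, under a raised-cosine
#' amplitude envelope. Pauses are digital silence, so the energy gate of
#' [detectValidFrames()] separates them cleanly from the voiced parts.
#' The output is an abstract voiced/pause sequence, not speech in any
#' language: the method is language-agnostic at the feature level.
#'
#' @param gen a `ClassGenerator`.
#' @param duration_s total duration in seconds (at least 1).
#' @param subject_offset scalar log-F0 offset for the synthetic speaker.
#' @param seed integer seed.
#' @param path optional output WAV path; when given the file is written.
#' @param subject_id,age metadata for the returned recording.
#' @return An `AudioRecording` (invisibly when `path` is given).
#' @export
synthSentenceWav <- function(gen, duration_s = 3, subject_offset = 0,
                             seed = 0L, path = NULL,
                             subject_id = "synthetic", age = 35) {
  stopifnot(inherits(gen, "ClassGenerator"), duration_s >= 1)
  sr <- 44100
  withr::with_seed(as.integer(seed), {
    voiced_len <- round(0.45 * sr)
    pause_len <- round(0.15 * sr)
    total <- round(duration_s * sr)
    x <- numeric(0)
    x <- c(x, numeric(pause_len))
    while (length(x) + voiced_len + pause_len <= total) {
      f0 <- gen$f0 * exp(subject_offset + stats::rnorm(1L, sd = 0.02))
      # Declining pitch contour over the segment, as in natural phrases.
      f0_t <- f0 * seq(1.05, 0.95, length.out = voiced_len)
      phase <- cumsum(f0_t) / sr
      saw <- 2 * (phase %% 1) - 1
      a <- gen$tilt
      y <- stats::filter((1 - a) * saw, a, method = "recursive")
      for (fmt in list(c(700, 110), c(1220, 120))) {
        r <- exp(-pi * fmt[2L] / sr)
        theta <- 2 * pi * fmt[1L] / sr
        y <- stats::filter(y, c(2 * r * cos(theta), -r^2), method = "recursive")
      }
      y <- as.numeric(y)
      ramp <- round(0.02 * sr)
      env <- c((1 - cos(pi * seq_len(ramp) / ramp)) / 2,
               rep(1, voiced_len - 2L * ramp),
               (1 + cos(pi * seq_len(ramp) / ramp)) / 2)
      y <- y * env
      y <- y / max(abs(y)) * 0.3 * 32767
      x <- c(x, y, numeric(pause_len))
    }
    if (length(x) < total) x <- c(x, numeric(total - length(x)))
    rec <- audioRecording(round(x), sr, subject_id = subject_id,
                          gender = gen$gender, age = age)
    if (!is.null(path)) {
      writeWav(rec$samples, sr, path)
      invisible(rec)
    } else {
      rec
    }
  })
}

#' Repeated recordings of one synthetic subject
#'
#' Generates `R` feature-level recordings of a single subject for the
#' repeatability protocol: all share the subject's offset, and each gets
#' fresh within-subject noise of SD `intra_sd`. With `intra_sd = 0`
#' there is no within-subject variation at all and the recordings are
#' exact repeats, so any bank classifies them identically.
#'
#' @param gen a `ClassGenerator`.
#' @param subject_offset length-12 subject offset vector.
#' @param R number of repeated recordings.
#' @param n_frames frames per recording.
#' @param intra_sd within-subject noise SD (overrides the generator's).
#' @param seed integer seed.
#' @param subject_id,age metadata.
#' @return List of `R` `RecordingFeatures`.
#' @export
makeRepeatabilityTestSet <- function(gen, subject_offset = rep(0, 12L),
                                     R = 50L, n_frames = 150L,
                                     intra_sd = gen$intra_sd, seed = 0L,
                                     subject_id = "synthetic", age = 35) {
  stopifnot(R >= 1L)
  gen$intra_sd <- intra_sd
  lapply(seq_len(R), function(r) {
    rec_seed <- if (intra_sd > 0) as.integer(seed) + r else as.integer(seed)
    sampleRecordingFeatures(gen, n_frames = n_frames,
                            subject_offset = subject_offset, seed = rec_seed,
                            subject_id = subject_id, age = age)
  })
}

# Evenly spread integer ages over [lo, hi]; guarantees that every
# +/- halfwidth window is populated once spacing <= halfwidth.
spreadAges <- function(n, lo = 15, hi = 60) {
  round(seq(lo, hi, length.out = max(n, 2L)))[seq_len(n)]
}

#' Sample a feature-level synthetic cohort
#'
#' Draws `n_subjects` per (gender, class) with per-subject offsets,
#' `recordings_per_subject` recordings each, frame counts uniform in
#' `frames_range`, and ages evenly spread over `age_range` (so the
#' moving-window standardizer is always fittable). This is the fast,
#' exact-oracle route through the pipeline: features are drawn directly
#' from the known generators, skipping the waveform stage.
#'
#' @param gens generators from [makeClassGenerators()].
#' @param n_subjects subjects per (gender, class).
#' @param recordings_per_subject recordings per subject.
#' @param frames_range integer range for the per-recording frame count.
#' @param age_range age range in years.
#' @param genders genders to include.
#' @param seed integer seed.
#' @return A list with `recordings` (list of `RecordingFeatures`),
#'   `labels`, `genders`, `subjects` (parallel vectors).
#' @export
sampleCohortFeatures <- function(gens, n_subjects = 10L,
                                 recordings_per_subject = 1L,
                                 frames_range = c(100L, 300L),
                                 age_range = c(15, 60),
                                 genders = names(gens), seed = 0L) {
  stopifnot(n_subjects >= 1L, recordings_per_subject >= 1L)
  seed <- as.integer(seed)
  recordings <- list()
  labels <- character(0)
  gender_v <- character(0)
  subjects <- character(0)
  counter <- 0L
  for (g in genders) {
    classes <- names(gens[[g]])
    # Interleave ages across classes so age never confounds class; the
    # age-window standardizer would otherwise absorb the class signal.
    ages <- spreadAges(n_subjects * length(classes),
                       age_range[1L], age_range[2L])
    for (cls in classes) {
      gen <- gens[[g]][[cls]]
      k_i <- match(cls, classes)
      for (s in seq_len(n_subjects)) {
        si <- (s - 1L) * length(classes) + k_i
        counter <- counter + 1L
        subj <- sprintf("%s_%s_%02d", g, cls, s)
        offset <- sampleSubjectOffset(gen, seed + 7919L * counter)
        age <- ages[si]
        n_frames <- withr::with_seed(seed + 7919L * counter + 1L, {
          sample(seq(frames_range[1L], frames_range[2L]), 1L)
        })
        for (r in seq_len(recordings_per_subject)) {
          rec <- sampleRecordingFeatures(
            gen, n_frames = n_frames, subject_offset = offset,
            seed = seed + 7919L * counter + 13L * r,
            subject_id = subj, age = age)
          recordings[[length(recordings) + 1L]] <- rec
          labels <- c(labels, cls)
          gender_v <- c(gender_v, g)
          subjects <- c(subjects, subj)
        }
      }
    }
  }
  list(recordings = recordings, labels = labels, genders = gender_v,
       subjects = subjects)
}

#' Simulate a waveform-level cohort on disk
#'
#' Writes one WAV per (subject, take) plus a `metadata.csv` (columns
#' `subject_id`, `path`, `gender`, `age`, `label`) compatible with the
#' `train` command. Ages are evenly spread over 15-60 years per gender;
#' each subject contributes two sentence takes by default.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects subjects per (gender, class).
#' @param recordings_per_subject takes per subject.
#' @param duration_s duration of each take in seconds.
#' @param separation class separation passed to [makeClassGenerators()].
#' @param seed integer seed.
#' @param genders genders to include.
#' @return The metadata data frame, invisibly.
#' @export
simulateCohort <- function(dir, n_subjects = 4L, recordings_per_subject = 2L,
                           duration_s = 3, separation = 3, seed = 0L,
                           genders = c("male", "female")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gens <- makeClassGenerators(separation = separation, seed = seed)
  seed <- as.integer(seed)
  rows <- list()
  counter <- 0L
  for (g in genders) {
    classes <- names(gens[[g]])
    # Ages interleaved across classes, as in sampleCohortFeatures().
    ages <- spreadAges(n_subjects * length(classes))
    for (cls in classes) {
      gen <- gens[[g]][[cls]]
      k_i <- match(cls, classes)
      for (s in seq_len(n_subjects)) {
        si <- (s - 1L) * length(classes) + k_i
        counter <- counter + 1L
        subj <- sprintf("%s_%s_%02d", g, cls, s)
        f0_offset <- withr::with_seed(seed + 104729L * counter,
                                      stats::rnorm(1L, sd = 0.05))
        for (r in seq_len(recordings_per_subject)) {
          wav <- file.path(dir, sprintf("%s_take%d.wav", subj, r))
          synthSentenceWav(gen, duration_s = duration_s,
                           subject_offset = f0_offset,
                           seed = seed + 104729L * counter + r,
                           path = wav, subject_id = subj, age = ages[si])
          rows[[length(rows) + 1L]] <-
            data.frame(subject_id = subj, path = wav, gender = g,
                       age = ages[si], label = cls)
        }
      }
    }
  }
  meta <- do.call(rbind, rows)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
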