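test_that("generators are pure functions of their seed", {
  g1 <- makeClassGenerators(separation = 2, seed = 99)
  g2 <- makeClassGenerators(separation = 2, seed = 99)
  expect_identical(g1, g2)
  g3 <- makeClassGenerators(separation = 2, seed = 100)
  expect_false(identical(g1, g3))
  # Class mean displacements are orthogonal with the requested length.
  base <- g1$male
  d12 <- base$SE$means[1, ] - base$TE$means[1, ]
  d13 <- base$SY$means[1, ] - base$TE$means[1, ]
  expect_equal(sum(d12 * d13), sum(d12 * d12) / 2, tolerance = 1e-9)
  expect_equal(sqrt(sum(d12^2)), 2 * sqrt(2), tolerance = 1e-9)
})

test_that("sampled recordings have the deterministic ts grid and seed behavior", {
  gens <- makeClassGenerators(separation = 1, seed = 5)
  gen <- gens$female$SE
  f <- sampleRecordingFeatures(gen, n_frames = 2, seed = 1)
  expect_equal(unname(f$y[, "ts"]), c(0, 1))
  a <- sampleRecordingFeatures(gen, n_frames = 50, seed = 7)
  b <- sampleRecordingFeatures(gen, n_frames = 50, seed = 7)
  expect_identical(a$y, b$y)
  gen0 <- gen
  gen0$intra_sd <- 0
  r1 <- sampleRecordingFeatures(gen0, n_frames = 50, seed = 7)
  r2 <- sampleRecordingFeatures(gen0, n_frames = 50, seed = 7)
  expect_identical(r1$y, r2$y)
})

test_that("component occupancy follows the conditional time law", {
  gens <- makeClassGenerators(separation = 0, seed = 2)
  gen <- gens$male$TE
  n <- 1e5
  f <- sampleRecordingFeatures(gen, n_frames = n, seed = 11)
  ts <- f$y[, "ts"]
  analytic <- colMeans(scvoice:::conditionalComponentProbs(gen, ts))
  empirical <- tabulate(f$components, gen$M_true) / n
  expect_true(all(abs(empirical - analytic) < 0.02))
})

test_that("synthetic sentences parse as mono 16-bit 44.1 kHz with real pauses", {
  gens <- makeClassGenerators(separation = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".wav")
  synthSentenceWav(gens$male$TE, duration_s = 2, seed = 3, path = path)
  rec <- readWav(path, gender = "male", age = 30)
  expect_equal(rec$sample_rate, 44100)
  expect_equal(rec$channels, 1L)
  expect_equal(rec$bit_depth, 16L)
  expect_length(rec$samples, 2 * 44100)

  cfg <- pipelineConfig()
  frames <- frameSignal(rec, cfg)
  mask <- detectValidFrames(frames, cfg)
  rms <- sqrt(colMeans(frames^2))
  expect_false(any(mask[rms == 0]))   # pure-pause frames invalid
  expect_true(all(mask[rms > 2000]))  # voiced frames valid
  expect_true(any(mask) && any(!mask))
})

test_that("low and high pitched classes differ in end-to-end MFCCs", {
  gens <- makeClassGenerators(separation = 0, seed = 6)  # same feature law
  cfg <- pipelineConfig()
  meanMfcc <- function(gen, seed) {
    rec <- synthSentenceWav(gen, duration_s = 1.5, seed = seed)
    colMeans(extractFeatures(rec, cfg)$y[, 1:12])
  }
  n_per <- 8
  low <- t(vapply(1:n_per, function(i) meanMfcc(gens$male$TE, i), numeric(12)))
  high <- t(vapply(1:n_per, function(i) meanMfcc(gens$male$SY, 100 + i),
                   numeric(12)))
  stat <- function(a, b) sqrt(sum((colMeans(a) - colMeans(b))^2))
  observed <- stat(low, high)
  pooled <- rbind(low, high)
  perms <- withr::with_seed(44, {
    vapply(1:199, function(i) {
      idx <- sample(nrow(pooled), n_per)
      stat(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE])
    }, numeric(1))
  })
  p_value <- (1 + sum(perms >= observed)) / 200
  expect_lt(p_value, 0.01)
})

test_that("repeatability test sets behave at the noise extremes", {
  world <- separatedWorld()
  gen <- world$gens$male$TE
  offset <- sampleSubjectOffset(gen, 5)

  # Zero within-subject variation: identical recordings, perfect repeats.
  fixed <- makeRepeatabilityTestSet(gen, offset, R = 20, intra_sd = 0,
                                    seed = 7)
  expect_identical(fixed[[1]]$y, fixed[[20]]$y)
  res <- lapply(fixed, classifyRecording, bank = world$bank)
  st <- subjectStability(res)
  expect_equal(st$repeatability, 100)
  expect_equal(st$probability_sd, 0)

  # Same seed reproduces the whole set.
  again <- makeRepeatabilityTestSet(gen, offset, R = 20, intra_sd = 0,
                                    seed = 7)
  expect_identical(lapply(fixed, `[[`, "y"), lapply(again, `[[`, "y"))
})

test_that("a boundary subject loses repeatability and confidence", {
  # A subject sitting exactly on the decision boundary of a symmetric
  # bank: class models differ only by small equidistant mean offsets, so
  # each repeated recording tips the decision by sampling noise alone.
  delta <- 0.05
  bank <- miniBank(c(TE = -delta, SE = delta, SY = 0))
  bank$models$male$SY$means[1, 1] <- 0
  bank$models$male$SY$means[1, 2] <- delta  # equidistant on another axis
  results <- lapply(1:40, function(r) {
    f <- randomFeatures(n = 60, seed = 7000 + r)
    suppressWarnings(classifyRecording(f, bank))
  })
  st <- suppressWarnings(subjectStability(results))
  expect_lt(st$repeatability, 100)
  expect_gte(st$probability_mean, 1 / 3)
  expect_lt(st$probability_mean, 0.7)
  expect_gt(st$probability_sd, 0)
})

test_that("the cohort simulator writes a trainable corpus", {
  dir <- withr::local_tempdir()
  meta <- simulateCohort(dir, n_subjects = 4, recordings_per_subject = 1,
                         duration_s = 2, separation = 2, seed = 14,
                         genders = "female")
  meta_disk <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta_disk), 12L)  # 4 subjects x 3 classes x 1 take
  expect_true(all(file.exists(meta_disk$path)))
  expect_setequal(unique(meta_disk$label), c("TE", "SE", "SY"))
  expect_true(all(meta_disk$age >= 15 & meta_disk$age <= 60))
  # Determinism: same seed, same bytes.
  dir2 <- withr::local_tempdir()
  simulateCohort(dir2, n_subjects = 4, recordings_per_subject = 1,
                 duration_s = 2, separation = 2, seed = 14,
                 genders = "female")
  f1 <- file.path(dir, basename(meta_disk$path[1]))
  f2 <- file.path(dir2, basename(meta_disk$path[1]))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
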