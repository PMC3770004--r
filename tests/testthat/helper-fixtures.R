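# Shared fixtures, built in code. Heavy objects (a trained bank) are
# memoized so the suite pays for them once.

.fixture_cache <- new.env(parent = emptyenv())

# A pure tone at int16 amplitude (the pipeline works on PCM-scale samples).
toneSamples <- function(freq = 220, duration = 1, sr = 44100, amp = 10000) {
  amp * sin(2 * pi * freq * (seq_len(round(duration * sr)) - 1) / sr)
}

toneRecording <- function(freq = 220, duration = 1, sr = 44100, amp = 10000,
                          gender = "female", age = 30) {
  audioRecording(round(toneSamples(freq, duration, sr, amp)), sr,
                 subject_id = "tone", gender = gender, age = age)
}

# Random valid RecordingFeatures without going through audio.
randomFeatures <- function(n = 40, seed = 1, gender = "male", age = 30,
                           standardized = TRUE) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 12), n, 12)
    colnames(x) <- sprintf("mfcc%02d", 1:12)
    f <- recordingFeatures(cbind(x, ts = (seq_len(n) - 1) / (n - 1)),
                           subject_id = "rand", gender = gender, age = age)
    f$standardized <- standardized
    f
  })
}

# Well-separated synthetic world with a trained single-gender bank.
separatedWorld <- function() {
  if (is.null(.fixture_cache$world)) {
    cfg <- pipelineConfig()
    gens <- makeClassGenerators(separation = 5, seed = 11)
    train <- sampleCohortFeatures(gens, n_subjects = 10, genders = "male",
                                  seed = 12)
    bank <- fitModelBank(train$recordings, train$labels, cfg)
    .fixture_cache$world <- list(cfg = cfg, gens = gens, train = train,
                                 bank = bank)
  }
  .fixture_cache$world
}

# Minimal hand-built single-component diagonal GMM (13-d).
miniGmm <- function(mean1 = 0, weight = 1) {
  mu <- matrix(0, 1, 13)
  mu[1, 1] <- mean1
  scvoice:::newGmm(weights = weight, means = mu,
                   vars = matrix(1, 1, 13), covs = NULL,
                   covariance = "diagonal")
}

# Hand-built bank of single-component models; features must already be
# standardized when classified against it.
miniBank <- function(mean1_by_class = c(TE = 0, SE = 0, SY = 0),
                     cfg = pipelineConfig()) {
  models <- lapply(mean1_by_class, miniGmm)
  bank <- list(schema_version = 1L,
               models = list(male = models),
               standardizer = NULL,
               classes = names(mean1_by_class),
               config = cfg,
               fingerprint = configFingerprint(cfg))
  class(bank) <- "ModelBank"
  bank
}

fakeResult <- function(predicted, confidence = 0.5, subject = "s1") {
  out <- list(posterior = NULL, predicted = predicted,
              confidence = confidence, loglik = NULL,
              subject_id = subject, n_frames = 100L)
  class(out) <- "DiagnosisResult"
  out
}

# Independent full-matrix multivariate normal log-density (test oracle).
oracleMvnLogPdf <- function(y, mu, sigma) {
  d <- length(mu)
  centered <- y - mu
  -0.5 * d * log(2 * pi) - 0.5 * determinant(sigma, logarithm = TRUE)$modulus -
    0.5 * drop(crossprod(centered, solve(sigma, centered)))
}

# Brute-force frame start enumerator (test oracle).
oracleFrameStarts <- function(L, F, H) {
  starts <- integer(0)
  s <- 0L
  while (s + F <= L) {
    starts <- c(starts, s)
    s <- s + H
  }
  starts
}
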