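test_that("normalized class probabilities obey their contracts", {
  world <- separatedWorld()
  withr::with_seed(31, {
    for (i in 1:20) {
      gen <- world$gens$male[[sample(names(world$gens$male), 1)]]
      f <- sampleRecordingFeatures(gen, n_frames = sample(50:200, 1),
                                   subject_offset = rnorm(12, sd = 0.5),
                                   seed = i, age = sample(20:55, 1))
      res <- classifyRecording(f, world$bank)
      expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
      expect_true(all(res$posterior >= 0))
      expect_gte(res$confidence, 1 / 3 - 1e-12)
      expect_equal(res$predicted,
                   world$bank$classes[which.max(res$posterior)])
    }
  })
})

test_that("symmetric likelihoods give the uniform posterior and a tie warning", {
  bank <- miniBank(c(TE = 0, SE = 0, SY = 0))
  f <- randomFeatures(n = 10, seed = 2)
  expect_warning(res <- classifyRecording(f, bank), "tie")
  expect_equal(unname(res$posterior), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(res$confidence, 1 / 3, tolerance = 1e-12)
  expect_equal(res$predicted, "TE")  # first in class order
})

test_that("a 2:1:1 likelihood ratio yields posterior (0.5, 0.25, 0.25)", {
  # Models differ only in the first coordinate mean; the recording sits
  # at 0 there, so each frame contributes delta^2/2 to the TE advantage.
  # Two frames, each contributing delta^2/2, give L = (log 2, 0, 0) + const
  # when delta = sqrt(log 2).
  delta <- sqrt(log(2))
  bank <- miniBank(c(TE = 0, SE = delta, SY = delta))
  y <- matrix(0, 2, 13)
  y[, 13] <- c(0, 1)
  f <- recordingFeatures(y, gender = "male", age = 30)
  f$standardized <- TRUE
  res <- suppressWarnings(classifyRecording(f, bank))
  expect_equal(res$loglik[["TE"]] - res$loglik[["SE"]], log(2),
               tolerance = 1e-12)
  expect_equal(unname(res$posterior), c(0.5, 0.25, 0.25), tolerance = 1e-12)
  expect_equal(res$predicted, "TE")
})

test_that("log-domain recording likelihood equals the naive product", {
  world <- separatedWorld()
  gmm <- world$bank$models$male$SE
  w <- gmm$weights
  withr::with_seed(17, {
    for (N in c(1, 5, 20)) {
      Y <- matrix(rnorm(N * 13, sd = 0.5), N, 13)
      naive <- prod(vapply(seq_len(N), function(i) {
        sum(vapply(seq_along(w), function(j)
          w[j] * prod(dnorm(Y[i, ], gmm$means[j, ], sqrt(gmm$vars[j, ]))),
          numeric(1)))
      }, numeric(1)))
      skip_if(naive == 0)  # would underflow: out of the oracle's domain
      expect_equal(sum(mixtureLogPdf(Y, gmm)), log(naive), tolerance = 1e-8)
    }
  })
})

test_that("frame order does not affect the decision", {
  world <- separatedWorld()
  f <- sampleRecordingFeatures(world$gens$male$SY, n_frames = 80, seed = 4,
                               age = 40)
  res1 <- classifyRecording(f, world$bank)
  perm <- withr::with_seed(5, sample(nrow(f$y)))
  g <- f
  g$y <- f$y[perm, ]   # ts stays attached to its frame
  g$standardized <- f$standardized
  res2 <- classifyRecording(g, world$bank)
  expect_equal(res2$loglik, res1$loglik)
  expect_equal(res2$posterior, res1$posterior)
  expect_identical(res2$predicted, res1$predicted)
})

test_that("duplicated class models receive identical probabilities", {
  world <- separatedWorld()
  bank <- world$bank
  bank$models$male$SE <- bank$models$male$TE
  f <- sampleRecordingFeatures(world$gens$male$SY, n_frames = 60, seed = 9,
                               age = 35)
  res <- suppressWarnings(classifyRecording(f, bank))
  expect_equal(unname(res$posterior["TE"]), unname(res$posterior["SE"]),
               tolerance = 1e-12)
})

test_that("classification requires a complete bank for the gender", {
  world <- separatedWorld()
  f <- sampleRecordingFeatures(world$gens$male$TE, n_frames = 50, seed = 3)
  f$gender <- "female"
  expect_error(classifyRecording(f, world$bank), "no models for gender")
  partial <- world$bank
  partial$models$male$SY <- NULL
  g <- sampleRecordingFeatures(world$gens$male$TE, n_frames = 50, seed = 3)
  expect_error(classifyRecording(g, partial), "missing class")
})

test_that("a saved bank reloads to identical posteriors", {
  world <- separatedWorld()
  path <- withr::local_tempfile(fileext = ".json")
  saveModelBank(world$bank, path)
  bank2 <- loadModelBank(path)
  f <- sampleRecordingFeatures(world$gens$male$TE, n_frames = 70, seed = 23,
                               age = 44)
  r1 <- classifyRecording(f, world$bank)
  r2 <- classifyRecording(f, bank2)
  expect_equal(r2$posterior, r1$posterior, tolerance = 1e-12)
  expect_identical(r2$predicted, r1$predicted)
  expect_identical(bank2$fingerprint, world$bank$fingerprint)
})

test_that("corrupt or incompatible bank files are refused", {
  world <- separatedWorld()
  path <- withr::local_tempfile(fileext = ".json")
  saveModelBank(world$bank, path)
  txt <- readChar(path, file.size(path))
  bad <- withr::local_tempfile(fileext = ".json")
  writeChar(substr(txt, 1, 200), bad, eos = NULL)
  expect_error(loadModelBank(bad), "parse")
  wrong <- withr::local_tempfile(fileext = ".json")
  writeChar(sub('"schema_version":1', '"schema_version":99', txt), wrong,
            eos = NULL)
  expect_error(loadModelBank(wrong), "schema")
})

test_that("a hand-written single-component bank classifies validly", {
  bank <- miniBank(c(TE = -1, SE = 0, SY = 1))
  f <- randomFeatures(n = 30, seed = 8)
  res <- classifyRecording(f, bank)
  expect_s3_class(res, "DiagnosisResult")
  expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
  expect_true(res$predicted %in% c("TE", "SE", "SY"))
})
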