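# Draw from a known 2-component 13-d diagonal mixture whose components
# sit at distinct time positions (the recovery oracle's ground truth).
drawKnownMixture <- function(n, seed = 42,
                             w = c(0.4, 0.6),
                             mu_feat = c(-1.5, 1.5),
                             ts_mu = c(0.3, 0.7), ts_sd = 0.05) {
  withr::with_seed(seed, {
    comp <- sample(1:2, n, replace = TRUE, prob = w)
    x <- matrix(rnorm(n * 12), n, 12) + mu_feat[comp]
    ts <- pmin(pmax(rnorm(n, ts_mu[comp], ts_sd), 0), 1)
    list(Y = cbind(x, ts = ts), comp = comp,
         truth = list(w = w, mu_feat = mu_feat, ts_mu = ts_mu))
  })
}

test_that("time-partition assignment maps ts slices to components", {
  expect_equal(initialAssignment(0.01, M = 15), 1L)
  expect_equal(initialAssignment(1.0, M = 15), 15L)
  expect_equal(initialAssignment(c(0, 0.2, 0.4, 0.6, 0.9), M = 3),
               c(1L, 1L, 2L, 2L, 3L))
  # Everything strictly inside the first 1/M goes to component 1.
  ts <- seq(0, 1 / 15 - 1e-9, length.out = 50)
  expect_true(all(initialAssignment(ts, M = 15) == 1L))
  expect_true(all(initialAssignment(runif(100), M = 7) %in% 1:7))
  expect_error(initialAssignment(1.2, M = 3), "\\[0, 1\\]")
})

test_that("Gaussian log-density matches closed form and the full-matrix oracle", {
  mu <- rep(0, 13)
  expect_equal(gaussianLogPdf(mu, mu, rep(1, 13)), -13 / 2 * log(2 * pi))

  withr::with_seed(7, {
    for (i in 1:20) {
      y <- rnorm(13)
      m <- rnorm(13)
      v <- rexp(13) + 0.1
      expect_equal(gaussianLogPdf(y, m, v),
                   as.numeric(oracleMvnLogPdf(y, m, diag(v))),
                   tolerance = 1e-10)
      # Full-matrix implementation path against the same oracle.
      A <- matrix(rnorm(169), 13)
      S <- crossprod(A) + diag(13) * 0.5
      expect_equal(gaussianLogPdf(y, m, S),
                   as.numeric(oracleMvnLogPdf(y, m, S)),
                   tolerance = 1e-8)
      # Translation invariance.
      shift <- rnorm(13)
      expect_equal(gaussianLogPdf(y + shift, m + shift, v),
                   gaussianLogPdf(y, m, v))
    }
  })
  expect_error(gaussianLogPdf(rep(0, 13), rep(0, 13), rep(-1, 13)),
               "model invalid")
  expect_error(gaussianLogPdf(rep(0, 13), rep(0, 13),
                              matrix(-1, 13, 13)), "model invalid")
})

test_that("mixture log-density reduces and merges correctly", {
  g1 <- miniGmm(mean1 = 0.7)
  y <- withr::with_seed(1, rnorm(13))
  expect_equal(mixtureLogPdf(y, g1),
               gaussianLogPdf(y, g1$means[1, ], g1$vars[1, ]))
  # Two identical half-weight components equal the single component.
  g2 <- scvoice:::newGmm(weights = c(0.5, 0.5),
                         means = g1$means[c(1, 1), ],
                         vars = g1$vars[c(1, 1), ], covs = NULL,
                         covariance = "diagonal")
  expect_equal(mixtureLogPdf(y, g2), mixtureLogPdf(y, g1))
})

test_that("log-sum-exp mixture density matches the naive linear-domain sum", {
  withr::with_seed(3, {
    M <- 3
    w <- as.numeric(rmultinom(1, 100, rep(1, M))) / 100
    w[w == 0] <- 0.01; w <- w / sum(w)
    means <- matrix(rnorm(M * 13), M, 13)
    vars <- matrix(rexp(M * 13) + 0.2, M, 13)
    gmm <- scvoice:::newGmm(w, means, vars, NULL, "diagonal")
    for (i in 1:100) {
      y <- rnorm(13)
      naive <- sum(vapply(1:M, function(j)
        w[j] * prod(dnorm(y, means[j, ], sqrt(vars[j, ]))), numeric(1)))
      expect_equal(mixtureLogPdf(y, gmm), log(naive), tolerance = 1e-8)
    }
  })
})

test_that("M = 1 recovers pooled sample moments exactly", {
  d <- drawKnownMixture(500, seed = 5)
  cfg <- pipelineConfig()
  gmm <- fitGmm(d$Y, cfg, M = 1L)
  expect_equal(gmm$weights, 1)
  expect_equal(gmm$means[1, ], colMeans(d$Y))
  n <- nrow(d$Y)
  pop_var <- colMeans(d$Y^2) - colMeans(d$Y)^2
  expect_equal(gmm$vars[1, ], pop_var)
  expect_equal(tsSummary(gmm), mean(d$Y[, "ts"]))
})

test_that("EM log-likelihood is non-decreasing every iteration", {
  d <- drawKnownMixture(2000, seed = 8)
  cfg <- pipelineConfig()
  for (M in c(2L, 5L, 15L)) {
    gmm <- fitGmm(d$Y, cfg, M = M)
    expect_true(all(diff(gmm$loglik) >= -1e-8))
  }
})

test_that("EM recovers the parameters of a known well-separated mixture", {
  d <- drawKnownMixture(5000, seed = 42)
  cfg <- pipelineConfig()
  gmm <- fitGmm(d$Y, cfg, M = 2L)
  ord <- order(tsSummary(gmm))
  expect_true(all(abs(gmm$weights[ord] - d$truth$w) < 0.03))
  expect_true(all(abs(gmm$means[ord[1], 1:12] - d$truth$mu_feat[1]) < 0.1))
  expect_true(all(abs(gmm$means[ord[2], 1:12] - d$truth$mu_feat[2]) < 0.1))
  expect_true(all(abs(tsSummary(gmm)[ord] - d$truth$ts_mu) < 0.1))
})

test_that("parameter error shrinks as the sample grows", {
  cfg <- pipelineConfig()
  err <- vapply(c(2000L, 20000L), function(n) {
    d <- drawKnownMixture(n, seed = 77)
    gmm <- fitGmm(d$Y, cfg, M = 2L)
    ord <- order(tsSummary(gmm))
    truth_means <- rbind(c(rep(d$truth$mu_feat[1], 12), d$truth$ts_mu[1]),
                         c(rep(d$truth$mu_feat[2], 12), d$truth$ts_mu[2]))
    mean(abs(gmm$means[ord, ] - truth_means)) +
      mean(abs(gmm$weights[ord] - d$truth$w))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("insufficient data for the requested M is refused", {
  d <- drawKnownMixture(100, seed = 1)
  expect_error(fitGmm(d$Y, pipelineConfig(), M = 15L), "insufficient data")
})

test_that("full-covariance mode fits and scores coherently", {
  d <- drawKnownMixture(1500, seed = 13)
  cfg <- pipelineConfig(covariance = "full")
  gmm <- fitGmm(d$Y, cfg, M = 2L)
  expect_true(all(diff(gmm$loglik) >= -1e-8))
  expect_equal(dim(gmm$covs), c(13L, 13L, 2L))
  # Diagonal and full modes agree closely on this diagonal-truth data.
  gd <- fitGmm(d$Y, pipelineConfig(), M = 2L)
  y <- d$Y[7, ]
  expect_equal(mixtureLogPdf(y, gmm), mixtureLogPdf(y, gd), tolerance = 0.1)
})

test_that("component time summary is ordered on time-structured data", {
  world <- separatedWorld()
  gmm <- world$bank$models$male$TE
  ts <- tsSummary(gmm)
  expect_length(ts, 15L)
  expect_true(all(ts >= 0 & ts <= 1))
  expect_gt(cor(ts, seq_along(ts), method = "spearman"), 0.9)
})
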