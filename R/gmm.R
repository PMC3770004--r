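#' Time-partition initial assignment
#'
#' EM starts from a hard assignment of frames to components obtained by
#' slicing the sentence uniformly along the relative position `ts`: with
#' `M` components, frames from the first `1/M` of the sentence seed
#' component 1, and so on; `ts = 1` lands in component `M`. The
#' assignment only seeds EM — components move freely afterwards, but the
#' seeding gives each one a distinct stretch of the sentence to start
#' from, which is what makes the fit deterministic and time-anchored.
#'
#' @param ts numeric vector of relative positions in `[0, 1]`.
#' @param M number of mixture components.
#' @return Integer component indices in `1..M`.
#' @export
#' @examples
#' initialAssignment(c(0, 0.2, 0.4, 0.6, 0.9), M = 3)
initialAssignment <- function(ts, M) {
  stopifnot(M >= 1L, length(ts) >= 1L)
  if (any(ts < 0 | ts > 1)) stop("ts values must lie in [0, 1]", call. = FALSE)
  pmin(floor(ts * M), M - 1L) + 1L
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

rowLogSumExp <- function(X) {
  m <- apply(X, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok))
    out[ok] <- m[ok] + log(rowSums(exp(X[ok, , drop = FALSE] - m[ok])))
  out
}

#' Log-density of one Gaussian component
#'
#' Multivariate normal log-density. For a diagonal covariance (given as
#' a vector of variances) this is the sum of one-dimensional normal
#' log-densities; a full covariance matrix is handled through its
#' Cholesky factor.
#'
#' @param y numeric vector (one observation) or matrix (one observation
#'   per row).
#' @param mean component mean vector.
#' @param cov vector of variances (diagonal model) or a symmetric
#'   positive-definite covariance matrix.
#' @return Log-density value(s).
#' @export
gaussianLogPdf <- function(y, mean, cov) {
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  d <- length(mean)
  if (ncol(Y) != d) stop("dimension mismatch between y and mean", call. = FALSE)
  if (is.matrix(cov)) {
    if (!all(dim(cov) == d)) stop("covariance dimension mismatch", call. = FALSE)
    ch <- tryCatch(chol(cov), error = function(e)
      stop("model invalid: covariance is not positive-definite", call. = FALSE))
    centered <- sweep(Y, 2L, mean)
    z <- backsolve(ch, t(centered), transpose = TRUE)
    drop(-0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2))
  } else {
    if (length(cov) != d) stop("covariance dimension mismatch", call. = FALSE)
    if (any(cov <= 0))
      stop("model invalid: non-positive variance", call. = FALSE)
    centered <- sweep(Y, 2L, mean)
    drop(-0.5 * d * log(2 * pi) - 0.5 * sum(log(cov)) -
           0.5 * (centered^2 %*% (1 / cov)))
  }
}

# n x M matrix of per-component log-densities (no weights).
componentLogDens <- function(Y, gmm) {
  M <- length(gmm$weights)
  out <- matrix(NA_real_, nrow = nrow(Y), ncol = M)
  for (j in seq_len(M)) {
    cov_j <- if (gmm$covariance == "full") gmm$covs[, , j] else gmm$vars[j, ]
    out[, j] <- gaussianLogPdf(Y, gmm$means[j, ], cov_j)
  }
  out
}

#' Log-density under a Gaussian mixture model
#'
#' `log sum_j w_j g(y | mu_j, Sigma_j)`, evaluated through log-sum-exp so
#' that the result stays finite even where every component density
#' underflows in linear space.
#'
#' @param y observation vector or matrix (one observation per row).
#' @param gmm a fitted `GaussianMixtureModel`.
#' @return Log mixture density value(s).
#' @export
mixtureLogPdf <- function(y, gmm) {
  stopifnot(inherits(gmm, "GaussianMixtureModel"))
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  L <- sweep(componentLogDens(Y, gmm), 2L, log(gmm$weights), `+`)
  drop(rowLogSumExp(L))
}

newGmm <- function(weights, means, vars, covs, covariance, meta = list()) {
  gmm <- c(list(weights = weights, means = means, vars = vars, covs = covs,
                covariance = covariance), meta)
  class(gmm) <- "GaussianMixtureModel"
  gmm
}

# Moments of a hard partition; variance is the population (1/n) form so
# that M = 1 reproduces the weighted M-step exactly.
partitionMoments <- function(Y, assign, M, var_floor) {
  d <- ncol(Y)
  weights <- numeric(M)
  means <- matrix(0, M, d)
  vars <- matrix(var_floor, M, d)
  global_mu <- colMeans(Y)
  global_var <- pmax(colMeans(Y^2) - global_mu^2, var_floor)
  for (j in seq_len(M)) {
    rows <- which(assign == j)
    if (length(rows) == 0L) {
      # Empty time slice (short recording set): seed from global moments.
      weights[j] <- 0.5 / nrow(Y)
      means[j, ] <- global_mu
      vars[j, ] <- global_var
    } else {
      Yj <- Y[rows, , drop = FALSE]
      weights[j] <- length(rows) / nrow(Y)
      means[j, ] <- colMeans(Yj)
      vars[j, ] <- pmax(colMeans(Yj^2) - means[j, ]^2, var_floor)
    }
  }
  list(weights = weights / sum(weights), means = means, vars = vars)
}

#' Fit a Gaussian mixture model by EM with time-partition initialization
#'
#' Pools the frame feature vectors of one (gender, class) training group
#' and fits an `M`-component mixture over the 13 dimensions (12 MFCCs +
#' `ts`). Initialization is the hard time partition of
#' [initialAssignment()] followed by per-partition empirical moments;
#' EM then alternates responsibilities (E-step) and weighted moment
#' updates (M-step) until the mean log-likelihood per frame changes by
#' less than `cfg$em_tol` or `cfg$em_max_iter` iterations are reached.
#' Variances are floored at `cfg$var_floor`; a component whose
#' responsibility mass collapses is re-seeded from the initial time
#' partition with the largest total variance (a message is emitted).
#'
#' @param Y pooled `n` x 13 feature matrix whose final column is `ts`,
#'   or a list of `RecordingFeatures` to pool.
#' @param cfg a [pipelineConfig()]; uses `M`, `covariance`, `em_tol`,
#'   `em_max_iter`, `var_floor`, `seed`.
#' @param M number of components, overriding `cfg$M`.
#' @return A `GaussianMixtureModel`: weights, means (`M` x 13), diagonal
#'   variances or full covariances, the log-likelihood trajectory and
#'   convergence metadata.
#' @export
fitGmm <- function(Y, cfg = pipelineConfig(), M = cfg$M) {
  if (is.list(Y) && !is.matrix(Y))
    Y <- do.call(rbind, lapply(Y, function(r) {
      stopifnot(inherits(r, "RecordingFeatures"))
      r$y
    }))
  stopifnot(is.matrix(Y))
  n <- nrow(Y)
  d <- ncol(Y)
  if (n < M * (d + 1L))
    stop("insufficient data: ", n, " frames for ", M, " components in ", d,
         " dimensions (need at least ", M * (d + 1L), ")", call. = FALSE)
  full <- identical(cfg$covariance, "full")

  assign0 <- initialAssignment(Y[, d], M)
  init <- partitionMoments(Y, assign0, M, cfg$var_floor)
  reseed_order <- order(rowSums(init$vars), decreasing = TRUE)

  weights <- init$weights
  means <- init$means
  vars <- init$vars
  covs <- if (full) {
    a <- array(0, dim = c(d, d, M))
    for (j in seq_len(M)) a[, , j] <- diag(vars[j, ], d)
    a
  } else NULL

  loglik <- numeric(0)
  converged <- FALSE
  n_reseeds <- 0L
  for (iter in seq_len(cfg$em_max_iter)) {
    gmm <- newGmm(weights, means, vars, covs, cfg$covariance)
    L <- sweep(componentLogDens(Y, gmm), 2L, log(weights), `+`)
    row_ll <- rowLogSumExp(L)
    ll <- mean(row_ll)
    loglik <- c(loglik, ll)
    if (iter > 1L && abs(ll - loglik[iter - 1L]) < cfg$em_tol) {
      converged <- TRUE
      break
    }
    R <- exp(L - row_ll)
    nk <- colSums(R)

    dead <- which(nk < n * 1e-10)
    if (length(dead) > 0L) {
      for (j in dead) {
        src <- reseed_order[(n_reseeds %% M) + 1L]
        n_reseeds <- n_reseeds + 1L
        message("re-seeding collapsed component ", j,
                " from time partition ", src)
        means[j, ] <- init$means[src, ]
        vars[j, ] <- init$vars[src, ]
        if (full) covs[, , j] <- diag(vars[j, ], d)
        weights[j] <- 1 / n
      }
      weights <- weights / sum(weights)
      next
    }

    weights <- nk / n
    means <- t(R) %*% Y / nk
    if (full) {
      for (j in seq_len(M)) {
        centered <- sweep(Y, 2L, means[j, ])
        S <- crossprod(centered * R[, j], centered) / nk[j]
        diag(S) <- pmax(diag(S), cfg$var_floor)
        covs[, , j] <- S
      }
      vars <- t(apply(covs, 3L, diag))
    } else {
      vars <- pmax(t(R) %*% Y^2 / nk - means^2, cfg$var_floor)
    }
  }

  newGmm(weights, means, vars, covs, cfg$covariance,
         meta = list(n_frames = n, em_iterations = length(loglik),
                     converged = converged, loglik = loglik,
                     final_log_likelihood = loglik[length(loglik)] * n,
                     n_reseeds = n_reseeds))
}

#' @export
print.GaussianMixtureModel <- function(x, ...) {
  cat(sprintf("GaussianMixtureModel: %d components, %d dims, %s covariance\n",
              length(x$weights), ncol(x$means), x$covariance))
  if (!is.null(x$n_frames))
    cat(sprintf("  fitted on %d frames, %d EM iterations (%s)\n",
                x$n_frames, x$em_iterations,
                if (isTRUE(x$converged)) "converged" else "max iterations"))
  invisible(x)
}

#' Mean time position of each mixture component
#'
#' The `ts` coordinate of each component mean, in component order. On a
#' trained model these values show where along the sentence each
#' Gaussian sits; with the time-partition initialization they come out
#' approximately increasing, spanning the sentence from start to end.
#'
#' @param gmm a fitted `GaussianMixtureModel`.
#' @return Numeric vector of length `M` with values in `[0, 1]`.
#' @export
tsSummary <- function(gmm) {
  stopifnot(inherits(gmm, "GaussianMixtureModel"))
  unname(gmm$means[, ncol(gmm$means)])
}
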