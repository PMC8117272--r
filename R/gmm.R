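#' K-means initialization for mixture fitting
#'
#' Seeds k-means++ centers, runs k-means with 10 restarts keeping the
#' lowest within-cluster sum of squares, and converts the best clustering
#' into initial mixture parameters: weights are cluster fractions, means
#' the centroids, covariances the within-cluster sample covariances
#' regularized to be symmetric positive definite.
#'
#' @param points numeric matrix, one row per observation.
#' @param K number of components (>= 1).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param nstart number of k-means restarts (default 10).
#' @param reg diagonal regularization added to each covariance.
#' @return list with `weights`, `means` (K x d) and `covariances`
#'   (d x d x K array).
#' @export
kmeans_init <- function(points, K, seed, nstart = 10, reg = 1e-6) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (K < 1) stop("K must be >= 1")
  if (n < K) stop("fewer points than components")
  set.seed(as.integer(seed))

  if (K == 1) {
    cl <- rep(1L, n)
  } else {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_centers(points, K)
      km <- suppressWarnings(
        stats::kmeans(points, centers = centers, iter.max = 100)
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    cl <- best$cluster
  }

  w <- as.numeric(table(factor(cl, levels = seq_len(K)))) / n
  means <- matrix(0, K, d)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    pk <- points[cl == k, , drop = FALSE]
    means[k, ] <- colMeans(pk)
    S <- if (nrow(pk) > 1) stats::cov(pk) else diag(0, d)
    S <- (S + t(S)) / 2
    diag(S) <- diag(S) + reg
    # inflate until SPD (duplicated resampled points can collapse a cluster)
    while (inherits(try(chol(S), silent = TRUE), "try-error")) {
      diag(S) <- diag(S) + 10 * reg
    }
    covs[, , k] <- S
  }
  list(weights = w, means = means, covariances = covs)
}

# k-means++ seeding: first center uniform, then points sampled with
# probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(points, K) {
  n <- nrow(points)
  centers <- matrix(0, K, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  d2 <- rowSums((points - matrix(centers[1, ], n, ncol(points), byrow = TRUE))^2)
  for (k in seq_len(K - 1) + 1) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[k, ] <- points[idx, ]
    nd <- rowSums((points - matrix(centers[k, ], n, ncol(points), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  # kmeans() requires distinct centers
  centers + matrix(stats::rnorm(length(centers), sd = 1e-10), K, ncol(points))
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Full-covariance EM from a given initialization.  The log-likelihood is
#' non-decreasing across iterations; fitting stops when its relative
#' change falls below `tol` or after `max_iter` iterations.  Covariances
#' are regularized by adding `reg` to the diagonal at every M-step;
#' components whose weight collapses anyway are dropped with a warning.
#'
#' @param points numeric matrix, one row per observation.
#' @param init initialization as returned by [kmeans_init()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param reg diagonal covariance regularization.
#' @param seed integer recorded in the model for provenance.
#' @param participant_id,target optional labels carried into the model.
#' @return an object of class `reach_gmm` with fields `weights`, `means`,
#'   `covariances`, `K`, `log_likelihood`, `bic`, `n_points`,
#'   `loglik_trace`, `converged`, `seed`, `participant_id`, `target`.
#' @export
em_fit <- function(points, init, tol = 1e-6, max_iter = 500, reg = 1e-6,
                   seed = NA_integer_, participant_id = NA_character_,
                   target = NA_character_) {
  points <- as.matrix(points)
  K0 <- length(init$weights)
  if (nrow(points) <= K0) stop("need more points than components")
  fit <- em_gmm_cpp(points, init$weights, init$means, init$covariances,
                    tol, max_iter, reg)
  if (fit$dropped > 0) {
    warning(fit$dropped, " degenerate component(s) dropped during EM")
  }
  K <- length(fit$weights)
  if (K == 0) stop("all components degenerate")
  if (!fit$converged && fit$iterations >= max_iter) {
    warning("EM did not converge within max_iter; returning best-so-far fit")
  }
  model <- structure(list(
    weights = as.numeric(fit$weights),
    means = fit$means,
    covariances = fit$covariances,
    K = K,
    log_likelihood = fit$log_likelihood,
    bic = NA_real_,
    n_points = nrow(points),
    loglik_trace = as.numeric(fit$loglik_trace),
    converged = fit$converged,
    seed = seed,
    participant_id = participant_id,
    target = target
  ), class = "reach_gmm")
  model$bic <- bic_score(model)
  model
}

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = k ln(n) - 2 logL` with
#' `k = (K - 1) + K d + K d (d + 1) / 2` free parameters (weights, means,
#' full covariances); for the 2-D spatiotemporal models `k = 6K - 1`.
#' Lower is better.
#'
#' @param model a `reach_gmm`.
#' @param n number of observations; defaults to the count the model was
#'   fitted on.
#' @return the BIC value.
#' @export
bic_score <- function(model, n = model$n_points) {
  if (is.null(n) || n <= 0) stop("n must be positive")
  K <- model$K
  d <- ncol(model$means)
  k <- (K - 1) + K * d + K * d * (d + 1) / 2
  k * log(n) - 2 * model$log_likelihood
}

#' Fit mixtures over a range of orders and select by BIC
#'
#' Fits one EM run per candidate order K (each initialized by the best of
#' 10 k-means++ restarts) and returns the model with the smallest BIC,
#' ties broken toward the smaller order.
#'
#' @param points numeric matrix of observations.
#' @param kmin,kmax candidate order range (defaults 2 and 25).  If there
#'   are not enough points `kmax` is reduced with a warning.
#' @param seed integer seed; each candidate order uses the deterministic
#'   sub-seed `seed + K`.
#' @param tol,max_iter,reg EM settings, see [em_fit()].
#' @param participant_id,target labels carried into the model.
#' @return the minimum-BIC `reach_gmm`.
#' @export
select_gmm <- function(points, kmin = 2, kmax = 25, seed = 1,
                       tol = 1e-6, max_iter = 500, reg = 1e-6,
                       participant_id = NA_character_, target = NA_character_) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (kmax < kmin) stop("kmax must be >= kmin")
  if (n <= kmax) {
    warning("fewer points than kmax + 1; reducing kmax to n - 1")
    kmax <- n - 1
    if (kmax < kmin) stop("too few points for kmin components")
  }
  best <- NULL
  for (K in kmin:kmax) {
    fit <- tryCatch({
      init <- kmeans_init(points, K, seed = seed + K, reg = reg)
      em_fit(points, init, tol = tol, max_iter = max_iter, reg = reg,
             seed = seed, participant_id = participant_id, target = target)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  if (is.null(best)) stop("all candidate orders failed to fit")
  best
}

#' @export
print.reach_gmm <- function(x, ...) {
  cat(sprintf("<reach_gmm> K = %d, logL = %.2f, BIC = %.2f, n = %d%s\n",
              x$K, x$log_likelihood, x$bic, x$n_points,
              if (!is.na(x$participant_id))
                sprintf(" (%s/%s)", x$participant_id, x$target) else ""))
  invisible(x)
}
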