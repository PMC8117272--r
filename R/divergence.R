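#' A single Gaussian component
#'
#' @param mean numeric mean vector.
#' @param cov symmetric positive-definite covariance matrix.
#' @param weight mixing weight in (0, 1].
#' @return an object of class `gaussian_component`.
#' @export
gaussian_component <- function(mean, cov, weight = 1) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("dimension mismatch between mean and covariance")
  }
  if (weight <= 0) stop("weight must be positive")
  if (inherits(try(chol(cov), silent = TRUE), "try-error")) {
    stop("covariance must be symmetric positive definite")
  }
  structure(list(weight = weight, mean = mean, cov = cov),
            class = "gaussian_component")
}

# Coerce a reach_gmm / gaussian_component / plain list into the internal
# mixture form: weights (normalized), means (K x d), covariances (d x d x K).
as_mixture <- function(m) {
  if (inherits(m, "gaussian_component")) {
    d <- length(m$mean)
    return(list(weights = 1,
                means = matrix(m$mean, 1, d),
                covariances = array(m$cov, c(d, d, 1))))
  }
  if (is.null(m$weights) || is.null(m$means) || is.null(m$covariances)) {
    stop("not a mixture model: need weights, means, covariances")
  }
  K <- length(m$weights)
  if (K == 0) stop("empty mixture")
  means <- as.matrix(m$means)
  list(weights = as.numeric(m$weights) / sum(m$weights),
       means = means,
       covariances = m$covariances)
}

# log |Sigma| and a lower Cholesky factor, with an SPD check
chol_lower <- function(S) {
  L <- try(t(chol(S)), silent = TRUE)
  if (inherits(L, "try-error")) stop("singular or non-SPD covariance")
  L
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' Closed form
#' \deqn{KL(a\|b) = \tfrac12\left[\mathrm{tr}(\Sigma_b^{-1}\Sigma_a)
#'   + (\mu_b-\mu_a)^\top \Sigma_b^{-1} (\mu_b-\mu_a) - d
#'   + \ln\frac{\det \Sigma_b}{\det \Sigma_a}\right].}
#' Nonnegative, zero iff the two Gaussians coincide.
#'
#' @param a,b [gaussian_component()] objects of equal dimension.
#' @return the divergence (nats).
#' @export
gaussian_kld <- function(a, b) {
  d <- length(a$mean)
  if (length(b$mean) != d) stop("dimension mismatch")
  La <- chol_lower(a$cov)
  Lb <- chol_lower(b$cov)
  # tr(Sb^-1 Sa) via triangular solves
  M <- forwardsolve(Lb, a$cov)
  M <- forwardsolve(Lb, t(M))
  tr <- sum(diag(M))
  dm <- b$mean - a$mean
  z <- forwardsolve(Lb, dm)
  quad <- sum(z^2)
  logdet <- 2 * (sum(log(diag(Lb))) - sum(log(diag(La))))
  kl <- 0.5 * (tr + quad - d + logdet)
  max(kl, 0)
}

# K_f x K_g matrix of pairwise component KLs
component_kld_matrix <- function(f, g) {
  Kf <- length(f$weights); Kg <- length(g$weights)
  M <- matrix(0, Kf, Kg)
  for (i in seq_len(Kf)) {
    ci <- gaussian_component(f$means[i, ], f$covariances[, , i])
    for (j in seq_len(Kg)) {
      M[i, j] <- gaussian_kld(ci, gaussian_component(g$means[j, ], g$covariances[, , j]))
    }
  }
  M
}

#' Variational approximation to the KL divergence between mixtures
#'
#' The Hershey-Olsen variational bound-based approximation
#' \deqn{D_{var}(f\|g) = \sum_a \omega_a \ln
#'   \frac{\sum_{a'} \omega_{a'} e^{-KL(f_a\|f_{a'})}}
#'        {\sum_b \pi_b e^{-KL(f_a\|g_b)}},}
#' computed in log space, exact for single-component mixtures, and
#' clamped below at zero (the approximation is not guaranteed
#' nonnegative).
#'
#' @param f,g mixture models (`reach_gmm` or lists with `weights`,
#'   `means`, `covariances`).
#' @return approximate KL(f || g) in nats, >= 0.
#' @export
variational_kld <- function(f, g) {
  f <- as_mixture(f); g <- as_mixture(g)
  Mff <- component_kld_matrix(f, f)
  Mfg <- component_kld_matrix(f, g)
  lw <- log(f$weights)
  lp <- log(g$weights)
  terms <- vapply(seq_along(f$weights), function(a) {
    logsumexp(lw - Mff[a, ]) - logsumexp(lp - Mfg[a, ])
  }, 0)
  max(sum(f$weights * terms), 0)
}

#' Bidirectional Kullback-Leibler divergence between mixtures
#'
#' The symmetrized (Jeffreys-type) divergence: the sum of the two
#' directed variational approximations,
#' `BKLD = D_var(f || g) + D_var(g || f)`.
#'
#' @param f,g mixture models.
#' @return BKLD >= 0; zero iff the mixtures coincide.
#' @export
bkld <- function(f, g) {
  variational_kld(f, g) + variational_kld(g, f)
}

#' Natural log of the bidirectional KL divergence
#'
#' `log(max(BKLD, eps))`; the floor keeps identical models (BKLD = 0)
#' finite, with a warning since a floored value signals a degenerate
#' comparison.
#'
#' @param f,g mixture models.
#' @param eps positive floor (default 1e-12).
#' @return log-BKLD.
#' @export
log_bkld <- function(f, g, eps = 1e-12) {
  v <- bkld(f, g)
  if (v < eps) {
    warning("BKLD below eps; log-BKLD floored (degenerate comparison)")
    v <- eps
  }
  log(v)
}

#' Sigma points of a Gaussian (unscented transform)
#'
#' The classical 2d+1 sigma-point set: the mean with weight
#' `kappa / (d + kappa)`, and the mean plus/minus each column of the
#' Cholesky factor of `(d + kappa) Sigma`, each with weight
#' `1 / (2 (d + kappa))`.  The weighted mean and scatter of the points
#' reproduce the Gaussian's mean and covariance exactly.
#'
#' @param c a [gaussian_component()] (or list with `mean`, `cov`).
#' @param kappa spread parameter; `d + kappa` must be positive.  The
#'   classical heuristic `kappa = 3 - d` matches fourth-moment terms.
#' @return list with `points` ((2d+1) x d matrix) and `weights`.
#' @export
sigma_points <- function(c, kappa = 1) {
  mu <- as.numeric(c$mean)
  S <- as.matrix(c$cov)
  d <- length(mu)
  if (d + kappa <= 0) stop("d + kappa must be positive")
  L <- t(chol((d + kappa) * S))  # lower triangular; columns are the spreads
  pts <- matrix(mu, 2 * d + 1, d, byrow = TRUE)
  for (i in seq_len(d)) {
    pts[1 + i, ] <- mu + L[, i]
    pts[1 + d + i, ] <- mu - L[, i]
  }
  w <- c(kappa / (d + kappa), rep(1 / (2 * (d + kappa)), 2 * d))
  list(points = pts, weights = w)
}

# log density of a mixture at rows of X
mixture_logdensity <- function(m, X) {
  X <- as.matrix(X)
  K <- length(m$weights)
  d <- ncol(X)
  lp <- matrix(-Inf, nrow(X), K)
  for (k in seq_len(K)) {
    L <- chol_lower(m$covariances[, , k])
    Xc <- t(X) - m$means[k, ]
    Z <- forwardsolve(L, Xc)
    quad <- colSums(Z^2)
    logdet <- 2 * sum(log(diag(L)))
    lp[, k] <- log(m$weights[k]) - 0.5 * (d * log(2 * pi) + logdet + quad)
  }
  apply(lp, 1, logsumexp)
}

#' Hellinger distance between mixtures via the unscented transform
#'
#' The Bhattacharyya coefficient is written as an expectation under f,
#' \eqn{BC = \int \sqrt{f g} = E_f[\sqrt{g/f}]}, and the expectation
#' under each mixture component is approximated by the unscented
#' transform over that component's sigma points:
#' \deqn{BC \approx \sum_a \omega_a \sum_k W_k \sqrt{g(x_{a,k}) / f(x_{a,k})}.}
#' The density ratio is evaluated in log space.  BC is clamped to
#' `[0, 1]` and `HD = sqrt(1 - BC)`.  The returned value is the mean of
#' the f-expanded and g-expanded estimates, so it is symmetric by
#' construction.
#'
#' @param f,g mixture models.
#' @param kappa sigma-point spread, see [sigma_points()].
#' @return Hellinger distance in `[0, 1]`.
#' @export
hellinger_unscented <- function(f, g, kappa = 1) {
  f <- as_mixture(f); g <- as_mixture(g)
  0.5 * (hd_one_sided(f, g, kappa) + hd_one_sided(g, f, kappa))
}

# one direction: expectation expanded under f
hd_one_sided <- function(f, g, kappa) {
  bc <- 0
  for (a in seq_along(f$weights)) {
    sp <- sigma_points(list(mean = f$means[a, ], cov = f$covariances[, , a]),
                       kappa = kappa)
    lf <- mixture_logdensity(f, sp$points)
    lg <- mixture_logdensity(g, sp$points)
    r <- exp(0.5 * (lg - lf))
    ok <- is.finite(r)
    if (!all(ok)) {
      warning("degenerate sigma point skipped in Hellinger estimate")
      r <- r[ok]
      wts <- sp$weights[ok] / sum(sp$weights[ok])
    } else {
      wts <- sp$weights
    }
    bc <- bc + f$weights[a] * sum(wts * r)
  }
  bc <- min(max(bc, 0), 1)
  sqrt(1 - bc)
}

#' Closed-form Hellinger distance between two Gaussians
#'
#' Exact formula via the Gaussian Bhattacharyya coefficient
#' \deqn{BC = \frac{\det(\Sigma_1)^{1/4} \det(\Sigma_2)^{1/4}}
#'      {\det(\bar\Sigma)^{1/2}}
#'   \exp\left(-\tfrac18 (\mu_1-\mu_2)^\top \bar\Sigma^{-1}
#'   (\mu_1-\mu_2)\right), \quad \bar\Sigma = (\Sigma_1+\Sigma_2)/2,}
#' with `HD = sqrt(1 - BC)`.  Used to validate the unscented estimator,
#' which is exact only in the limit.
#'
#' @param a,b [gaussian_component()] objects.
#' @return Hellinger distance in `[0, 1]`.
#' @export
gaussian_hellinger <- function(a, b) {
  Sbar <- (a$cov + b$cov) / 2
  La <- chol_lower(a$cov); Lb <- chol_lower(b$cov); Ls <- chol_lower(Sbar)
  logdet_a <- 2 * sum(log(diag(La)))
  logdet_b <- 2 * sum(log(diag(Lb)))
  logdet_s <- 2 * sum(log(diag(Ls)))
  dm <- a$mean - b$mean
  z <- forwardsolve(Ls, dm)
  log_bc <- 0.25 * logdet_a + 0.25 * logdet_b - 0.5 * logdet_s -
    sum(z^2) / 8
  bc <- min(max(exp(log_bc), 0), 1)
  sqrt(1 - bc)
}

#' Nearest-neighbour distance of a subject model to reference models
#'
#' Evaluates the chosen stochastic distance between the subject model and
#' every reference model for the same target, and returns the minimum
#' (ties broken toward the first reference).  When the subject is itself
#' part of the reference set (control participants), pass its id via
#' `exclude_id` for the leave-one-out comparison; a reference with the
#' same participant id as the subject is always excluded.
#'
#' @param subject a `reach_gmm`.
#' @param refs list of `reach_gmm` reference models.
#' @param metric "HD", "BKLD" or "logBKLD".
#' @param kappa sigma-point spread for HD.
#' @param exclude_id participant id(s) to drop from `refs` (defaults to
#'   the subject's own id).
#' @return list of class `distance_result` with `metric`, `value`,
#'   `subject_id`, `nearest_ref_id`, `target` and `all_ref_values` (a
#'   data frame of per-reference values).
#' @export
nearest_neighbor_distance <- function(subject, refs,
                                      metric = c("HD", "BKLD", "logBKLD"),
                                      kappa = 1,
                                      exclude_id = subject$participant_id) {
  metric <- match.arg(metric)
  if (length(refs) == 0) stop("empty reference set")
  ref_ids <- vapply(refs, function(r)
    as.character(r$participant_id), "")
  tgts <- vapply(refs, function(r) as.character(r$target), "")
  if (!is.na(subject$target) &&
      any(!is.na(tgts) & tgts != subject$target)) {
    stop("all reference models must share the subject's target")
  }
  drop <- !is.na(ref_ids) & ref_ids %in% exclude_id
  refs <- refs[!drop]
  ref_ids <- ref_ids[!drop]
  if (length(refs) == 0) stop("no references left after leave-one-out exclusion")

  vals <- vapply(refs, function(r) {
    switch(metric,
           HD = hellinger_unscented(subject, r, kappa = kappa),
           BKLD = bkld(subject, r),
           logBKLD = log_bkld(subject, r))
  }, 0)
  i <- which.min(vals)  # which.min keeps the first index on ties
  structure(list(
    metric = metric,
    value = vals[i],
    subject_id = subject$participant_id,
    nearest_ref_id = ref_ids[i],
    target = subject$target,
    all_ref_values = data.frame(ref_id = ref_ids, value = vals,
                                stringsAsFactors = FALSE)
  ), class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> %s(%s vs nearest %s @ %s) = %.4f over %d refs\n",
              x$metric, x$subject_id, x$nearest_ref_id, x$target, x$value,
              nrow(x$all_ref_values)))
  invisible(x)
}
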