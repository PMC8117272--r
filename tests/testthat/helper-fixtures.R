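# Shared fixtures and independent oracles for the test suite.
# Oracle helpers here are written independently of the package internals
# (plain quadratic-form densities, brute-force scans, Monte-Carlo sums).

# triangular speed profile: linear rise 0 -> 100 over samples 0..60,
# linear fall 100 -> 0 over samples 60..120 (121 samples)
triangle_speed <- function() {
  c(seq(0, 100, length.out = 61), seq(100, 0, length.out = 61)[-1])
}

# brute-force segmentation scan implementing the verbal rule directly:
# onset = first sample strictly above thr staying above for >= hold_n
# samples; offset = sample before the first post-peak run strictly below
# thr lasting >= hold_n samples or reaching the end. 0-based indices.
brute_force_bounds <- function(speed, fs, frac = 0.1, hold = 0.1) {
  thr <- frac * max(speed)
  hold_n <- round(hold * fs)
  n <- length(speed)
  onset <- NA
  for (i in seq_len(n - hold_n + 1)) {
    if (all(speed[i:(i + hold_n - 1)] > thr)) { onset <- i - 1; break }
  }
  peak <- which.max(speed)
  offset <- NA
  for (i in (peak + 1):n) {
    if (speed[i] < thr) {
      run_end <- i
      while (run_end < n && speed[run_end + 1] < thr) run_end <- run_end + 1
      if (run_end - i + 1 >= hold_n || run_end == n) { offset <- i - 2; break }
      # skip past this short run
    }
  }
  if (is.na(offset)) offset <- n - 1
  c(onset = onset, offset = offset)
}

# independent 2-D mixture log-density via plain quadratic forms
oracle_mix_logdensity <- function(m, X) {
  K <- length(m$weights)
  lp <- matrix(-Inf, nrow(X), K)
  for (k in seq_len(K)) {
    S <- m$covariances[, , k]
    dt <- S[1, 1] * S[2, 2] - S[1, 2]^2
    dx <- X[, 1] - m$means[k, 1]
    dy <- X[, 2] - m$means[k, 2]
    quad <- (S[2, 2] * dx^2 - 2 * S[1, 2] * dx * dy + S[1, 1] * dy^2) / dt
    lp[, k] <- log(m$weights[k]) - 0.5 * (2 * log(2 * pi) + log(dt) + quad)
  }
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

# sample from a 2-D mixture (MASS::mvrnorm per component)
sample_mixture <- function(m, n) {
  K <- length(m$weights)
  z <- sample.int(K, n, replace = TRUE, prob = m$weights)
  X <- matrix(0, n, 2)
  for (k in seq_len(K)) {
    idx <- which(z == k)
    if (length(idx)) {
      X[idx, ] <- MASS::mvrnorm(length(idx), m$means[k, ],
                                m$covariances[, , k])
    }
  }
  X
}

# trajectory-like random mixture with moderately separated components:
# means along a smooth path in [-1,1]^2, spacing >= 3.5 component SDs
random_trajectory_model <- function(K, seed) {
  set.seed(seed)
  tpos <- seq(-0.7, 0.7, length.out = K) + rnorm(K, 0, 0.06)
  apos <- sin(1.5 * tpos) + rnorm(K, 0, 0.08)
  means <- cbind(tpos, apos)
  covs <- array(0, c(2, 2, K))
  sdmax <- if (K > 1) min(dist(means)) / 3.5 else 0.25
  for (k in seq_len(K)) {
    ang <- runif(1, -0.5, 0.5)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    D <- diag(runif(2, 0.5 * sdmax, sdmax)^2)
    covs[, , k] <- R %*% D %*% t(R)
  }
  w <- runif(K, 0.7, 1.3)
  list(weights = w / sum(w), means = means, covariances = covs)
}

# mild perturbation of a mixture (within-group model variability scale)
perturb_model <- function(m, seed, mscale = 0.4, cscale = 0.12) {
  set.seed(seed)
  K <- length(m$weights)
  sd0 <- sqrt(mean(apply(m$covariances, 3, function(S) mean(diag(S)))))
  m$means <- m$means + matrix(rnorm(2 * K, 0, mscale * sd0), K, 2)
  for (k in seq_len(K)) {
    m$covariances[, , k] <- m$covariances[, , k] * exp(rnorm(1, 0, cscale))
  }
  w <- m$weights * exp(rnorm(K, 0, 0.15))
  m$weights <- w / sum(w)
  m
}

# small synthetic cohort for pipeline-level tests
small_cohort_config <- function(seed = 11) {
  cohort_config(n_controls = 4, n_stroke = 4, trials_per_target = 5,
                targets = c("NC", "FC"), seed = seed)
}
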