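# 1-D Gaussians embedded in 2-D with an identical standard-normal second
# dimension; the second dimension contributes nothing to KL or HD.
embed2 <- function(mu, var) {
  gaussian_component(c(mu, 0), diag(c(var, 1)))
}

test_that("Gaussian KL divergence matches closed forms and quadrature", {
  a <- embed2(0, 1)
  expect_equal(gaussian_kld(a, a), 0)
  # KL(N(0,1) || N(1,1)) = 1/2
  expect_equal(gaussian_kld(a, embed2(1, 1)), 0.5, tolerance = 1e-12)
  # KL(N(0,1) || N(0,4)) = (1/4 - 1 + ln 4)/2
  expect_equal(gaussian_kld(a, embed2(0, 4)), (0.25 - 1 + log(4)) / 2,
               tolerance = 1e-12)
  # quadrature oracle for an asymmetric pair
  b <- embed2(0.7, 2.5)
  integrand <- function(x) {
    dnorm(x) * (dnorm(x, log = TRUE) - dnorm(x, 0.7, sqrt(2.5), log = TRUE))
  }
  expect_equal(gaussian_kld(a, b), integrate(integrand, -12, 12)$value,
               tolerance = 1e-8)
})

test_that("variational mixture KL collapses to the closed form for single components", {
  f <- list(weights = 1, means = matrix(c(0, 0), 1),
            covariances = array(diag(c(1, 1)), c(2, 2, 1)))
  g <- list(weights = 1, means = matrix(c(1, 0), 1),
            covariances = array(diag(c(1, 1)), c(2, 2, 1)))
  expect_equal(variational_kld(f, g), 0.5, tolerance = 1e-12)
  expect_equal(variational_kld(f, f), 0)
  expect_equal(bkld(f, g), 1.0, tolerance = 1e-12)
  expect_equal(log_bkld(f, g), 0, tolerance = 1e-12)
})

test_that("BKLD is symmetric, nonnegative, zero only at identity, permutation-invariant", {
  for (i in 1:5) {
    f <- random_trajectory_model(3, seed = 40 + i)
    g <- perturb_model(f, seed = 50 + i)
    expect_equal(bkld(f, g), bkld(g, f), tolerance = 1e-12)
    expect_gte(bkld(f, g), 0)
    expect_gt(bkld(f, g), 1e-6)
    expect_equal(bkld(f, f), 0)
    # permuting components changes nothing
    perm <- c(2, 3, 1)
    fp <- list(weights = f$weights[perm], means = f$means[perm, ],
               covariances = f$covariances[, , perm])
    expect_equal(bkld(fp, g), bkld(f, g), tolerance = 1e-9)
  }
  f <- random_trajectory_model(2, seed = 1)
  expect_warning(v <- log_bkld(f, f), "floored")
  expect_equal(v, log(1e-12))
})

test_that("sigma points reproduce the first two moments exactly", {
  # d = 2, kappa = 1: 5 points, weights (1/3, 1/6 x4)
  sp <- sigma_points(gaussian_component(c(0, 0), diag(2)), kappa = 1)
  expect_identical(dim(sp$points), c(5L, 2L))
  expect_equal(sp$weights, c(1 / 3, rep(1 / 6, 4)))
  expect_equal(sum(sp$weights), 1)
  # identity covariance: non-central points at +/- sqrt(3) e_i
  expect_equal(sort(abs(sp$points[sp$points != 0])), rep(sqrt(3), 4))

  # defining property for a random SPD covariance
  set.seed(60)
  A <- matrix(rnorm(4), 2)
  S <- crossprod(A) + diag(0.1, 2)
  mu <- c(0.3, -0.7)
  sp <- sigma_points(gaussian_component(mu, S), kappa = 1)
  expect_equal(colSums(sp$points * sp$weights), mu)
  ctr <- sweep(sp$points, 2, mu)
  expect_equal(t(ctr) %*% (ctr * sp$weights), S, ignore_attr = TRUE)
})

test_that("unscented Hellinger matches Gaussian closed forms and is bounded", {
  a <- embed2(0, 1)
  b <- embed2(1, 1)
  # closed form: HD = sqrt(1 - exp(-1/8)) for unit-variance unit shift
  expect_equal(gaussian_hellinger(a, b), sqrt(1 - exp(-1 / 8)),
               tolerance = 1e-12)
  # the unscented estimator agrees at its (3rd-order) approximation accuracy
  expect_equal(hellinger_unscented(a, b), sqrt(1 - exp(-1 / 8)),
               tolerance = 1e-3)
  expect_equal(hellinger_unscented(a, a), 0)
  # near-disjoint supports saturate toward 1
  expect_gte(hellinger_unscented(a, embed2(20, 1)), 0.99)
  expect_lte(hellinger_unscented(a, embed2(20, 1)), 1)
})

test_that("Hellinger estimates are symmetric and the one-sided halves agree", {
  for (i in 1:5) {
    f <- random_trajectory_model(2, seed = 70 + i)
    g <- perturb_model(f, seed = 80 + i)
    expect_identical(hellinger_unscented(f, g), hellinger_unscented(g, f))
    h_fg <- reachdist:::hd_one_sided(reachdist:::as_mixture(f),
                                     reachdist:::as_mixture(g), kappa = 1)
    h_gf <- reachdist:::hd_one_sided(reachdist:::as_mixture(g),
                                     reachdist:::as_mixture(f), kappa = 1)
    expect_lt(abs(h_fg - h_gf), 0.02)
    hd <- hellinger_unscented(f, g)
    expect_gte(hd, 0); expect_lte(hd, 1)
  }
})

test_that("divergences increase monotonically with mean separation", {
  base <- embed2(0, 1)
  shifts <- seq(0.25, 3, by = 0.25)
  hd <- vapply(shifts, function(s) hellinger_unscented(base, embed2(s, 1)), 0)
  bk <- vapply(shifts, function(s) bkld(base, embed2(s, 1)), 0)
  expect_true(all(diff(hd) > 0))
  expect_true(all(diff(bk) > 0))
})

test_that("nearest-neighbour scoring returns the minimum with leave-one-out", {
  mk <- function(shift, id) {
    m <- list(weights = 1, means = matrix(c(shift, 0), 1),
              covariances = array(diag(2), c(2, 2, 1)),
              participant_id = id, target = "NC")
    class(m) <- "reach_gmm"
    m
  }
  subject <- mk(0, "S1")
  refs <- list(mk(3, "C1"), mk(1, "C2"), mk(2, "C3"))
  res <- nearest_neighbor_distance(subject, refs, metric = "BKLD")
  expect_equal(res$value, bkld(subject, refs[[2]]))
  expect_identical(res$nearest_ref_id, "C2")
  expect_equal(res$value, min(res$all_ref_values$value))

  # a reference that IS the subject must be excluded, else the score is 0
  refs2 <- c(refs, list(mk(0, "S1")))
  res2 <- nearest_neighbor_distance(subject, refs2, metric = "BKLD")
  expect_identical(res2$nearest_ref_id, "C2")
  expect_gt(res2$value, 0)

  # ties keep the first reference
  refs3 <- list(mk(1, "C1"), mk(-1, "C2"))
  res3 <- nearest_neighbor_distance(subject, refs3, metric = "HD")
  expect_identical(res3$nearest_ref_id, "C1")

  expect_error(nearest_neighbor_distance(subject, list(), metric = "HD"),
               "empty")
  bad <- mk(1, "C9"); bad$target <- "FC"
  expect_error(nearest_neighbor_distance(subject, list(bad), metric = "HD"),
               "target")
})
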