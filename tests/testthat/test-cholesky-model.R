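test_that("component covariance is the outer product of the path factor", {
  expect_equal(component_covariance(chol_params(a11 = 1), "A"),
               matrix(c(1, 0, 0, 0), 2))
  expect_equal(component_covariance(chol_params(e11 = 1, e22 = 1), "E"),
               diag(2))
  # AE reference structure, against direct L %*% t(L) arithmetic
  A <- component_covariance(truth_params(), "A")
  expect_equal(round(A, 3), matrix(c(0.620, 0.315, 0.315, 0.350), 2))
})

test_that("expected pair covariance assembles within- and cross-twin blocks by zygosity", {
  p1 <- chol_params(a11 = 1)
  mz <- expected_pair_covariance(p1, "MZ")
  expect_equal(mz[c(1, 3), c(1, 3)], matrix(1, 2, 2))
  expect_equal(sum(abs(mz)) , 4)  # all other entries zero
  dz <- expected_pair_covariance(p1, "DZ")
  expect_equal(dz[1, 3], 0.5)
  expect_equal(diag(dz), c(1, 0, 1, 0))

  S <- expected_pair_covariance(truth_params(), "MZ")
  expect_equal(diag(S), rep(c(1, 1), 2), tolerance = 1e-12)
  expect_equal(S[1, 2], 0.315, tolerance = 5e-4)   # within-twin cross-visit
  expect_equal(S[1, 3], 0.620, tolerance = 5e-4)   # cross-twin visit 1
  expect_equal(S[2, 4], 0.350, tolerance = 5e-4)   # cross-twin visit 2
  expect_equal(S[1, 4], 0.315, tolerance = 5e-4)   # cross-twin cross-visit
})

test_that("pair covariances are symmetric, positive definite, and MZ-DZ differ by A/2", {
  set.seed(31)
  for (i in 1:25) {
    p <- random_valid_params()
    for (z in c("MZ", "DZ")) {
      S <- expected_pair_covariance(p, z)
      expect_equal(S, t(S))
      expect_no_error(chol(S))
    }
    diffc <- expected_pair_covariance(p, "MZ")[1:2, 3:4] -
      expected_pair_covariance(p, "DZ")[1:2, 3:4]
    expect_equal(diffc, 0.5 * component_covariance(p, "A"), tolerance = 1e-14)
  }
})

test_that("FIML pair log likelihood matches a generic Gaussian density oracle", {
  p <- truth_params()
  mm <- means_model(mu = c(log(7.1), log(7.6)))
  d <- sim_log_cohort(6, 6, seed = 3)

  # complete pair: 4-dimensional density
  pair <- d[1, ]
  y <- as.numeric(pair[, c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")])
  expect_equal(
    pair_loglik(pair, p, mm),
    mvn_logdens(y, rep(mm$mu, 2), expected_pair_covariance(p, pair$zygosity)),
    tolerance = 1e-10
  )

  # singleton observed at both visits: 2-dimensional within-twin marginal
  single <- d[2, ]
  single[, c("pwv2_v1", "pwv2_v2")] <- NA_real_
  expect_equal(
    pair_loglik(single, p, mm),
    mvn_logdens(as.numeric(single[, c("pwv1_v1", "pwv1_v2")]), mm$mu,
                expected_pair_covariance(p, single$zygosity)[1:2, 1:2]),
    tolerance = 1e-10
  )

  # nothing observed: exactly zero contribution
  empty <- d[3, ]
  empty[, c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")] <- NA_real_
  expect_identical(pair_loglik(empty, p, mm), 0)
})

test_that("pair likelihood is invariant to relabelling the twins", {
  p <- random_valid_params_seeded <- local({set.seed(5); random_valid_params()})
  mm <- means_model(mu = c(0.1, -0.2))
  d <- sim_log_cohort(5, 5, seed = 8)
  d$pwv1_v2[2] <- NA  # leave a hole so patterns differ between twins
  for (i in seq_len(nrow(d))) {
    pair <- d[i, ]
    swapped <- pair
    swapped[, c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")] <-
      pair[, c("pwv2_v1", "pwv2_v2", "pwv1_v1", "pwv1_v2")]
    expect_equal(pair_loglik(swapped, p, mm), pair_loglik(pair, p, mm),
                 tolerance = 1e-10)
  }
})

test_that("dataset deviance accumulates pair densities and is exchangeable", {
  p <- truth_params()
  mm <- means_model(mu = c(log(7.1), log(7.6)))
  d <- simulate_twin_cohort(complete_config(15, 15, missingness = c(0.1, 0.2)),
                            seed = 21)
  d <- log_transform_phenotype(d)
  stopifnot(nrow(d) >= 25)

  expect_equal(dataset_m2ll(d[1, ], p, mm), -2 * pair_loglik(d[1, ], p, mm))

  brute <- -2 * sum(vapply(seq_len(nrow(d)),
                           function(i) pair_loglik(d[i, ], p, mm), numeric(1)))
  expect_equal(dataset_m2ll(d, p, mm), brute, tolerance = 1e-8)

  swapped <- d
  swapped[, c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")] <-
    d[, c("pwv2_v1", "pwv2_v2", "pwv1_v1", "pwv1_v2")]
  expect_equal(dataset_m2ll(swapped, p, mm), dataset_m2ll(d, p, mm),
               tolerance = 1e-8)
})

test_that("zero cross-visit paths factorise the deviance into univariate models", {
  p <- chol_params(a11 = 0.8, a22 = 0.5, c11 = 0.3, c22 = 0.4,
                   e11 = 0.6, e22 = 0.7)
  mm <- means_model(mu = c(0.2, -0.1))
  d <- sim_log_cohort(10, 10, seed = 13)

  # univariate twin-model deviance per visit, built from 2x2 blocks directly
  uni_dev <- function(visit) {
    pre <- function(x) p[[paste0(x, if (visit == 1) "11" else "22")]]^2
    V <- pre("a") + pre("c") + pre("e")
    tot <- 0
    for (i in seq_len(nrow(d))) {
      k <- if (d$zygosity[i] == "MZ") 1 else 0.5
      S <- matrix(c(V, k * pre("a") + pre("c"), k * pre("a") + pre("c"), V), 2)
      y <- as.numeric(d[i, paste0("pwv", 1:2, "_v", visit)])
      obs <- !is.na(y)
      if (!any(obs)) next
      tot <- tot - 2 * mvn_logdens(y[obs], rep(mm$mu[visit], sum(obs)),
                                   S[obs, obs, drop = FALSE])
    }
    tot
  }
  expect_equal(dataset_m2ll(d, p, mm), uni_dev(1) + uni_dev(2),
               tolerance = 1e-8)
})
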