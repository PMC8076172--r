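test_that("standardized components reproduce the reference AE fractions and sum to one", {
  std <- standardized_components(truth_params())
  frac <- function(comp, v) std$fraction[std$component == comp & std$visit == v]
  expect_equal(frac("A", 1), 0.62, tolerance = 1e-12)
  expect_equal(frac("A", 2), 0.35, tolerance = 1e-12)
  expect_equal(frac("E", 2), 0.65, tolerance = 1e-12)

  set.seed(17)
  for (i in 1:20) {
    std <- standardized_components(random_valid_params())
    sums <- tapply(std$fraction, std$visit, sum)
    expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-10)
  }

  e_only <- chol_params(e11 = 1, e21 = 0.2, e22 = 0.8)
  std0 <- standardized_components(e_only)
  expect_equal(std0$fraction[std0$component == "A"], c(0, 0))
})

test_that("specific heritability isolates the novel visit-2 genetic fraction", {
  expect_equal(specific_heritability(truth_params()), 0.19, tolerance = 1e-12)
  expect_equal(specific_heritability(chol_params(a11 = 1, a21 = 0.5, e11 = 1,
                                                 e21 = 0.2, e22 = 0.9)), 0)
  # with no carried-over genetics, all visit-2 heritability is novel
  p <- chol_params(a11 = 0.7, a21 = 0, a22 = 0.5, e11 = 0.6, e21 = 0.1, e22 = 0.8)
  std <- standardized_components(p)
  expect_equal(specific_heritability(p),
               std$fraction[std$component == "A" & std$visit == 2])
})

test_that("cross-visit correlations match their closed forms and mark undefined cases", {
  cors <- cross_visit_correlations(truth_params())
  expect_equal(cors$r_ph, 0.315, tolerance = 5e-4)   # sqrt(0.62 * 0.16)
  expect_equal(cors$r_g, 0.676, tolerance = 5e-4)    # a11 a21 / sqrt(V_A1 V_A2)
  expect_true(is.na(cors$r_c))                       # no C variance: undefined
  expect_equal(cors$r_e, 0)                          # e21 = 0

  one_factor <- chol_params(a11 = 0.8, a21 = 0.5, a22 = 0, e11 = 0.5, e22 = 0.5)
  expect_equal(cross_visit_correlations(one_factor)$r_g, 1)
  no_overlap <- chol_params(a11 = 0.8, a21 = 0, a22 = 0.5, e11 = 0.5, e22 = 0.5)
  expect_equal(cross_visit_correlations(no_overlap)$r_g, 0)
})

test_that("tracking correlation identity holds for AE models with e21 = 0", {
  set.seed(23)
  for (i in 1:20) {
    p <- chol_params(a11 = runif(1, 0.2, 1), a21 = runif(1, -1, 1),
                     a22 = runif(1, 0.1, 1), e11 = runif(1, 0.2, 1),
                     e21 = 0, e22 = runif(1, 0.2, 1))
    ds <- derived_stats(p)
    expect_equal(abs(ds$r_ph),
                 sqrt(ds$h2_v1 * (ds$h2_v2 - ds$specific_h2)),
                 tolerance = 1e-12)
  }
})

test_that("difference-score decomposition follows the delta-weight formulas", {
  dd <- difference_score_decomposition(truth_params())
  h2d <- dd$fraction[dd$component == "A"]
  expect_equal(h2d, 0.2482, tolerance = 1e-4)
  expect_equal(sum(dd$fraction), 1, tolerance = 1e-12)

  e_only <- chol_params(e11 = 1, e21 = 0.3, e22 = 0.9)
  dd0 <- difference_score_decomposition(e_only)
  expect_equal(dd0$fraction[dd0$component == "A"], 0)

  # perfect tracking: visit 2 reproduces visit 1 exactly, Var(delta) = 0
  degenerate <- chol_params(a11 = 0.7, a21 = 0.7, a22 = 0,
                            e11 = 0.5, e21 = 0.5, e22 = 0)
  expect_true(all(is.na(difference_score_decomposition(degenerate)$fraction)))
})

test_that("derived statistics are invariant to factor column sign flips", {
  set.seed(29)
  p <- random_valid_params()
  flipped <- p
  flipped$a11 <- -p$a11; flipped$a21 <- -p$a21   # flip column 1 of A
  flipped$e22 <- -p$e22                          # flip column 2 of E
  expect_equal(derived_stats(do.call(chol_params, flipped)),
               derived_stats(p), tolerance = 1e-12)
})

test_that("simulated moments reproduce the model-implied tracking and delta decomposition", {
  d <- log_transform_phenotype(
    simulate_twin_cohort(complete_config(25000, 25000), seed = 37)
  )
  y_v1 <- c(d$pwv1_v1, d$pwv2_v1)
  y_v2 <- c(d$pwv1_v2, d$pwv2_v2)
  ds <- derived_stats(truth_params())
  expect_lt(abs(cor(y_v1, y_v2) - ds$r_ph), 0.01)

  delta1 <- d$pwv1_v2 - d$pwv1_v1
  delta2 <- d$pwv2_v2 - d$pwv2_v1
  v_delta <- var(c(delta1, delta2))
  dd <- difference_score_decomposition(truth_params())
  expect_lt(abs(v_delta - sum(dd$variance)), 0.015)
  # MZ cross-twin covariance of the change score isolates its genetic part
  mz <- d$zygosity == "MZ"
  expect_lt(abs(cov(delta1[mz], delta2[mz]) - dd$variance[dd$component == "A"]),
            0.015)
})
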