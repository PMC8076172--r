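test_that("the packaged reference configuration encodes the emulated cohort", {
  cfg <- reference_config()
  std <- standardized_components(cfg$params)
  frac <- function(comp, v) std$fraction[std$component == comp & std$visit == v]
  expect_equal(frac("A", 1), 0.62, tolerance = 1e-12)
  expect_equal(frac("A", 2), 0.35, tolerance = 1e-12)
  expect_equal(specific_heritability(cfg$params), 0.19, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(std$fraction, std$visit, sum)), c(1, 1),
               tolerance = 1e-12)

  ea <- cfg$groups[cfg$groups$ethnicity == "EA", ]
  expect_equal(sum(ea$n_mz), 46L)
  expect_equal(sum(ea$n_dz), 75L)
  expect_equal(sum(ea$n_singleton), 47L)
  aa <- cfg$groups[cfg$groups$ethnicity == "AA", ]
  expect_equal(sum(aa$n_mz), 25L)
  expect_equal(sum(aa$n_dz), 59L)
  expect_equal(sum(aa$n_singleton), 40L)
  # unit phenotypic variance at both visits on the log scale
  expect_equal(diag(expected_pair_covariance(cfg$params, "MZ"))[1:2], c(1, 1),
               tolerance = 1e-12)
})

test_that("simulation respects counts, determinism and the empty edge case", {
  cfg <- reference_config()
  d1 <- simulate_twin_cohort(cfg, seed = 12)
  d2 <- simulate_twin_cohort(cfg, seed = 12)
  expect_identical(d1, d2)
  d3 <- simulate_twin_cohort(cfg, seed = 13)
  expect_false(identical(d1, d3))

  expect_equal(nrow(d1), sum(cfg$groups$n_mz + cfg$groups$n_dz + cfg$groups$n_singleton))
  expect_equal(sum(d1$singleton), sum(cfg$groups$n_singleton))
  expect_true(all(is.na(d1$pwv2_v1[d1$singleton])))
  expect_true(all(is.na(d1$sex2[d1$singleton])))
  # MZ pairs are sex-concordant and ethnicity is pair-level by construction
  mzc <- d1[d1$zygosity == "MZ" & !d1$singleton, ]
  expect_true(all(mzc$sex1 == mzc$sex2))

  empty_cfg <- twin_sim_config(
    groups = data.frame(ethnicity = "EA", sex = "F",
                        n_mz = 0, n_dz = 0, n_singleton = 0),
    params = truth_params()
  )
  expect_equal(nrow(simulate_twin_cohort(empty_cfg, seed = 1)), 0L)
})

test_that("missingness is MCAR at the configured per-visit rates", {
  cfg <- complete_config(4000, 4000, missingness = c(0.05, 0.2))
  d <- simulate_twin_cohort(cfg, seed = 44)
  n_entries <- 2 * 8000
  rate_v1 <- sum(is.na(d$pwv1_v1), is.na(d$pwv2_v1)) / n_entries
  rate_v2 <- sum(is.na(d$pwv1_v2), is.na(d$pwv2_v2)) / n_entries
  expect_lt(abs(rate_v1 - 0.05), 0.012)
  expect_lt(abs(rate_v2 - 0.20), 0.02)
  # MCAR: observed co-twin values have the same mean whether or not the
  # other visit is missing
  obs <- log(d$pwv1_v1)
  grp <- is.na(d$pwv1_v2)
  diff <- mean(obs[grp], na.rm = TRUE) - mean(obs[!grp], na.rm = TRUE)
  se <- sd(obs, na.rm = TRUE) *
    sqrt(1 / sum(grp & !is.na(obs)) + 1 / sum(!grp & !is.na(obs)))
  expect_lt(abs(diff), 3 * se)
})

test_that("large-sample pair moments match the model-implied covariances", {
  cfg <- complete_config(20000, 20000)
  d <- log_transform_phenotype(simulate_twin_cohort(cfg, seed = 55))
  for (z in c("MZ", "DZ")) {
    Y <- as.matrix(d[d$zygosity == z, c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")])
    Yde <- rbind(Y, Y[, c(3, 4, 1, 2)])   # double entry: labels are arbitrary
    expect_lt(max(abs(unname(cov(Yde)) - expected_pair_covariance(truth_params(), z))),
              0.016)
  }
  # MZ - DZ cross-twin covariance difference identifies V_A / 2 per visit
  cross <- function(z, v) {
    sub <- d[d$zygosity == z, ]
    cov(sub[[paste0("pwv1_v", v)]], sub[[paste0("pwv2_v", v)]])
  }
  VA <- component_covariance(truth_params(), "A")
  expect_lt(abs(cross("MZ", 1) - cross("DZ", 1) - 0.5 * VA[1, 1]), 0.02)
  expect_lt(abs(cross("MZ", 2) - cross("DZ", 2) - 0.5 * VA[2, 2]), 0.02)
})

test_that("refitting large simulated cohorts recovers every standardized component", {
  std_true <- standardized_components(truth_params())$fraction
  est <- sapply(1:3, function(i) {
    d <- sim_log_cohort(10000, 10000, seed = 77 + i)
    f <- fit_cholesky(d, model_spec("AE"))
    standardized_components(f)$fraction
  })
  expect_lt(max(abs(rowMeans(est) - std_true)), 0.01)
})

test_that("generator configs round-trip through YAML and drive identical cohorts", {
  cfg <- reference_config()
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg2$params), unclass(cfg$params), tolerance = 1e-12)
  expect_equal(cfg2$groups, cfg$groups)
  expect_equal(simulate_twin_cohort(cfg2, seed = 4),
               simulate_twin_cohort(cfg, seed = 4), tolerance = 1e-9)
})

test_that("generator configs are validated", {
  expect_error(
    twin_sim_config(groups = data.frame(ethnicity = "EA", sex = "F",
                                        n_mz = -1, n_dz = 0, n_singleton = 0),
                    params = truth_params()),
    "n_mz"
  )
  expect_error(
    twin_sim_config(groups = data.frame(ethnicity = "EA", sex = "F",
                                        n_mz = 1, n_dz = 1, n_singleton = 0),
                    params = chol_params(a11 = 1)),   # no E: singular
    "positive-definite"
  )
})
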