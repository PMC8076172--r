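test_that("degenerate and counting properties of the LRT", {
  d <- sim_log_cohort(60, 60, seed = 71)
  ae1 <- fit_cholesky(d, model_spec("AE"))
  ae2 <- fit_cholesky(d, model_spec("AE"))
  t0 <- lrt(ae1, ae2)
  expect_equal(t0$statistic, 0, tolerance = 1e-6)
  expect_equal(t0$df, 0L)
  expect_equal(t0$p_value, 1)

  ace <- fit_cholesky(d, model_spec("ACE"))
  t1 <- lrt(ace, ae1)
  expect_identical(t1$df, 3L)   # nine vs six free paths, same means model

  ce <- fit_cholesky(d, model_spec("CE"))
  expect_error(lrt(ae1, ce), "not nested")
})

test_that("the e21 = 0 test is calibrated near its nominal level under the null", {
  # truth has e21 = 0, an interior null for this path
  rejections <- vapply(1:200, function(i) {
    d <- sim_log_cohort(100, 100, seed = 7000 + i)
    full <- fit_cholesky(d, model_spec("AE"))
    red <- fit_cholesky(d, model_spec("AE", drop_paths = "e21"))
    lrt(full, red)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("the ladder recovers the generating AE structure with e21 pruned", {
  hits <- vapply(1:50, function(i) {
    d <- sim_log_cohort(1000, 1000, seed = 3000 + i)
    lad <- model_ladder(d)
    pt <- lad$path_tests
    dec <- function(pth) pt$decision[grepl(paste0("^", pth), pt$comparison)]
    lad$selected == "AE" &&
      identical(dec("e21"), "drop") &&
      identical(dec("a21"), "retain") &&
      identical(dec("a22"), "retain")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("with no familial aggregation the AE vs E comparison rarely rejects", {
  # boundary null (all genetic paths zero): standard chi-square reference is
  # conservative, so non-rejection should be at least the nominal 95%
  keep <- vapply(1:100, function(i) {
    cfg <- complete_config(100, 100,
                           params = chol_params(e11 = 1, e21 = 0.3, e22 = 0.9))
    d <- log_transform_phenotype(simulate_twin_cohort(cfg, seed = 4000 + i))
    ae <- fit_cholesky(d, model_spec("AE"))
    e <- fit_cholesky(d, model_spec("E"))
    lrt(ae, e)$p_value >= 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.9)
})

test_that("ladder reports are deterministic for identical data and seed", {
  d <- sim_log_cohort(80, 80, seed = 55)
  l1 <- model_ladder(d, seed = 2)
  l2 <- model_ladder(d, seed = 2)
  expect_identical(tidy(l1), tidy(l2))
  expect_identical(glance(l1), glance(l2))
})

test_that("multigroup homogeneity test counts its degrees of freedom by groups and paths", {
  d <- log_transform_phenotype(simulate_twin_cohort(reference_config(), seed = 66))
  mg <- fit_multigroup(d, model_spec("AE"), groups = c("ethnicity", "sex"))
  expect_equal(length(mg$groups), 4L)
  expect_identical(mg$lrt$df, 3L * 6L)   # (4 - 1) x 6 free AE paths
  expect_gte(mg$lrt$statistic, 0)
})

test_that("cloning one dataset into two groups reproduces the single-group fit", {
  d <- sim_log_cohort(120, 120, seed = 77)
  single <- fit_cholesky(d, model_spec("AE"))
  d2 <- dplyr::bind_rows(
    dplyr::mutate(d, ethnicity = "EA", family_id = paste0(family_id, "-a")),
    dplyr::mutate(d, ethnicity = "AA", family_id = paste0(family_id, "-b"))
  )
  mg <- fit_multigroup(d2, model_spec("AE"), groups = "ethnicity")
  expect_equal(unlist(mg$reduced$params), unlist(single$params), tolerance = 1e-3)
  expect_equal(mg$reduced$deviance, 2 * single$deviance, tolerance = 1e-4)
  expect_equal(mg$lrt$statistic, 0, tolerance = 0.01)
})

test_that("homogeneity test holds its level and detects real group differences", {
  # null: four groups drawn from one truth
  null_cfg <- twin_sim_config(
    groups = data.frame(ethnicity = rep(c("EA", "AA"), each = 2),
                        sex = rep(c("F", "M"), 2),
                        n_mz = 50, n_dz = 50, n_singleton = 0),
    params = truth_params(), mu = c(log(7.1), log(7.6))
  )
  rej_null <- vapply(1:60, function(i) {
    d <- log_transform_phenotype(simulate_twin_cohort(null_cfg, seed = 8000 + i))
    fit_multigroup(d, model_spec("AE"), groups = c("ethnicity", "sex"))$lrt$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej_null), 0.00)
  expect_lte(mean(rej_null), 0.12)

  # power: two groups whose visit-1 heritability differs by 0.3
  low_h2 <- chol_params(a11 = sqrt(0.32), a21 = sqrt(0.16), a22 = sqrt(0.19),
                        e11 = sqrt(0.68), e21 = 0, e22 = sqrt(0.65))
  rej_alt <- vapply(1:10, function(i) {
    d1 <- simulate_twin_cohort(complete_config(500, 500), seed = 9000 + i)
    d2 <- simulate_twin_cohort(complete_config(500, 500, params = low_h2),
                               seed = 9500 + i)
    d2$ethnicity <- "AA"
    d2$family_id <- paste0(d2$family_id, "-b")
    d <- log_transform_phenotype(dplyr::bind_rows(d1, d2))
    fit_multigroup(d, model_spec("AE"), groups = "ethnicity")$lrt$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej_alt), 0.8)
})
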