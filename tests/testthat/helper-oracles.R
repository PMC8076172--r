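# Independent oracles and fixture builders, deliberately coded without
# reusing the package's likelihood machinery.

# Generic multivariate-normal log density via solve()/determinant().
mvn_logdens <- function(x, mu, S) {
  k <- length(x)
  d <- x - mu
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (k * log(2 * pi) + ld + as.numeric(t(d) %*% solve(S) %*% d))
}

# Double-entry Pearson correlation by explicit stacking.
double_entry_oracle <- function(x1, x2) {
  keep <- !is.na(x1) & !is.na(x2)
  stats::cor(c(x1[keep], x2[keep]), c(x2[keep], x1[keep]))
}

# The generating truth used throughout: the packaged AE reference structure.
truth_params <- function() {
  chol_params(
    a11 = sqrt(0.62), a21 = sqrt(0.16), a22 = sqrt(0.19),
    e11 = sqrt(0.38), e21 = 0, e22 = sqrt(0.65)
  )
}

# Single-group complete-pair cohort config built on the reference truth.
complete_config <- function(n_mz, n_dz, params = truth_params(),
                            mu = c(log(7.1), log(7.6)), missingness = c(0, 0)) {
  twin_sim_config(
    groups = data.frame(ethnicity = "EA", sex = "F",
                        n_mz = n_mz, n_dz = n_dz, n_singleton = 0),
    params = params, mu = mu, missingness = missingness
  )
}

sim_log_cohort <- function(n_mz, n_dz, seed, ...) {
  log_transform_phenotype(simulate_twin_cohort(complete_config(n_mz, n_dz, ...),
                                               seed = seed))
}

# A tiny hand-built twin table on the log scale (values arbitrary but fixed).
toy_pairs <- function() {
  tibble::tibble(
    family_id = c("f1", "f2", "f3", "f4"),
    zygosity = c("MZ", "DZ", "MZ", "DZ"),
    ethnicity = c("EA", "EA", "AA", "AA"),
    sex1 = c("F", "M", "F", "F"),
    sex2 = c("F", "F", "F", NA),
    pwv1_v1 = c(0.3, -0.2, 0.1, 0.5),
    pwv1_v2 = c(0.6, 0.1, NA, 0.2),
    pwv2_v1 = c(0.2, 0.0, -0.1, NA),
    pwv2_v2 = c(0.4, NA, 0.3, NA),
    singleton = c(FALSE, FALSE, FALSE, TRUE)
  )
}

random_valid_params <- function() {
  chol_params(
    a11 = runif(1, -1, 1), a21 = runif(1, -1, 1), a22 = runif(1, -1, 1),
    c11 = runif(1, -1, 1), c21 = runif(1, -1, 1), c22 = runif(1, -1, 1),
    e11 = runif(1, 0.2, 1), e21 = runif(1, -1, 1), e22 = runif(1, 0.2, 1)
  )
}

write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
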