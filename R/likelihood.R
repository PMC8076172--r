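# Full-information maximum likelihood machinery.
#
# Each pair contributes the multivariate-normal log density of whatever
# subset of its four slots (twin1 visit1, twin1 visit2, twin2 visit1,
# twin2 visit2) was observed, evaluated under the sub-matrix of the expected
# 4x4 pair covariance and sub-vector of expected means selected by the
# observation pattern. Pairs are grouped by (group, zygosity, pattern) once,
# so an objective evaluation costs one Cholesky factorisation per distinct
# pattern rather than per pair.

slot_visit <- c(1L, 2L, 1L, 2L)

# Precompute pattern-grouped data. `group` is a vector of pair-level group
# labels (or NULL for a single group). Returns cells plus bookkeeping.
fiml_cells <- function(data, covariates = character(), group = NULL) {
  pcols <- phenotype_columns()
  Y <- as.matrix(data[, pcols])
  n <- nrow(Y)
  if (n == 0L) abort("Empty dataset")
  glab <- if (is.null(group)) rep("all", n) else as.character(group)
  if (anyNA(glab)) abort("Missing group label for some pairs")
  covmat <- lapply(covariates, function(stem) {
    cols <- paste0(stem, c("1", "1", "2", "2"), "_v", c(1, 2, 1, 2))
    miss <- setdiff(cols, names(data))
    if (length(miss)) abort(paste0("Missing covariate column(s): ", paste(miss, collapse = ", ")))
    as.matrix(data[, cols])
  })
  names(covmat) <- covariates

  obs <- !is.na(Y)
  for (stem in covariates) {
    bad <- which(obs & is.na(covmat[[stem]]), arr.ind = TRUE)
    if (nrow(bad)) {
      abort(paste0("Covariate '", stem, "' missing for an observed phenotype entry, family_id ",
                   data$family_id[bad[1, 1]]))
    }
  }

  pat_key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  key <- paste(glab, data$zygosity, pat_key, sep = "|")
  idx_by_key <- split(seq_len(n), key)
  levels_g <- sort(unique(glab))

  cells <- lapply(idx_by_key, function(idx) {
    o <- obs[idx[1], ]
    slots <- which(o)
    if (!length(slots)) return(NULL)  # no observations: log-lik contribution 0
    list(
      g = match(glab[idx[1]], levels_g),
      zyg = data$zygosity[idx[1]],
      slots = slots,
      Y = Y[idx, slots, drop = FALSE],
      X = lapply(covmat, function(m) m[idx, slots, drop = FALSE]),
      n = length(idx)
    )
  })
  cells <- cells[!vapply(cells, is.null, logical(1))]
  list(cells = cells, group_levels = levels_g, n_pairs = n,
       covariates = covariates)
}

# -2 log likelihood given path params (shared across groups) and a list of
# means_model objects, one per group level.
fiml_m2ll <- function(prep, params, means_by_group) {
  sig <- list(MZ = expected_pair_covariance(params, "MZ"),
              DZ = expected_pair_covariance(params, "DZ"))
  for (z in c("MZ", "DZ")) {
    ev <- eigen(sig[[z]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) {
      return(1e10 + 1e8 * (1e-10 - min(ev)))
    }
  }
  total <- 0
  for (cell in prep$cells) {
    mm <- means_by_group[[cell$g]]
    S <- sig[[cell$zyg]][cell$slots, cell$slots, drop = FALSE]
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    k <- length(cell$slots)
    mu_slot <- mm$mu[slot_visit[cell$slots]]
    D <- cell$Y - matrix(mu_slot, cell$n, k, byrow = TRUE)
    if (!is.null(mm$beta)) {
      for (stem in names(mm$beta)) {
        b <- mm$beta[[stem]][slot_visit[cell$slots]]
        D <- D - cell$X[[stem]] * matrix(b, cell$n, k, byrow = TRUE)
      }
    }
    Z <- backsolve(R, t(D), transpose = TRUE)
    total <- total +
      cell$n * k * log(2 * pi) +
      2 * cell$n * sum(log(diag(R))) +
      sum(Z * Z)
  }
  total
}

#' Log likelihood of a single twin pair
#'
#' The multivariate-normal log density of the observed entries of one pair
#' (row of a twin table) under the bivariate Cholesky model. A singleton
#' reduces to the within-twin marginal; a pair with nothing observed
#' contributes exactly 0.
#'
#' @param pair A one-row twin table (log-scale phenotype).
#' @param params A [chol_params()] object.
#' @param means A [means_model()] object.
#' @return The log density (scalar).
#' @export
pair_loglik <- function(pair, params, means = means_model()) {
  stopifnot(nrow(pair) == 1L)
  y <- as.numeric(pair[1, phenotype_columns()])
  slots <- which(!is.na(y))
  if (!length(slots)) return(0)
  S <- expected_pair_covariance(params, pair$zygosity[1])[slots, slots, drop = FALSE]
  mu <- means$mu[slot_visit[slots]]
  if (!is.null(means$beta)) {
    for (stem in names(means$beta)) {
      cols <- paste0(stem, c("1", "1", "2", "2"), "_v", c(1, 2, 1, 2))[slots]
      xv <- as.numeric(pair[1, cols])
      if (anyNA(xv)) {
        abort(paste0("Covariate '", stem, "' missing for observed entries of family_id ",
                     pair$family_id[1]))
      }
      mu <- mu + means$beta[[stem]][slot_visit[slots]] * xv
    }
  }
  R <- tryCatch(chol(S), error = function(e) {
    abort(paste0("Singular expected covariance for family_id ", pair$family_id[1]))
  })
  d <- y[slots] - mu
  z <- backsolve(R, d, transpose = TRUE)
  -0.5 * (length(slots) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z))
}

#' Deviance (-2 log likelihood) of a dataset
#'
#' Minus twice the sum of [pair_loglik()] over all pairs, the quantity that
#' nested likelihood-ratio tests difference.
#'
#' @param data A twin table on the analysis (log) scale.
#' @param params A [chol_params()] object.
#' @param means A [means_model()] object, or a named list of them (one per
#'   level of `group`).
#' @param group Optional pair-level group labels (character vector or column
#'   name in `data`).
#' @return The deviance (scalar).
#' @export
dataset_m2ll <- function(data, params, means = means_model(), group = NULL) {
  if (is.character(group) && length(group) == 1L && group %in% names(data)) {
    group <- data[[group]]
  }
  covs <- if (inherits(means, "means_model")) names(means$beta) else names(means[[1]]$beta)
  prep <- fiml_cells(data, covariates = covs %||% character(), group = group)
  means_by_group <- if (inherits(means, "means_model")) {
    rep(list(means), length(prep$group_levels))
  } else {
    if (!all(prep$group_levels %in% names(means))) {
      abort("`means` must be a named list covering every group level")
    }
    means[prep$group_levels]
  }
  fiml_m2ll(prep, params, means_by_group)
}
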