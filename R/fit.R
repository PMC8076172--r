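# Encode/decode the free-parameter vector: free paths first (shared across
# groups), then per group (mu_v1, mu_v2, then beta_v1, beta_v2 per covariate).

n_mean_par <- function(spec) 2L + 2L * length(spec$covariates)

par_names <- function(spec, group_levels) {
  mp <- c("mu_v1", "mu_v2",
          if (length(spec$covariates))
            paste0("beta_", rep(spec$covariates, each = 2), "_v", 1:2))
  c(spec$free_paths,
    unlist(lapply(group_levels, function(g) {
      if (length(group_levels) == 1L) mp else paste0(mp, "[", g, "]")
    })))
}

decode_par <- function(par, spec, n_groups) {
  np <- n_free_paths(spec)
  paths <- setNames(numeric(9), path_names())
  paths[spec$free_paths] <- par[seq_len(np)]
  params <- do.call(chol_params, as.list(paths))
  nm <- n_mean_par(spec)
  means <- lapply(seq_len(n_groups), function(g) {
    block <- par[np + (g - 1L) * nm + seq_len(nm)]
    beta <- NULL
    if (length(spec$covariates)) {
      beta <- lapply(seq_along(spec$covariates), function(i) block[2L + 2L * (i - 1L) + 1:2])
      names(beta) <- spec$covariates
    }
    means_model(mu = block[1:2], beta = beta)
  })
  list(params = params, means = means)
}

# Moment-based start values: visit-wise individual variances split across the
# included components; cross paths start at a tenth of the within scale. The
# c paths start at a small non-zero multiple of the SD because the deviance
# is an even function of each Cholesky factor column, so an exact zero start
# is a stationary point the optimizer would never leave.
start_values <- function(prep_data, spec, group_levels, group_lab) {
  v1 <- c(prep_data$pwv1_v1, prep_data$pwv2_v1)
  v2 <- c(prep_data$pwv1_v2, prep_data$pwv2_v2)
  s1 <- sqrt(max(var(v1, na.rm = TRUE), 1e-6))
  s2 <- sqrt(max(var(v2, na.rm = TRUE), 1e-6))
  comps <- spec$components
  share <- if (setequal(comps, c("A", "C", "E"))) c(A = 0.4, C = 0.2, E = 0.4)
           else if (setequal(comps, c("A", "E"))) c(A = 0.5, C = 0, E = 0.5)
           else if (setequal(comps, c("C", "E"))) c(A = 0, C = 0.5, E = 0.5)
           else c(A = 0, C = 0, E = 1)
  paths <- setNames(numeric(9), path_names())
  for (comp in comps) {
    pre <- tolower(comp)
    sh <- max(share[comp], 0.15)
    paths[paste0(pre, "11")] <- sqrt(sh) * s1
    x21 <- if (paste0(pre, "21") %in% spec$free_paths) 0.1 * sqrt(sh) * s2 else 0
    paths[paste0(pre, "21")] <- x21
    paths[paste0(pre, "22")] <- sqrt(max(sh * s2^2 - x21^2, 0.1 * sh * s2^2))
  }
  paths[setdiff(path_names(), spec$free_paths)] <- 0
  start <- paths[spec$free_paths]
  for (g in group_levels) {
    keep <- group_lab == g
    m1 <- mean(c(prep_data$pwv1_v1[keep], prep_data$pwv2_v1[keep]), na.rm = TRUE)
    m2 <- mean(c(prep_data$pwv1_v2[keep], prep_data$pwv2_v2[keep]), na.rm = TRUE)
    if (!is.finite(m1)) m1 <- 0
    if (!is.finite(m2)) m2 <- 0
    start <- c(start, m1, m2, rep(0, 2L * length(spec$covariates)))
  }
  unname(start)
}

numeric_grad <- function(fn, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    hi <- h * (1 + abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    (fn(up) - fn(dn)) / (2 * hi)
  }, numeric(1))
}

run_optim <- function(obj, start, maxit = 1000) {
  o1 <- optim(start, obj, method = "BFGS",
              control = list(maxit = maxit, reltol = 1e-12))
  # polish: a second quasi-Newton pass from the solution guards against
  # premature line-search termination
  o2 <- optim(o1$par, obj, method = "BFGS",
              control = list(maxit = maxit, reltol = 1e-12))
  if (o2$value <= o1$value) o2 else o1
}

#' Fit a bivariate Cholesky twin model by FIML
#'
#' Minimises the full-information -2 log likelihood over the free path
#' coefficients and means-model parameters. Pairs with missing entries and
#' singletons contribute the density of their observed entries only. The
#' optimiser is quasi-Newton (BFGS) with numerical gradients, a moment-based
#' start, and optional seed-controlled perturbed restarts; parameter vectors
#' whose implied pair covariance has an eigenvalue below 1e-10 are rejected
#' with a large penalised deviance. The reported factors are reflected so
#' diagonal paths are non-negative.
#'
#' @param data A twin table on the analysis (log) scale.
#' @param spec A [model_spec()].
#' @param group Optional pair-level grouping: a column name in `data` or a
#'   vector of labels. Paths are shared across groups; intercepts (and
#'   covariate coefficients) are group-specific.
#' @param start Optional numeric start vector (free paths then means blocks).
#' @param n_starts Number of optimisation starts (first is moment-based,
#'   the rest perturbed); up to 5 extra restarts are attempted automatically
#'   if the optimiser reports non-convergence.
#' @param seed Seed for the restart perturbations.
#' @return An object of class `cholesky_fit` with elements `params`
#'   ([chol_params()]), `means` (named list of [means_model()] per group),
#'   `deviance`, `n_free`, `converged`, `gradient_norm`, `n_restarts`.
#' @export
fit_cholesky <- function(data, spec = model_spec("ACE"), group = NULL,
                         start = NULL, n_starts = 1, seed = 1) {
  group_col <- NULL
  if (is.character(group) && length(group) == 1L && group %in% names(data)) {
    group_col <- group
    group <- data[[group]]
  }
  prep <- fiml_cells(data, covariates = spec$covariates, group = group)
  G <- length(prep$group_levels)
  glab <- if (is.null(group)) rep("all", nrow(data)) else as.character(group)
  if (is.null(start)) {
    start <- start_values(data, spec, prep$group_levels, glab)
  }
  obj <- function(par) {
    dec <- decode_par(par, spec, G)
    fiml_m2ll(prep, dec$params, dec$means)
  }

  starts <- list(start)
  if (n_starts > 1) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i) {
      start * (1 + runif(length(start), -0.3, 0.3)) +
        runif(length(start), -0.05, 0.05)
    }))
    starts <- c(starts, extra)
  }

  best <- NULL
  tried <- 0L
  for (s in starts) {
    tried <- tried + 1L
    o <- run_optim(obj, s)
    if (is.null(best) || o$value < best$value) best <- o
  }
  # automatic perturbed restarts on non-convergence
  auto <- 0L
  while (best$convergence != 0 && auto < 5L) {
    auto <- auto + 1L
    s <- with_seed(child_seed(seed, auto), {
      best$par * (1 + runif(length(start), -0.2, 0.2))
    })
    o <- run_optim(obj, s)
    tried <- tried + 1L
    if (o$value < best$value || (o$convergence == 0 && o$value <= best$value + 1e-8)) {
      best <- o
    }
  }

  dec <- decode_par(best$par, spec, G)
  grad <- numeric_grad(obj, best$par)
  means <- setNames(dec$means, prep$group_levels)
  structure(
    list(
      params = reflect_params(dec$params),
      means = means,
      spec = spec,
      deviance = best$value,
      n_free = length(best$par),
      converged = best$convergence == 0,
      gradient_norm = sqrt(sum(grad^2)),
      n_restarts = tried,
      n_pairs = prep$n_pairs,
      group_levels = prep$group_levels,
      group_col = group_col,
      data = data,
      group_labels = glab,
      prep = prep
    ),
    class = "cholesky_fit"
  )
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat("Bivariate Cholesky fit (", paste(x$spec$components, collapse = ""),
      if (length(x$spec$drop_paths)) paste0(", ", paste(x$spec$drop_paths, collapse = "="),
                                            " = 0") else "",
      ")\n", sep = "")
  cat("  pairs:", x$n_pairs,
      " deviance:", format(x$deviance, digits = 10),
      " free parameters:", x$n_free, "\n")
  cat("  converged:", x$converged,
      " |grad|:", format(x$gradient_norm, digits = 3), "\n")
  print(x$params)
  invisible(x)
}
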