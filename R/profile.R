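#' Profile-likelihood confidence interval for a derived statistic
#'
#' Likelihood-based interval for any quantity computable from the fitted
#' paths (e.g. `"h2_v1"`, `"specific_h2"`, `"r_g"`, `"h2_delta"`): the
#' bounds are the values of the quantity at which the profiled deviance
#' rises above the minimum by the chi-square(1) quantile for the requested
#' level (3.84 at 0.95). For variance-fraction quantities the constraint is
#' imposed exactly by solving for one "pivot" path coefficient given the
#' target value and re-optimising the remaining parameters; correlation
#' quantities use a quadratic-penalty profile instead. Searches are
#' warm-started along the profile path and respect the quantity's natural
#' boundaries (fractions in [0, 1], correlations in [-1, 1]); if the
#' deviance never reaches the cutoff before a boundary, that side is
#' reported at the boundary and flagged one-sided.
#'
#' @param fit A converged `cholesky_fit`.
#' @param quantity Name of a column of [derived_stats()].
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `quantity`, `estimate`, `level`, `lower`,
#'   `upper`, `lower_at_boundary`, `upper_at_boundary`.
#' @export
profile_ci <- function(fit, quantity = "h2_v1", level = 0.95) {
  stopifnot(inherits(fit, "cholesky_fit"))
  if (!fit$converged) warn("Profiling a fit that did not report convergence")
  spec <- fit$spec
  G <- length(fit$group_levels)
  prep <- fit$prep
  obj_full <- function(par) {
    dec <- decode_par(par, spec, G)
    fiml_m2ll(prep, dec$params, dec$means)
  }
  qfun <- function(par) {
    derived_quantity(decode_par(par, spec, G)$params, quantity)
  }
  par_hat <- encode_fit_par(fit)
  q_hat <- qfun(par_hat)
  if (is.na(q_hat)) abort(paste0("Quantity '", quantity, "' is undefined at the estimate"))
  dev_min <- fit$deviance
  cutoff <- dev_min + qchisq(level, df = 1)
  bounds <- quantity_bounds(quantity)

  piv <- profile_pivot(quantity)
  profiled <- if (!is.null(piv) && piv$pivot %in% spec$free_paths) {
    profiled_pivot(piv, spec, G, prep, par_hat)
  } else {
    profiled_penalty(obj_full, qfun, par_hat)
  }

  search_side <- function(side) {
    # side = -1 for the lower bound, +1 for the upper
    boundary <- if (side < 0) bounds[1] else bounds[2]
    step <- max(0.02, 0.15 * abs(boundary - q_hat))
    t_prev <- q_hat
    start <- NULL
    repeat {
      t_next <- q_hat + side * step
      hit_boundary <- (side < 0 && t_next <= boundary) ||
        (side > 0 && t_next >= boundary)
      if (hit_boundary) t_next <- boundary + side * (-1e-9)
      pr <- profiled(t_next, start)
      g_next <- pr$dev - cutoff
      if (g_next > 0) {
        # bracketed: bisect between t_prev and t_next with warm starts
        lo_t <- t_prev; hi_t <- t_next
        warm <- pr$start
        for (i in 1:20) {
          mid <- (lo_t + hi_t) / 2
          pm <- profiled(mid, warm)
          warm <- pm$start
          if (pm$dev - cutoff > 0) hi_t <- mid else lo_t <- mid
          if (abs(hi_t - lo_t) < 1.5e-3) break
        }
        return(list(bound = (lo_t + hi_t) / 2, at_boundary = FALSE))
      }
      if (hit_boundary) {
        return(list(bound = boundary, at_boundary = TRUE))
      }
      t_prev <- t_next
      start <- pr$start
      step <- step * 1.6
    }
  }

  lo <- search_side(-1)
  hi <- search_side(+1)
  if (lo$at_boundary || hi$at_boundary) {
    inform(paste0("Profile interval for ", quantity,
                  " reached the feasible boundary; reported one-sided"))
  }
  tibble::tibble(
    quantity = quantity, estimate = q_hat, level = level,
    lower = min(lo$bound, q_hat), upper = max(hi$bound, q_hat),
    lower_at_boundary = lo$at_boundary, upper_at_boundary = hi$at_boundary
  )
}

# Quadratic-penalty profiler: minimise deviance + w (q - t)^2 over all free
# parameters. Used where no exact pivot substitution exists.
profiled_penalty <- function(obj_full, qfun, par_hat) {
  function(t, start) {
    if (is.null(start)) start <- par_hat
    pen <- function(par) obj_full(par) + 1e6 * (qfun(par) - t)^2
    cur <- optim(start, pen, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-9))$par
    list(dev = obj_full(cur), start = cur)
  }
}

# Exact substitution: for variance-fraction quantities q = num/(num + rest),
# one squared path (the pivot) can be solved from the target and the other
# parameters: pivot^2 = t/(1-t) * rest - already. A negative solution means
# the target is infeasible given the other parameters, which the inner
# objective penalises so the optimiser moves back into the feasible region.
profile_pivot <- function(quantity) {
  sq <- function(p, nm) p[[nm]]^2
  d2 <- function(p, pre) (p[[paste0(pre, "21")]] - p[[paste0(pre, "11")]])^2 +
    p[[paste0(pre, "22")]]^2
  v2rest <- function(p, skip) {
    tot <- 0
    for (nm in c("a21", "a22", "c21", "c22", "e21", "e22")) {
      if (nm != skip) tot <- tot + sq(p, nm)
    }
    tot
  }
  switch(
    quantity,
    h2_v1 = list(pivot = "a11",
                 sq_value = function(t, p) t / (1 - t) * (sq(p, "c11") + sq(p, "e11"))),
    c2_v1 = list(pivot = "c11",
                 sq_value = function(t, p) t / (1 - t) * (sq(p, "a11") + sq(p, "e11"))),
    e2_v1 = list(pivot = "e11",
                 sq_value = function(t, p) t / (1 - t) * (sq(p, "a11") + sq(p, "c11"))),
    h2_v2 = list(pivot = "a22",
                 sq_value = function(t, p) {
                   rest <- sq(p, "c21") + sq(p, "c22") + sq(p, "e21") + sq(p, "e22")
                   t / (1 - t) * rest - sq(p, "a21")
                 }),
    c2_v2 = list(pivot = "c22",
                 sq_value = function(t, p) {
                   rest <- sq(p, "a21") + sq(p, "a22") + sq(p, "e21") + sq(p, "e22")
                   t / (1 - t) * rest - sq(p, "c21")
                 }),
    e2_v2 = list(pivot = "e22",
                 sq_value = function(t, p) {
                   rest <- sq(p, "a21") + sq(p, "a22") + sq(p, "c21") + sq(p, "c22")
                   t / (1 - t) * rest - sq(p, "e21")
                 }),
    specific_h2 = list(pivot = "a22",
                       sq_value = function(t, p) t / (1 - t) * v2rest(p, "a22")),
    h2_delta = list(pivot = "a22",
                    sq_value = function(t, p) {
                      t / (1 - t) * (d2(p, "c") + d2(p, "e")) -
                        (p$a21 - p$a11)^2
                    }),
    c2_delta = list(pivot = "c22",
                    sq_value = function(t, p) {
                      t / (1 - t) * (d2(p, "a") + d2(p, "e")) -
                        (p$c21 - p$c11)^2
                    }),
    e2_delta = list(pivot = "e22",
                    sq_value = function(t, p) {
                      t / (1 - t) * (d2(p, "a") + d2(p, "c")) -
                        (p$e21 - p$e11)^2
                    }),
    NULL
  )
}

profiled_pivot <- function(piv, spec, G, prep, par_hat) {
  free <- spec$free_paths
  keep <- free != piv$pivot
  np <- length(free)
  start0 <- par_hat[c(which(keep), seq(np + 1L, length(par_hat)))]
  function(t, start) {
    if (is.null(start)) start <- start0
    objr <- function(par) {
      paths <- setNames(numeric(9), path_names())
      paths[free[keep]] <- par[seq_len(sum(keep))]
      p <- as.list(paths)
      val <- piv$sq_value(t, p)
      if (!is.finite(val)) return(1e10)
      if (val < 0) return(1e10 + 1e6 * (-val))
      paths[piv$pivot] <- sqrt(val)
      full_par <- c(paths[free], par[seq(sum(keep) + 1L, length(par))])
      dec <- decode_par(unname(full_par), spec, G)
      fiml_m2ll(prep, dec$params, dec$means)
    }
    o <- optim(start, objr, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-10))
    list(dev = o$value, start = o$par)
  }
}

# Re-encode a fit's parameters into the optimiser vector layout.
encode_fit_par <- function(fit) {
  spec <- fit$spec
  paths <- unlist(fit$params)[spec$free_paths]
  means <- unlist(lapply(fit$means, function(mm) {
    c(mm$mu, unlist(mm$beta))
  }))
  unname(c(paths, means))
}
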