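#' Likelihood-ratio test between nested Cholesky fits
#'
#' The deviance difference between a reduced model (some paths fixed to
#' zero, or a component removed) and the full model it is nested in,
#' referred to the chi-square distribution with df equal to the difference
#' in free parameters. Standard chi-square reference distributions are used
#' throughout, including for variance components whose null lies on the
#' boundary of the parameter space, where the test is conservative.
#'
#' @param full,reduced `cholesky_fit` objects; `reduced$spec` must be nested
#'   in `full$spec`.
#' @param tol Tolerance below which a negative deviance difference is
#'   clipped to zero; beyond it a refit warning is issued.
#' @return An object of class `lrt_result` with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced, tol = 1e-4) {
  if (!spec_is_nested(reduced$spec, full$spec)) {
    abort("`reduced` is not nested in `full`")
  }
  df <- full$n_free - reduced$n_free
  if (df < 0) abort("`reduced` has more free parameters than `full`")
  stat <- reduced$deviance - full$deviance
  if (stat < -tol) {
    warn(paste0("Negative chi-square (", format(stat, digits = 4),
                "): the full model may need refitting from better starts"))
  }
  stat <- max(stat, 0)
  p <- if (df == 0L) as.numeric(stat <= tol) else pchisq(stat, df, lower.tail = FALSE)
  structure(
    list(
      statistic = stat, df = df, p_value = p,
      deviance_full = full$deviance, deviance_reduced = reduced$deviance,
      full_label = paste(full$spec$components, collapse = ""),
      reduced_label = paste0(paste(reduced$spec$components, collapse = ""),
                             if (length(reduced$spec$drop_paths))
                               paste0(" (", paste(reduced$spec$drop_paths, collapse = ","),
                                      " = 0)") else "")
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: chi-square(%d) = %.3f, p = %.4g\n",
              x$full_label, x$reduced_label, x$df, x$statistic, x$p_value))
  invisible(x)
}

ladder_row <- function(comparison, test) {
  tibble::tibble(
    comparison = comparison,
    deviance_full = test$deviance_full,
    deviance_reduced = test$deviance_reduced,
    chisq = test$statistic,
    df = test$df,
    p_value = test$p_value
  )
}

#' The nested likelihood-ratio model ladder
#'
#' Runs the standard twin-model selection sequence on a two-visit dataset:
#' fit ACE, AE, CE and E, compare ACE vs AE, ACE vs CE and AE vs E (3 df
#' each); select the most parsimonious model not significantly worse than
#' ACE (preferring the lower deviance when both AE and CE survive, and E if
#' it survives against the selected reduction); then, within the selected
#' model, test each cross/specific path (`e21 = 0`, `a21 = 0`, `a22 = 0`,
#' 1 df each) and drop those that are non-significant to form the final
#' model. A rung whose fit fails is recorded and the ladder continues.
#'
#' @param data A twin table on the analysis (log) scale.
#' @param covariates Covariate stems for the means model (e.g. `"map"`).
#' @param group Optional grouping passed to [fit_cholesky()].
#' @param alpha Significance level used for the selection decisions.
#' @param n_starts,seed Optimiser settings passed to [fit_cholesky()].
#' @return An object of class `chol_ladder` with `tests` (component rungs),
#'   `path_tests`, `selected`, `final_spec` and `final_fit`.
#' @export
model_ladder <- function(data, covariates = character(), group = NULL,
                         alpha = 0.05, n_starts = 1, seed = 1) {
  safe_fit <- function(spec) {
    tryCatch(
      fit_cholesky(data, spec, group = group, n_starts = n_starts, seed = seed),
      error = function(e) structure(list(error = conditionMessage(e)), class = "failed_fit")
    )
  }
  ok <- function(f) !inherits(f, "failed_fit")
  specs <- list(
    ACE = model_spec("ACE", covariates = covariates),
    AE = model_spec("AE", covariates = covariates),
    CE = model_spec("CE", covariates = covariates),
    E = model_spec("E", covariates = covariates)
  )
  fits <- lapply(specs, safe_fit)

  tests <- tibble::tibble()
  add_test <- function(tests, label, full, reduced) {
    if (ok(full) && ok(reduced)) {
      dplyr::bind_rows(tests, ladder_row(label, lrt(full, reduced)))
    } else {
      dplyr::bind_rows(tests, tibble::tibble(
        comparison = label, deviance_full = NA_real_, deviance_reduced = NA_real_,
        chisq = NA_real_, df = NA_integer_, p_value = NA_real_
      ))
    }
  }
  tests <- add_test(tests, "ACE vs AE", fits$ACE, fits$AE)
  tests <- add_test(tests, "ACE vs CE", fits$ACE, fits$CE)
  tests <- add_test(tests, "AE vs E", fits$AE, fits$E)

  p_of <- function(label) {
    v <- tests$p_value[tests$comparison == label]
    if (length(v)) v[1] else NA_real_
  }
  selected <- "ACE"
  keep_ae <- ok(fits$AE) && !is.na(p_of("ACE vs AE")) && p_of("ACE vs AE") >= alpha
  keep_ce <- ok(fits$CE) && !is.na(p_of("ACE vs CE")) && p_of("ACE vs CE") >= alpha
  if (keep_ae && keep_ce) {
    selected <- if (fits$AE$deviance <= fits$CE$deviance) "AE" else "CE"
  } else if (keep_ae) {
    selected <- "AE"
  } else if (keep_ce) {
    selected <- "CE"
  }
  if (selected == "AE" && ok(fits$E) &&
      !is.na(p_of("AE vs E")) && p_of("AE vs E") >= alpha) {
    selected <- "E"
  }

  sel_spec <- specs[[selected]]
  sel_fit <- fits[[selected]]
  candidate_paths <- intersect(c("e21", "a21", "a22"), sel_spec$free_paths)
  path_tests <- tibble::tibble()
  droppable <- character()
  if (ok(sel_fit)) {
    for (pth in candidate_paths) {
      red_spec <- model_spec(paste(sel_spec$components, collapse = ""),
                             drop_paths = c(sel_spec$drop_paths, pth),
                             covariates = covariates)
      red_fit <- safe_fit(red_spec)
      if (ok(red_fit)) {
        t <- lrt(sel_fit, red_fit)
        drop <- t$p_value >= alpha
        path_tests <- dplyr::bind_rows(
          path_tests,
          dplyr::mutate(ladder_row(paste0(pth, " != 0 vs ", pth, " = 0"), t),
                        decision = if (drop) "drop" else "retain")
        )
        if (drop) droppable <- c(droppable, pth)
      } else {
        path_tests <- dplyr::bind_rows(path_tests, tibble::tibble(
          comparison = paste0(pth, " = 0"), deviance_full = NA_real_,
          deviance_reduced = NA_real_, chisq = NA_real_, df = NA_integer_,
          p_value = NA_real_, decision = "fit failed"
        ))
      }
    }
  }
  final_spec <- model_spec(paste(sel_spec$components, collapse = ""),
                           drop_paths = c(sel_spec$drop_paths, droppable),
                           covariates = covariates)
  final_fit <- if (length(droppable)) safe_fit(final_spec) else sel_fit

  structure(
    list(fits = fits, tests = tests, path_tests = path_tests,
         selected = selected, final_spec = final_spec, final_fit = final_fit,
         alpha = alpha, seed = seed),
    class = "chol_ladder"
  )
}

#' @export
print.chol_ladder <- function(x, ...) {
  cat("Model ladder (alpha =", x$alpha, ")\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  if (nrow(x$path_tests)) {
    cat("Path tests within", x$selected, "model:\n")
    print(as.data.frame(x$path_tests), row.names = FALSE)
  }
  cat("Selected:", x$selected, "; final model:",
      paste(x$final_spec$components, collapse = ""),
      if (length(x$final_spec$drop_paths))
        paste0("with ", paste(x$final_spec$drop_paths, collapse = ", "), " = 0") else "",
      "\n")
  invisible(x)
}

#' Multigroup fit and homogeneity test
#'
#' Fits the model separately in every group (the full, heterogeneous model:
#' all paths and means group-specific) and with the path coefficients
#' constrained equal across groups while intercepts stay group-specific
#' (the reduced, homogeneous model), and compares them by likelihood-ratio
#' test with df = (groups - 1) x number of free paths. Opposite-sex DZ pairs
#' have no pair-level sex and are excluded, with a message, whenever `"sex"`
#' is part of the grouping.
#'
#' @param data A twin table on the analysis (log) scale.
#' @param spec A [model_spec()].
#' @param groups Pair-level grouping columns; `"sex"` means the pair-level
#'   sex (same-sex pairs only).
#' @param n_starts,seed Optimiser settings.
#' @return An object of class `multigroup_fit` with per-group fits (`full`),
#'   the constrained fit (`reduced`) and the homogeneity `lrt`.
#' @export
fit_multigroup <- function(data, spec = model_spec("AE"),
                           groups = c("ethnicity", "sex"),
                           n_starts = 1, seed = 1) {
  lab_parts <- lapply(groups, function(g) {
    if (g == "sex") pair_sex(data) else data[[g]]
  })
  glab <- do.call(paste, c(lab_parts, sep = "."))
  if ("sex" %in% groups) {
    os <- pair_sex(data) == "OS"
    if (any(os)) {
      inform(paste0("Excluding ", sum(os),
                    " opposite-sex pair(s) from the sex-grouped analysis"))
      data <- data[!os, , drop = FALSE]
      glab <- glab[!os]
    }
  }
  levels_g <- sort(unique(glab))
  if (length(levels_g) < 2L) abort("Need at least two non-empty groups")

  full_fits <- lapply(levels_g, function(g) {
    sub <- data[glab == g, , drop = FALSE]
    if (!nrow(sub)) abort(paste0("Empty group: ", g))
    fit_cholesky(sub, spec, n_starts = n_starts, seed = seed)
  })
  names(full_fits) <- levels_g
  full_dev <- sum(vapply(full_fits, `[[`, numeric(1), "deviance"))
  full_nfree <- sum(vapply(full_fits, `[[`, numeric(1), "n_free"))

  reduced <- fit_cholesky(data, spec, group = glab,
                          n_starts = n_starts, seed = seed)

  df <- (length(levels_g) - 1L) * n_free_paths(spec)
  stat <- max(reduced$deviance - full_dev, 0)
  hom <- structure(
    list(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         deviance_full = full_dev, deviance_reduced = reduced$deviance,
         full_label = "group-specific paths",
         reduced_label = "paths equal across groups"),
    class = "lrt_result"
  )
  structure(
    list(full = full_fits, reduced = reduced, lrt = hom,
         groups = levels_g, spec = spec,
         converged = all(vapply(full_fits, `[[`, logical(1), "converged")) &&
           reduced$converged),
    class = "multigroup_fit"
  )
}

#' @export
print.multigroup_fit <- function(x, ...) {
  cat("Multigroup Cholesky fit over", length(x$groups), "groups:",
      paste(x$groups, collapse = ", "), "\n")
  print(x$lrt)
  invisible(x)
}
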