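#' Tidy a fitted bivariate Cholesky model
#'
#' @param x A `cholesky_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, `fixed`
#'   (paths constrained to zero by the model spec), and `group` for
#'   means-model terms.
#' @method tidy cholesky_fit
#' @export
tidy.cholesky_fit <- function(x, ...) {
  paths <- tibble::tibble(
    term = path_names(),
    estimate = unlist(x$params)[path_names()],
    fixed = !path_names() %in% x$spec$free_paths,
    group = NA_character_
  )
  means <- purrr::imap_dfr(x$means, function(mm, g) {
    tibble::tibble(
      term = c("mu_v1", "mu_v2",
               if (!is.null(mm$beta))
                 paste0("beta_", rep(names(mm$beta), each = 2), "_v", 1:2)),
      estimate = c(mm$mu, unlist(mm$beta)),
      fixed = FALSE,
      group = g
    )
  })
  dplyr::bind_rows(paths, means)
}

#' Model-level summary of a Cholesky fit
#'
#' @param x A `cholesky_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `deviance`, `n_free`, `n_pairs`, `converged`,
#'   `gradient_norm`, `n_restarts`.
#' @method glance cholesky_fit
#' @export
glance.cholesky_fit <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance, n_free = x$n_free, n_pairs = x$n_pairs,
    converged = x$converged, gradient_norm = x$gradient_norm,
    n_restarts = x$n_restarts
  )
}

#' @method tidy lrt_result
#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(
    comparison = paste(x$full_label, "vs", x$reduced_label),
    deviance_full = x$deviance_full, deviance_reduced = x$deviance_reduced,
    chisq = x$statistic, df = x$df, p_value = x$p_value
  )
}

#' @method tidy chol_ladder
#' @export
tidy.chol_ladder <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$tests, stage = "components", decision = NA_character_),
    if (nrow(x$path_tests)) dplyr::mutate(x$path_tests, stage = "paths")
  ) |>
    dplyr::relocate("stage")
}

#' @method glance chol_ladder
#' @export
glance.chol_ladder <- function(x, ...) {
  tibble::tibble(
    selected = x$selected,
    final_model = paste(x$final_spec$components, collapse = ""),
    dropped_paths = paste(x$final_spec$drop_paths, collapse = ","),
    final_deviance = if (inherits(x$final_fit, "cholesky_fit"))
      x$final_fit$deviance else NA_real_,
    alpha = x$alpha
  )
}

#' @method tidy multigroup_fit
#' @export
tidy.multigroup_fit <- function(x, ...) tidy(x$lrt)

#' @method glance multigroup_fit
#' @export
glance.multigroup_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    chisq = x$lrt$statistic, df = x$lrt$df, p_value = x$lrt$p_value,
    converged = x$converged
  )
}
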