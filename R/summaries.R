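#' Twin correlations by stratum
#'
#' Double-entry Pearson correlations between co-twins, per visit and stratum
#' (by default ethnicity x zygosity, the classic twin-correlation table).
#' Each complete pair contributes both orderings (twin1, twin2) and
#' (twin2, twin1), which makes the estimate exactly invariant to how twins
#' were labelled within a pair. Pairs with either twin unobserved at the
#' requested visit, and singletons, contribute nothing. Strata with fewer
#' complete pairs than `min_pairs` are reported as unavailable (`NA`), never
#' fabricated.
#'
#' @param data A twin table.
#' @param visit Visits to tabulate, subset of `c(1, 2)`.
#' @param strata Character vector of pair-level stratifying columns.
#' @param min_pairs Minimum complete pairs per stratum (default 3).
#' @return A tibble with the stratum keys, `visit`, `n_pairs` and `r`.
#' @export
twin_correlations <- function(data, visit = c(1, 2),
                              strata = c("ethnicity", "zygosity"),
                              min_pairs = 3) {
  stopifnot(all(visit %in% c(1, 2)))
  purrr::map_dfr(visit, function(v) {
    c1 <- paste0("pwv1_v", v)
    c2 <- paste0("pwv2_v", v)
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
      dplyr::summarise(
        visit = v,
        n_pairs = sum(!is.na(.data[[c1]]) & !is.na(.data[[c2]])),
        r = double_entry_cor(.data[[c1]], .data[[c2]], min_pairs),
        .groups = "drop"
      )
  }) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(strata, "visit"))))
}

double_entry_cor <- function(x1, x2, min_pairs) {
  keep <- !is.na(x1) & !is.na(x2)
  if (sum(keep) < min_pairs) return(NA_real_)
  a <- c(x1[keep], x2[keep])
  b <- c(x2[keep], x1[keep])
  cor(a, b)
}

#' Descriptive statistics by stratum
#'
#' Individual-level means and sample standard deviations (divisor n - 1) of
#' the phenotype and any covariates, per visit and stratum (by default
#' ethnicity x sex). Twins are unstacked into individuals, so singletons
#' contribute exactly one individual; missing entries are excluded variable
#' by variable. Empty strata are reported with `n = 0` and `NA` statistics.
#'
#' @param data A twin table.
#' @param variables Variable stems to summarise; each stem `x` must have
#'   columns `x<twin>_v<visit>`. Defaults to whichever of `pwv`, `map`, `age`
#'   are present.
#' @param strata Individual-level stratifying columns; `"sex"` refers to the
#'   per-twin sex.
#' @return A tibble with stratum keys, `visit`, `variable`, `n`, `mean`, `sd`.
#' @export
twin_descriptives <- function(data, variables = NULL,
                              strata = c("ethnicity", "sex")) {
  if (is.null(variables)) {
    stems <- c("pwv", "map", "age")
    variables <- stems[vapply(stems, function(s) {
      paste0(s, "1_v1") %in% names(data)
    }, logical(1))]
  }
  long <- twin_individuals(data, variables)
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(strata, "visit", "variable")))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (sum(!is.na(.data$value)) > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) > 1) sd(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(strata, "visit", "variable"))))
}

# Unstack a pair-per-row table into one row per individual x visit x variable.
twin_individuals <- function(data, variables) {
  purrr::map_dfr(1:2, function(tw) {
    sex_col <- paste0("sex", tw)
    keep <- !is.na(data[[sex_col]]) |
      !apply(is.na(data[, paste0("pwv", tw, "_v", 1:2), drop = FALSE]), 1, all)
    base <- tibble::tibble(
      family_id = data$family_id[keep],
      twin = tw,
      zygosity = data$zygosity[keep],
      ethnicity = data$ethnicity[keep],
      sex = data[[sex_col]][keep]
    )
    purrr::map_dfr(1:2, function(v) {
      purrr::map_dfr(variables, function(stem) {
        col <- paste0(stem, tw, "_v", v)
        dplyr::mutate(
          base,
          visit = v, variable = stem,
          value = if (col %in% names(data)) data[[col]][keep] else NA_real_
        )
      })
    })
  })
}
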