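params_of <- function(x) {
  if (inherits(x, "cholesky_fit")) x$params
  else if (inherits(x, "chol_params")) x
  else abort("Expected a `cholesky_fit` or `chol_params` object")
}

visit_variances <- function(p) {
  V <- component_covariance(p, "A") + component_covariance(p, "C") +
    component_covariance(p, "E")
  c(diag(V)[1], diag(V)[2])
}

#' Standardized variance components per visit
#'
#' The fraction of phenotypic variance at each visit attributable to A, C
#' and E: at visit 1, `h2 = a11^2 / (a11^2 + c11^2 + e11^2)`; at visit 2 the
#' numerators are `x21^2 + x22^2` per component. Fractions sum to 1 at each
#' visit.
#'
#' @param x A `cholesky_fit` or [chol_params()] object.
#' @return A tibble with `visit`, `component`, `variance` (raw scale) and
#'   `fraction`.
#' @export
standardized_components <- function(x) {
  p <- params_of(x)
  tot <- visit_variances(p)
  if (any(tot <= 0)) abort("Zero total variance at a visit")
  purrr::map_dfr(c("A", "C", "E"), function(comp) {
    cv <- component_covariance(p, comp)
    tibble::tibble(
      visit = c(1L, 2L), component = comp,
      variance = diag(cv), fraction = diag(cv) / tot
    )
  }) |>
    dplyr::arrange(.data$visit, .data$component)
}

#' Visit-2 specific (novel) heritability
#'
#' The fraction of visit-2 phenotypic variance explained by the genetic
#' factor unique to visit 2: `a22^2` over the total visit-2 variance. This
#' quantifies genetic influences that emerge between the two measurement
#' occasions.
#'
#' @inheritParams standardized_components
#' @return A scalar fraction.
#' @export
specific_heritability <- function(x) {
  p <- params_of(x)
  tot <- visit_variances(p)
  if (tot[2] <= 0) abort("Zero total variance at visit 2")
  p$a22^2 / tot[2]
}

#' Cross-visit component and phenotypic correlations
#'
#' The genetic correlation `r_g = COV_A(v1, v2) / sqrt(V_A(v1) V_A(v2))`
#' (and `r_c`, `r_e` analogously), plus the model-implied phenotypic
#' tracking correlation `r_ph` between the two visits. A correlation whose
#' component has zero variance at either visit is undefined and reported as
#' `NA` (never as 0: both 0 and 1 are misleading at that boundary).
#'
#' @inheritParams standardized_components
#' @return A one-row tibble with `r_g`, `r_c`, `r_e`, `r_ph`.
#' @export
cross_visit_correlations <- function(x) {
  p <- params_of(x)
  comp_cor <- function(comp) {
    cv <- component_covariance(p, comp)
    if (cv[1, 1] <= 0 || cv[2, 2] <= 0) return(NA_real_)
    cv[1, 2] / sqrt(cv[1, 1] * cv[2, 2])
  }
  tot <- visit_variances(p)
  cov_ph <- p$a11 * p$a21 + p$c11 * p$c21 + p$e11 * p$e21
  tibble::tibble(
    r_g = comp_cor("A"), r_c = comp_cor("C"), r_e = comp_cor("E"),
    r_ph = if (all(tot > 0)) cov_ph / sqrt(tot[1] * tot[2]) else NA_real_
  )
}

#' Difference-score variance decomposition
#'
#' Applying delta weights (-1, +1) to the two visits decomposes the variance
#' of the change score (visit 2 minus visit 1) into components
#' `V_X(delta) = (x21 - x11)^2 + x22^2` for X in A, C, E; the heritability
#' of change is the genetic fraction of `Var(delta)`. When the visit-2
#' loadings exactly reproduce visit 1 with no specific paths, `Var(delta)`
#' is zero and the decomposition is undefined (`NA`).
#'
#' @inheritParams standardized_components
#' @return A tibble with `component`, `variance`, `fraction`.
#' @export
difference_score_decomposition <- function(x) {
  p <- params_of(x)
  v <- vapply(c("a", "c", "e"), function(pre) {
    (p[[paste0(pre, "21")]] - p[[paste0(pre, "11")]])^2 + p[[paste0(pre, "22")]]^2
  }, numeric(1))
  tot <- sum(v)
  tibble::tibble(
    component = c("A", "C", "E"),
    variance = unname(v),
    fraction = if (tot > 0) unname(v) / tot else rep(NA_real_, 3)
  )
}

#' All derived statistics of a fitted bivariate Cholesky model
#'
#' One-row tibble collecting everything the model implies beyond its raw
#' paths: per-visit standardized fractions (`h2_v1` ... `e2_v2`), the
#' visit-2 specific heritability, cross-visit component and phenotypic
#' correlations, difference-score fractions (`h2_delta`, `c2_delta`,
#' `e2_delta`), and the raw-scale component variances and cross-visit
#' covariances (`V_A_v1`, `COV_A`, ...). Undefined quantities are `NA`.
#'
#' @inheritParams standardized_components
#' @return A one-row tibble.
#' @export
derived_stats <- function(x) {
  p <- params_of(x)
  std <- standardized_components(p)
  frac <- function(comp, v) std$fraction[std$component == comp & std$visit == v]
  cors <- cross_visit_correlations(p)
  dd <- difference_score_decomposition(p)
  dfrac <- function(comp) dd$fraction[dd$component == comp]
  raw <- purrr::map_dfc(c("A", "C", "E"), function(comp) {
    cv <- component_covariance(p, comp)
    out <- tibble::tibble(v1 = cv[1, 1], v2 = cv[2, 2], cov = cv[1, 2])
    names(out) <- c(paste0("V_", comp, "_v1"), paste0("V_", comp, "_v2"),
                    paste0("COV_", comp))
    out
  })
  dplyr::bind_cols(
    tibble::tibble(
      h2_v1 = frac("A", 1), c2_v1 = frac("C", 1), e2_v1 = frac("E", 1),
      h2_v2 = frac("A", 2), c2_v2 = frac("C", 2), e2_v2 = frac("E", 2),
      specific_h2 = specific_heritability(p)
    ),
    cors,
    tibble::tibble(h2_delta = dfrac("A"), c2_delta = dfrac("C"),
                   e2_delta = dfrac("E")),
    raw
  )
}

# Derived quantities addressable by name, for profile intervals and reports.
# Scalar arithmetic only: this sits inside the profiling objective and is
# evaluated tens of thousands of times per interval.
derived_quantity <- function(params, quantity) {
  p <- params
  v1 <- function(pre) p[[paste0(pre, "11")]]^2
  v2 <- function(pre) p[[paste0(pre, "21")]]^2 + p[[paste0(pre, "22")]]^2
  cv <- function(pre) p[[paste0(pre, "11")]] * p[[paste0(pre, "21")]]
  V1 <- v1("a") + v1("c") + v1("e")
  V2 <- v2("a") + v2("c") + v2("e")
  comp_cor <- function(pre) {
    if (v1(pre) <= 0 || v2(pre) <= 0) return(NA_real_)
    cv(pre) / sqrt(v1(pre) * v2(pre))
  }
  dvar <- function(pre) {
    (p[[paste0(pre, "21")]] - p[[paste0(pre, "11")]])^2 + p[[paste0(pre, "22")]]^2
  }
  dtot <- dvar("a") + dvar("c") + dvar("e")
  switch(
    quantity,
    h2_v1 = v1("a") / V1, c2_v1 = v1("c") / V1, e2_v1 = v1("e") / V1,
    h2_v2 = v2("a") / V2, c2_v2 = v2("c") / V2, e2_v2 = v2("e") / V2,
    specific_h2 = p$a22^2 / V2,
    r_g = comp_cor("a"), r_c = comp_cor("c"), r_e = comp_cor("e"),
    r_ph = (cv("a") + cv("c") + cv("e")) / sqrt(V1 * V2),
    h2_delta = if (dtot > 0) dvar("a") / dtot else NA_real_,
    c2_delta = if (dtot > 0) dvar("c") / dtot else NA_real_,
    e2_delta = if (dtot > 0) dvar("e") / dtot else NA_real_,
    {
      ds <- derived_stats(params)
      if (!quantity %in% names(ds)) {
        abort(paste0("Unknown derived quantity: ", quantity))
      }
      ds[[quantity]][1]
    }
  )
}

quantity_bounds <- function(quantity) {
  if (quantity %in% c("r_g", "r_c", "r_e", "r_ph")) c(-1, 1)
  else if (grepl("^(h2|c2|e2|specific)", quantity)) c(0, 1)
  else c(-Inf, Inf)
}
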