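path_names <- function() {
  c("a11", "a21", "a22", "c11", "c21", "c22", "e11", "e21", "e22")
}

#' Bivariate Cholesky path coefficients
#'
#' The nine path coefficients of the bivariate ACE Cholesky model: for each
#' variance component (A additive genetic, C shared environment, E unique
#' environment) a lower-triangular 2x2 factor with paths `x11` (visit-1
#' loading), `x21` (visit-1 factor loading on visit 2) and `x22` (visit-2
#' specific loading), in units of the analysed (log) phenotype. The component
#' covariance matrix is the outer product L L' of each factor, so it is
#' positive semidefinite for any real paths; each factor's column signs are
#' unidentified, and fitted results are reported with non-negative diagonals.
#'
#' @param a11,a21,a22 Additive-genetic paths.
#' @param c11,c21,c22 Shared-environment paths.
#' @param e11,e21,e22 Unique-environment paths.
#' @return An object of class `chol_params`.
#' @export
#' @examples
#' p <- chol_params(a11 = sqrt(0.62), a21 = sqrt(0.16), a22 = sqrt(0.19),
#'                  e11 = sqrt(0.38), e22 = sqrt(0.65))
#' component_covariance(p, "A")
chol_params <- function(a11 = 0, a21 = 0, a22 = 0,
                        c11 = 0, c21 = 0, c22 = 0,
                        e11 = 0, e21 = 0, e22 = 0) {
  p <- c(a11 = a11, a21 = a21, a22 = a22,
         c11 = c11, c21 = c21, c22 = c22,
         e11 = e11, e21 = e21, e22 = e22)
  stopifnot(is.numeric(p), length(p) == 9L, all(is.finite(p)))
  structure(as.list(p), class = "chol_params")
}

#' @export
print.chol_params <- function(x, ...) {
  cat("Bivariate Cholesky paths:\n")
  m <- matrix(unlist(x), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "C", "E"), c("x11", "x21", "x22")))
  print(round(m, 4))
  invisible(x)
}

as_chol_params <- function(x) {
  if (inherits(x, "chol_params")) return(x)
  do.call(chol_params, as.list(x)[path_names()])
}

#' Component covariance matrix
#'
#' The 2x2 (visit 1, visit 2) covariance contributed by one variance
#' component: the outer product L L' of its lower-triangular path factor,
#' i.e. entries `x11^2`, `x11*x21`, `x21^2 + x22^2`.
#'
#' @param params A [chol_params()] object.
#' @param component `"A"`, `"C"` or `"E"`.
#' @return A symmetric 2x2 matrix.
#' @export
component_covariance <- function(params, component = c("A", "C", "E")) {
  component <- match.arg(component)
  pre <- tolower(component)
  L <- matrix(c(params[[paste0(pre, "11")]], 0,
                params[[paste0(pre, "21")]], params[[paste0(pre, "22")]]),
              nrow = 2, byrow = TRUE)
  L %*% t(L)
}

#' Expected twin-pair covariance matrix
#'
#' The model-implied 4x4 covariance matrix of the observation vector
#' (twin1 visit1, twin1 visit2, twin2 visit1, twin2 visit2). Within-twin
#' blocks are A + C + E; cross-twin blocks are k A + C with the genetic
#' sharing coefficient k = 1 for MZ and 0.5 for DZ pairs (shared environment
#' is fully shared in both).
#'
#' @param params A [chol_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric 4x4 matrix.
#' @export
expected_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  k <- if (zygosity == "MZ") 1.0 else 0.5
  A <- component_covariance(params, "A")
  C <- component_covariance(params, "C")
  E <- component_covariance(params, "E")
  within <- A + C + E
  cross <- k * A + C
  rbind(cbind(within, cross), cbind(cross, within))
}

# Reflect factor column signs so diagonal paths are non-negative; the
# covariance model is invariant to these flips.
reflect_params <- function(params) {
  p <- unlist(params)
  for (pre in c("a", "c", "e")) {
    if (p[paste0(pre, "11")] < 0) {
      p[paste0(pre, "11")] <- -p[paste0(pre, "11")]
      p[paste0(pre, "21")] <- -p[paste0(pre, "21")]
    }
    if (p[paste0(pre, "22")] < 0) p[paste0(pre, "22")] <- -p[paste0(pre, "22")]
  }
  do.call(chol_params, as.list(p))
}
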