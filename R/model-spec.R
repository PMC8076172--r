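#' Model specification for the bivariate Cholesky fit
#'
#' Declares which variance components are included (E is mandatory: every
#' observation needs residual variance), which individual paths are fixed to
#' zero, and which covariates enter the means model. Excluded components have
#' all three of their paths fixed to zero; a fixed path is not counted as a
#' free parameter.
#'
#' @param components `"ACE"`, `"AE"`, `"CE"` or `"E"` (or a character vector
#'   of component letters).
#' @param drop_paths Paths fixed to zero, e.g. `c("e21")`; must belong to an
#'   included component.
#' @param covariates Covariate stems entering the means model per visit,
#'   e.g. `"map"`.
#' @return An object of class `chol_model_spec`.
#' @export
#' @examples
#' model_spec("AE", drop_paths = "e21")
model_spec <- function(components = "ACE", drop_paths = character(),
                       covariates = character()) {
  comps <- unique(strsplit(paste(components, collapse = ""), "")[[1]])
  bad <- setdiff(comps, c("A", "C", "E"))
  if (length(bad)) abort(paste0("Unknown component(s): ", paste(bad, collapse = ", ")))
  if (!"E" %in% comps) abort("The E component is mandatory")
  all_paths <- path_names()
  included <- all_paths[substr(all_paths, 1, 1) %in% tolower(comps)]
  bad_drop <- setdiff(drop_paths, all_paths)
  if (length(bad_drop)) abort(paste0("Unknown path(s): ", paste(bad_drop, collapse = ", ")))
  outside <- setdiff(drop_paths, included)
  if (length(outside)) {
    abort(paste0("Dropped path(s) not in an included component: ",
                 paste(outside, collapse = ", ")))
  }
  free <- setdiff(included, drop_paths)
  structure(
    list(components = sort(comps), drop_paths = sort(drop_paths),
         covariates = covariates, free_paths = free),
    class = "chol_model_spec"
  )
}

#' @export
print.chol_model_spec <- function(x, ...) {
  cat("Cholesky model spec: components",
      paste(x$components, collapse = ""), "\n")
  if (length(x$drop_paths)) cat("  paths fixed to 0:", paste(x$drop_paths, collapse = ", "), "\n")
  if (length(x$covariates)) cat("  means covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("  free paths:", paste(x$free_paths, collapse = ", "), "\n")
  invisible(x)
}

n_free_paths <- function(spec) length(spec$free_paths)

# reduced is nested in full when its free-path set is a subset and the
# means model is identical.
spec_is_nested <- function(reduced, full) {
  all(reduced$free_paths %in% full$free_paths) &&
    setequal(reduced$covariates, full$covariates)
}

#' Serialize / deserialize a model spec
#'
#' @param spec A [model_spec()] object.
#' @param path YAML file path.
#' @return `read_model_spec()` returns the spec; `write_model_spec()` the
#'   path, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(
    list(components = paste(spec$components, collapse = ""),
         drop_paths = as.list(spec$drop_paths),
         covariates = as.list(spec$covariates)),
    path
  )
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(
    components = x$components,
    drop_paths = unlist(x$drop_paths) %||% character(),
    covariates = unlist(x$covariates) %||% character()
  )
}

#' Means model for the observed phenotype
#'
#' Per-visit intercepts on the analysis (log) scale, plus optional per-visit
#' regression coefficients for covariates shared across twins (the model the
#' package uses for mean arterial pressure adjustment, which keeps the
#' adjustment inside the FIML likelihood rather than pre-residualising).
#'
#' @param mu Numeric length 2: intercepts for visit 1 and visit 2.
#' @param beta Named list of numeric length-2 vectors, one per covariate stem.
#' @return An object of class `means_model`.
#' @export
means_model <- function(mu = c(0, 0), beta = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 2L)
  if (!is.null(beta)) {
    stopifnot(is.list(beta), !is.null(names(beta)),
              all(vapply(beta, length, 1L) == 2L))
  }
  structure(list(mu = as.numeric(mu), beta = beta), class = "means_model")
}
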