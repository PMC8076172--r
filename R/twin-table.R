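#' Column-name schema for wide twin tables
#'
#' Maps the canonical column names used throughout the package onto the
#' header names of a particular CSV file. The canonical layout is one row per
#' twin pair (or singleton): `family_id`, `zygosity` (`MZ`/`DZ`), `ethnicity`
#' (pair-level), `sex1`/`sex2`, phenotype columns `pwv<twin>_v<visit>`, and
#' optional covariate columns `map<twin>_v<visit>` (mean arterial pressure)
#' and `age<twin>_v<visit>`.
#'
#' @param ... Named overrides, canonical name = file column name, e.g.
#'   `family_id = "famid"`.
#' @return A named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' twin_schema(family_id = "famid", zygosity = "zyg")
twin_schema <- function(...) {
  canonical <- c(
    "family_id", "zygosity", "ethnicity", "sex1", "sex2",
    "pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2",
    "map1_v1", "map1_v2", "map2_v1", "map2_v2",
    "age1_v1", "age1_v2", "age2_v1", "age2_v2"
  )
  schema <- setNames(canonical, canonical)
  overrides <- c(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), canonical)
    if (length(unknown)) {
      abort(paste0("Unknown schema field(s): ", paste(unknown, collapse = ", ")))
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

required_twin_columns <- function() {
  c(
    "family_id", "zygosity", "ethnicity", "sex1", "sex2",
    "pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2"
  )
}

phenotype_columns <- function() c("pwv1_v1", "pwv1_v2", "pwv2_v1", "pwv2_v2")

new_twin_tbl <- function(df, phenotype = "pwv", transform = "none") {
  out <- tibble::as_tibble(df)
  attr(out, "phenotype") <- phenotype
  attr(out, "transform") <- transform
  class(out) <- unique(c("twin_tbl", class(out)))
  out
}

#' Transform record of a twin table
#'
#' @param data A twin table as returned by [read_twin_table()] or
#'   [simulate_twin_cohort()].
#' @return `"none"` or `"log"`.
#' @export
twin_transform <- function(data) attr(data, "transform") %||% "none"

#' Read a wide twin phenotype table
#'
#' Reads a CSV with one row per twin pair and validates the twin-design
#' invariants: known zygosity codes, unique family ids, pair-level ethnicity,
#' and sex concordance of complete MZ pairs. Empty cells are missing values
#' (never zero). A row whose second-twin slots (sex and all phenotype /
#' covariate cells) are entirely empty is flagged as a singleton. Rows with no
#' non-missing phenotype value at all are dropped with a message, since they
#' carry no likelihood information.
#'
#' @param path Path to a CSV file (RFC-4180, empty string = missing).
#' @param schema Column mapping from [twin_schema()].
#' @param phenotype Label for the phenotype carried in the `pwv*` columns.
#' @return A `twin_tbl` tibble in canonical column order with attributes
#'   `phenotype` and `transform` (initially `"none"`), plus a logical
#'   `singleton` column.
#' @export
read_twin_table <- function(path, schema = twin_schema(), phenotype = "pwv") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  present <- schema[schema %in% names(raw)]
  missing_req <- setdiff(required_twin_columns(), names(present))
  if (length(missing_req)) {
    abort(paste0(
      "Missing required column(s): ",
      paste(schema[missing_req], collapse = ", ")
    ))
  }
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)
  df[] <- lapply(df, function(x) {
    x[trimws(x) == ""] <- NA_character_
    x
  })

  num_cols <- intersect(
    names(df),
    c(phenotype_columns(), paste0("map", rep(1:2, each = 2), "_v", 1:2),
      paste0("age", rep(1:2, each = 2), "_v", 1:2))
  )
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(paste0("Non-numeric value in column '", col, "', row ", bad[1]))
    }
    df[[col]] <- parsed
  }

  bad_zyg <- which(!df$zygosity %in% c("MZ", "DZ"))
  if (length(bad_zyg)) {
    abort(paste0(
      "Unknown zygosity code '", df$zygosity[bad_zyg[1]],
      "' in row ", bad_zyg[1]
    ))
  }
  dup <- df$family_id[duplicated(df$family_id)]
  if (length(dup)) {
    abort(paste0("Duplicate family_id: ", paste(unique(dup), collapse = ", ")))
  }
  discordant_mz <- which(
    df$zygosity == "MZ" & !is.na(df$sex1) & !is.na(df$sex2) & df$sex1 != df$sex2
  )
  if (length(discordant_mz)) {
    abort(paste0(
      "MZ pair with discordant sexes: family_id ",
      df$family_id[discordant_mz[1]]
    ))
  }

  twin2_cols <- intersect(names(df), c("sex2", "pwv2_v1", "pwv2_v2",
                                       "map2_v1", "map2_v2", "age2_v1", "age2_v2"))
  df$singleton <- apply(is.na(df[, twin2_cols, drop = FALSE]), 1, all)

  pheno_missing <- apply(is.na(df[, phenotype_columns(), drop = FALSE]), 1, all)
  if (any(pheno_missing)) {
    inform(paste0(
      "Dropping ", sum(pheno_missing),
      " row(s) with no phenotype observation (family_id: ",
      paste(utils::head(df$family_id[pheno_missing], 5), collapse = ", "), ")"
    ))
    df <- df[!pheno_missing, , drop = FALSE]
  }

  new_twin_tbl(df, phenotype = phenotype, transform = "none")
}

#' Write a twin table to CSV
#'
#' Inverse of [read_twin_table()]: missing values become empty cells, so a
#' write/read round trip reproduces the same table.
#'
#' @param data A twin table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(data, path) {
  out <- data[, setdiff(names(data), "singleton"), drop = FALSE]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Natural-log transform of the phenotype
#'
#' Replaces every non-missing phenotype value with its natural logarithm,
#' leaving the missingness pattern untouched and recording the transform so
#' it cannot be applied twice. The base does not matter for standardized
#' variance fractions and correlations; natural log is used.
#'
#' @param data A twin table with `transform == "none"`.
#' @return The transformed twin table (`transform == "log"`).
#' @export
log_transform_phenotype <- function(data) {
  if (twin_transform(data) == "log") {
    abort("Phenotype already log transformed")
  }
  for (col in phenotype_columns()) {
    x <- data[[col]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      abort(paste0(
        "Non-positive phenotype value in ", col,
        " for family_id ", data$family_id[bad[1]]
      ))
    }
    data[[col]] <- log(x)
  }
  attr(data, "transform") <- "log"
  data
}

# Pair-level sex label: M/F for same-sex pairs, OS for opposite-sex DZ,
# the observed twin's sex for singletons.
pair_sex <- function(data) {
  dplyr::case_when(
    is.na(data$sex2) ~ data$sex1,
    is.na(data$sex1) ~ data$sex2,
    data$sex1 == data$sex2 ~ data$sex1,
    TRUE ~ "OS"
  )
}
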