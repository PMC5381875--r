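# Readers, writers and validators for the pipeline's tabular inputs.
# All tables travel as TSV (UTF-8, "." decimal); counts are taxa x samples
# with taxa as rows, matching the long dimension of genus tables.

#' Validate a taxon-by-sample count table
#'
#' A count table is an integer matrix with unique taxon row names and unique
#' sample column names, no negative entries and at least one nonzero entry.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_count_table <- function(x) {
  check_that(is.matrix(x) && is.numeric(x), "counts", "must be a numeric matrix")
  check_that(!is.null(rownames(x)) && !is.null(colnames(x)), "counts",
             "must carry taxon rownames and sample colnames")
  check_that(!anyDuplicated(rownames(x)), "counts", "duplicate taxon ids")
  check_that(!anyDuplicated(colnames(x)), "counts", "duplicate sample ids")
  check_that(!anyNA(x), "counts", "missing values are not allowed")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid `counts`: negative count at taxon '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  if (any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid `counts`: non-integer count at taxon '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  check_that(sum(x) > 0, "counts", "all entries are zero")
  invisible(x)
}

#' Read a taxon-by-sample count table from TSV
#'
#' Expects a header row of sample ids and a first column of taxon ids.
#' Row and column order are preserved from the file.
#'
#' @param path path to a TSV file.
#' @return integer matrix (taxa x samples).
#' @export
read_count_table <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count table body must be numeric: ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#'
#' @param x count matrix (taxa x samples).
#' @param path output path.
#' @param id_col name of the taxon id column in the header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, id_col = "taxon") {
  validate_count_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a taxonomy map
#'
#' Maps each taxon id to a (phylum, class, genus) lineage. Unassigned ranks
#' are encoded as the explicit string `"unclassified"`, never empty.
#'
#' @param x data.frame with columns `taxon`, `phylum`, `class`, `genus`.
#' @return `x`, invisibly, if valid.
#' @export
validate_taxonomy <- function(x) {
  check_that(is.data.frame(x), "taxonomy", "must be a data.frame")
  need <- c("taxon", "phylum", "class", "genus")
  check_that(all(need %in% names(x)), "taxonomy",
             paste("must have columns", paste(need, collapse = ", ")))
  check_that(!anyDuplicated(x$taxon), "taxonomy", "duplicate taxon ids")
  for (col in need) {
    check_that(all(nzchar(as.character(x[[col]]))), col, "empty names not allowed")
  }
  invisible(x)
}

#' Read a taxonomy map from TSV
#' @param path path to TSV with columns taxon, phylum, class, genus.
#' @return validated data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_strict(path)
  names(df)[1] <- "taxon"
  df$taxon <- as.character(df$taxon)
  validate_taxonomy(df)
  df
}

#' Write a taxonomy map as TSV
#' @param x taxonomy data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(x, path) {
  validate_taxonomy(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Environmental variables carried by an EnvTable, with units.
ENV_VARIABLES <- c(pH = "unitless", SOC = "g/kg", AP = "mg/kg", TP = "mg/kg",
                   NO3 = "mg/kg", NH4 = "mg/kg",
                   sand = "g/kg", silt = "g/kg", clay = "g/kg")

#' Validate an environment table
#'
#' Samples are rows; columns are soil variables (pH plus non-negative
#' concentrations/texture fractions). pH must lie in (0, 14).
#'
#' @param x data.frame with a `sample` column and numeric soil variables.
#' @return `x`, invisibly, if valid.
#' @export
validate_env_table <- function(x) {
  check_that(is.data.frame(x), "env", "must be a data.frame")
  check_that("sample" %in% names(x), "env", "must have a `sample` column")
  check_that(!anyDuplicated(x$sample), "sample", "duplicate sample ids")
  vars <- setdiff(names(x), "sample")
  check_that(length(vars) > 0, "env", "no environmental variables present")
  for (v in vars) {
    check_that(is.numeric(x[[v]]) && !anyNA(x[[v]]), v, "must be numeric, no NA")
  }
  if ("pH" %in% vars) {
    check_that(all(x$pH > 0 & x$pH < 14), "pH", "must lie in (0, 14)")
  }
  for (v in setdiff(vars, "pH")) {
    check_that(all(x[[v]] >= 0), v, "concentrations must be >= 0")
  }
  invisible(x)
}

#' Read an environment table from TSV
#' @param path path to TSV with a sample-id column then numeric variables.
#' @return validated data.frame (samples as rows).
#' @export
read_env_table <- function(path) {
  df <- read_tsv_strict(path)
  names(df)[1] <- "sample"
  df$sample <- as.character(df$sample)
  validate_env_table(df)
  df
}

#' Write an environment table as TSV
#' @param x env data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(x, path) {
  validate_env_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strict TSV reader: header required, every row must have the header's
# width (short/long rows are an error, never padded).
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  widths <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(widths != widths[1])) {
    stop(sprintf("ragged TSV: row %d has %d fields, header has %d (%s)",
                 which(widths != widths[1])[1], widths[widths != widths[1]][1],
                 widths[1], path), call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Packaged study fixtures
#'
#' Returns the published per-sample summary tables shipped with the package:
#' `"richness"` (per-sample effective sequences, OTU richness, Good's
#' coverage, Chao1 and Shannon index for the seven rhizosphere samples) or
#' `"env"` (soil chemistry and texture means, with the per-cell standard
#' deviations as attribute `"sd"`).
#'
#' @param which `"richness"` or `"env"`.
#' @return data.frame; for `"env"` a validated environment table.
#' @export
study_fixture <- function(which = c("richness", "env")) {
  which <- match.arg(which)
  path <- function(f) system.file("extdata", f, package = "rhizonet", mustWork = TRUE)
  if (which == "richness") {
    df <- read_tsv_strict(path("table1_richness.tsv"))
    names(df)[1] <- "sample"
    return(df)
  }
  env <- read_env_table(path("table2_env.tsv"))
  sd <- read_env_table(path("table2_env_sd.tsv"))
  attr(env, "sd") <- sd
  env
}
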