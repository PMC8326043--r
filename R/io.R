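## Readers and writers for the pipeline's table formats. All tables are
## plain TSV; abundance tables may also be BIOM (via the biomformat
## package). Orientation is always stated by the caller, never guessed.

#' Read an abundance table
#'
#' @param path File path.
#' @param format `"tsv"` (first column = row IDs) or `"biom"` (requires the
#'   biomformat package; BIOM stores observations as rows, so the matrix is
#'   transposed to samples-by-features after reading).
#' @param orientation Orientation of the TSV file: `"samples_by_taxa"` or
#'   `"taxa_by_samples"`; the returned matrix is always samples-by-taxa.
#' @return Numeric matrix, samples as rows, IDs preserved verbatim.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 orientation = c("samples_by_taxa",
                                                 "taxa_by_samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop_dietbiome("BIOM input needs the 'biomformat' package")
    b <- biomformat::read_biom(path)
    M <- t(as(biomformat::biom_data(b), "matrix"))
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop_dietbiome("duplicated row IDs in ", path, ": ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", "))
    M <- as.matrix(df[, -1, drop = FALSE])
    if (is.character(M)) {
      num <- suppressWarnings(as.numeric(M))
      bad <- which(is.na(num) & !is.na(M))
      if (length(bad)) {
        pos <- arrayInd(bad[1], dim(M))
        stop_dietbiome(sprintf("non-numeric cell in %s at row %d, column '%s'",
                               path, pos[1], colnames(M)[pos[2]]))
      }
      M <- matrix(num, nrow(M), ncol(M), dimnames = dimnames(M))
    }
    storage.mode(M) <- "double"
    rownames(M) <- ids
    if (orientation == "taxa_by_samples") M <- t(M)
  }
  if (anyDuplicated(colnames(M)))
    stop_dietbiome("duplicated column IDs in ", path)
  M
}

#' Write an abundance (or any samples-by-features) matrix as TSV
#'
#' @param X Matrix with row and column names.
#' @param path Output path.
#' @param id_column Name for the leading ID column.
#' @export
write_abundance_table <- function(X, path, id_column = "sample_id") {
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as square TSV
#'
#' Sample IDs appear as both the header row and the leading column.
#' @param D Square symmetric matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(D, path) {
  D <- check_distance_matrix(D)
  write_abundance_table(unclass(D), path, id_column = "sample_id")
}

#' Read a square TSV distance matrix
#' @param path File path.
#' @return Validated symmetric matrix with zero diagonal.
#' @export
read_distance_matrix <- function(path) {
  M <- read_abundance_table(path)
  if (!identical(rownames(M), colnames(M)))
    stop_dietbiome("distance matrix row/column IDs disagree in ", path)
  check_distance_matrix(M)
}

#' Read a covariate or FPQ response table (TSV)
#' @param path File path.
#' @param id_column Name of the ID column that must be present.
#' @return data.frame with IDs as character.
#' @export
read_sample_table <- function(path, id_column = "sample_id") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(df))
    stop_dietbiome(path, " lacks the '", id_column, "' column")
  df[[id_column]] <- as.character(df[[id_column]])
  if (anyDuplicated(df[[id_column]]))
    stop_dietbiome("duplicated IDs in ", path)
  df
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file with entries `fpq`, `covariates`, `abundance`,
#'   `ko` (input paths), optional `scoring_config`, `covariate_terms`,
#'   `permutations`, `seed`, `detection`, `prevalence`, `fdr`,
#'   `pseudocount`, `output_dir`.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config_from_list(cfg)
}

run_config_from_list <- function(cfg) {
  defaults <- list(covariate_terms = c("age", "sex", "bmi", "smoking",
                                       "medication"),
                   permutations = 999L, seed = 1L, detection = 0.001,
                   prevalence = 0.01, fdr = 0.05, pseudocount = NULL,
                   scoring_config = NULL, output_dir = "dietbiome-results")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[nm] <- defaults[nm]
  for (nm in c("fpq", "covariates", "abundance", "ko")) {
    if (is.null(cfg[[nm]]))
      stop_dietbiome("run config lacks input path '", nm, "'")
    if (!file.exists(cfg[[nm]]))
      stop_dietbiome("input file not found: ", cfg[[nm]])
  }
  for (nm in c("detection", "prevalence", "fdr"))
    assert_scalar_number(cfg[[nm]], nm, 0, 1)
  assert_scalar_number(cfg$permutations, "permutations", lower = 1)
  structure(cfg, class = "run_config")
}

## Write a tidy TSV with a comment header carrying the config hash so every
## output names the configuration that produced it.
write_result_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dietbiome config %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
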