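#' Read a sample annotation table
#'
#' Expects a CSV with header
#' `sample_id,x_mm,y_mm,z_mm,tissue_class,network`. The schema mirrors a
#' brain-atlas sample annotation: an ID, 3D coordinates in mm (MNI-style),
#' an ontological tissue-class label, and a functional-network label where
#' `"none"` or an empty field means unlabeled.
#'
#' @param path Path to the CSV file.
#' @return A validated sample data.frame (see [validate_samples()]).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stopf("sample file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_samples(df)
}

#' Write a sample annotation table
#' @param samples A sample data.frame.
#' @param path Output CSV path.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix aligned to a sample table
#'
#' Expects a TSV whose first column is `gene_id` and whose remaining
#' columns are sample IDs in any order. Columns are reordered to the sample
#' table's order; genes containing any non-finite value are dropped with a
#' message stating the count.
#'
#' @param path Path to the TSV file.
#' @param samples The sample table the matrix must align to.
#' @return A genes x samples numeric matrix.
#' @export
read_expression <- function(path, samples) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  samples <- validate_samples(samples)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") {
    stopf("first column of expression TSV must be `gene_id`, found `%s`",
          names(df)[1])
  }
  missing_samples <- setdiff(samples$sample_id, names(df)[-1])
  if (length(missing_samples)) {
    stopf("sample(s) in annotation missing from expression header: %s",
          paste(missing_samples, collapse = ", "))
  }
  expr <- as.matrix(df[, samples$sample_id, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- as.character(df$gene_id)
  bad <- !apply(is.finite(expr), 1, all)
  if (any(bad)) {
    message(sprintf("dropping %d gene(s) with non-finite values", sum(bad)))
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' Write an expression matrix
#' @param expr A genes x samples matrix with dimnames.
#' @param path Output TSV path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an audit configuration file
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`), holding any of the arguments of
#' [run_audit()] plus an optional `simulate:` block of
#' [synthetic_config()] arguments.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_audit_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("unsupported config extension `.%s` (use YAML or JSON)", ext)
  }
}
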