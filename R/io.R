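# Plain-text readers/writers for the pipeline's tabular formats. All
# tables are tab-separated with a header; abundance matrices use NA for
# missing entries and keep features as the first column.

#' Read / write a long-format peptide table
#'
#' Columns: `peptide_id`, `sample_id`, `fraction`, `peak_area`, `qvalue`.
#' Schema violations are reported with the offending column.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide_id", "sample_id", "fraction", "peak_area", "qvalue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("peptide table %s lacks columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(df$peak_area < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative peak_area at line %d of %s", bad[1] + 1L, path))
  }
  bad <- which(df$qvalue < 0 | df$qvalue > 1)
  if (length(bad) > 0) {
    stop(sprintf("qvalue outside [0,1] at line %d of %s", bad[1] + 1L, path))
  }
  df
}

#' @rdname read_peptide_table
#' @param table Peptide table to write.
#' @export
write_peptide_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an abundance matrix as TSV
#'
#' Features x samples; the first column (`feature`) holds row names and
#' missing entries are written as `NA`.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_abundance_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "feature") {
    stop(sprintf("%s: first column must be 'feature', found '%s'",
                 path, names(df)[1]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric abundance values", path))
  rownames(m) <- df$feature
  m
}

#' @rdname read_abundance_matrix
#' @param x Matrix to write.
#' @export
write_abundance_matrix <- function(x, path) {
  df <- data.frame(feature = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write simple TSV tables (metadata, maps, result tables)
#'
#' @param path File path.
#' @param required Columns that must be present.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      stop(sprintf("%s lacks columns: %s", path,
                   paste(missing_cols, collapse = ", ")))
    }
  }
  df
}

#' @rdname read_tsv_table
#' @param table data.frame to write.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene list (one symbol per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read / write planted ground truth as JSON
#'
#' @param path File path.
#' @return The ground-truth list (`proteins` and `samples` data.frames).
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::fromJSON(path)
  lapply(gt, as.data.frame)
}

#' @rdname read_ground_truth
#' @param truth Ground-truth list from [simulate_dia_cohort()].
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", na = "null",
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}
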