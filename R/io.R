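# Table readers/writers shared by all stages. All tables are TSV with a
# header; floating values are written with 6 significant digits.

#' Write a table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Significant digits for floating-point columns (default 6).
#' @export
write_tsv <- function(df, path, digits = 6) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Delimited reader keyed on extension (.tsv/.txt tab, .csv comma).
read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a well-measurement table
#'
#' @param path TSV/CSV with columns `plate_id`, `well`, `cell_line`,
#'   `perturbation_id`, `perturbation_class`, `treatment`, `dose`, `signal`.
#' @return Data frame of well measurements.
#' @export
read_well_table <- function(path) {
  check_columns(read_table_auto(path),
                c("plate_id", "well", "cell_line", "perturbation_id",
                  "perturbation_class", "treatment", "dose", "signal"),
                path)
}

#' Read a perturbation blacklist (one id per line)
#'
#' @param path Text file; blank lines and `#` comments ignored.
#' @return Character vector of ids.
#' @export
read_blacklist <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a differential-expression table
#'
#' @param path TSV/CSV with columns `gene_id`, `fold_change`, `p_value`,
#'   `adjusted_p` and optionally `direction`.
#' @return Data frame.
#' @export
read_de_table <- function(path) {
  check_columns(read_table_auto(path),
                c("gene_id", "fold_change", "p_value", "adjusted_p"), path)
}

#' Read a target-evidence table
#'
#' @param path TSV/CSV with columns `mirna_id`, `gene_id`, `source`,
#'   `evidence_class`.
#' @return Data frame.
#' @export
read_target_evidence <- function(path) {
  check_columns(read_table_auto(path),
                c("mirna_id", "gene_id", "source", "evidence_class"), path)
}

#' Read a tumor expression matrix with sample annotation
#'
#' @param matrix_path TSV of intensities, first column gene ids, remaining
#'   columns samples; empty cells or `NA` mark missing values.
#' @param annotation_path TSV with columns `sample_id`, `tissue_group`.
#' @return A [tumor_matrix()].
#' @export
read_tumor_matrix <- function(matrix_path, annotation_path) {
  tab <- read_table_auto(matrix_path)
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  ann <- check_columns(read_table_auto(annotation_path),
                       c("sample_id", "tissue_group"), annotation_path)
  missing <- setdiff(colnames(m), ann$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) without tissue annotation: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tumor_matrix(m, ann$tissue_group[match(colnames(m), ann$sample_id)])
}
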