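#' Write a count matrix as TSV
#'
#' Rows are miRNAs, columns samples; the first column is `mirna` and the
#' header row carries the sample ids.
#'
#' @param cm a [count_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(mirna = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_count_matrix()] (first column
#'   `mirna`, remaining columns one sample each).
#' @param group optional group labels per sample; if `NULL`, labels are
#'   inferred from sample names starting with `control`/`ctrl` or
#'   `treated`/`treat`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, group = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "mirna") stop("first column must be 'mirna'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mirna
  if (is.null(group)) {
    nm <- tolower(colnames(m))
    group <- ifelse(grepl("^(control|ctrl)", nm), "control",
                    ifelse(grepl("^(treated|treat)", nm), "treated", NA))
    if (any(is.na(group))) {
      stop("cannot infer groups from sample names; pass `group` explicitly")
    }
  }
  count_matrix(m, group)
}

#' Write an interaction table as TSV
#' @param tab data.frame with `mirna`, `gene`, `score`/`evidence`,
#'   `source`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a Cp table as TSV
#' @param cp data.frame from [simulate_qpcr()] or of the same shape.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cp_table <- function(cp, path) {
  utils::write.table(cp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a differential expression table as TSV
#' @param de a `de_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(
    de[, c("mirna", "logFC", "p_value", "fdr", "direction")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential expression table from TSV
#' @param path TSV with columns `mirna`, `logFC`, `p_value`, `fdr`,
#'   `direction`.
#' @return data.frame of class `de_result`.
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "logFC", "p_value", "fdr", "direction")
  if (!all(need %in% names(de))) {
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  }
  class(de) <- c("de_result", "data.frame")
  de
}
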