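#' Two-group miRNA count matrix
#'
#' Light container for non-negative integer read counts of mature miRNAs
#' (rows) across labeled samples (columns), with a two-level group factor.
#'
#' @param counts non-negative integer matrix with miRNA row names and
#'   sample column names. miRNA ids must be unique after case folding.
#' @param group factor (or character) of length `ncol(counts)` with levels
#'   `control` and `treated`; both groups must be non-empty.
#' @return object of class `count_matrix`: list with `counts` and `group`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("rno-miR-", 1:3, "-5p"),
#'                             paste0("s", 1:4)))
#' cm <- count_matrix(m, rep(c("control", "treated"), each = 2))
count_matrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have miRNA row names and sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (anyDuplicated(tolower(rownames(counts)))) {
    stop("duplicate miRNA ids after case normalization")
  }
  group <- factor(as.character(group), levels = c("control", "treated"))
  if (length(group) != ncol(counts)) {
    stop("group must have one label per sample")
  }
  if (any(is.na(group))) {
    stop("group labels must be 'control' or 'treated'")
  }
  if (any(table(group) == 0)) {
    stop("both groups must be non-empty")
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "samples (", sum(x$group == "control"), "control /",
      sum(x$group == "treated"), "treated )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Keep miRNAs detectable above a total-count threshold
#'
#' The detectability criterion is a minimum total read count across all
#' samples; with `min_total = 1` a miRNA counts as detectable if it was
#' seen at all. Row order is preserved.
#'
#' @param cm a [count_matrix()].
#' @param min_total non-negative integer threshold on the row sum.
#' @return filtered `count_matrix` (possibly with zero rows, with a
#'   warning).
#' @export
filter_detectable <- function(cm, min_total = 1) {
  stopifnot(inherits(cm, "count_matrix"), min_total >= 0)
  keep <- rowSums(cm$counts) >= min_total
  if (!any(keep)) {
    warning("no miRNA passes the detectability filter; returning an empty matrix")
  }
  structure(list(counts = cm$counts[keep, , drop = FALSE], group = cm$group),
            class = "count_matrix")
}
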