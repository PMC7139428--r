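#' Read a GMT annotation file
#'
#' Standard gene-set format: one term per line, tab-separated
#' `term <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file.
#' @return named list `term -> character vector of genes` (upper-cased),
#'   with term descriptions in `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): need term, description, genes")
  terms <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- terms
  attr(sets, "descriptions") <- stats::setNames(desc, terms)
  sets
}

#' Write a GMT annotation file
#' @param annotation named list `term -> genes`.
#' @param path output file.
#' @param descriptions optional named character of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(annotation), names(annotation))
  }
  lines <- vapply(names(annotation), function(tm) {
    paste(c(tm, descriptions[[tm]], annotation[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Gene Ontology over-representation with fold enrichment
#'
#' Classic over-representation analysis of a target list against a term
#' annotation: for each term with at least one target gene, the overlap
#' `k` out of `n` targets is compared with the term's `K` genes in the
#' `N`-gene universe. Fold enrichment is `(k/n) / (K/N)` and the p-value is
#' the hypergeometric upper tail `P(X >= k)`. Multiple testing is corrected
#' across all tested terms, either Benjamini-Hochberg (default) or
#' Bonferroni (both corrections are in common use for this analysis and
#' give different significance calls; choose explicitly when reproducing a
#' published list).
#'
#' @param targets character vector of target genes (must lie in the
#'   universe).
#' @param annotation named list `term -> genes` (e.g. [read_gmt()]).
#' @param universe gene universe; defaults to all genes in the annotation.
#' @param method `"BH"` or `"bonferroni"`.
#' @return data.frame of class `enrichment_result`, sorted by fold
#'   enrichment (descending; ties by smaller p, then term id), with
#'   columns `term`, `name`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `p_adjusted`, `method`.
#' @export
enrich_targets <- function(targets, annotation, universe = NULL,
                           method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  targets <- unique(toupper(targets))
  if (is.null(universe)) {
    universe <- unique(unlist(annotation, use.names = FALSE))
  }
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty gene universe")
  if (!length(targets)) stop("empty target list")
  outside <- setdiff(targets, universe)
  if (length(outside)) {
    stop("target gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  desc <- attr(annotation, "descriptions")
  n <- length(targets)
  N <- length(universe)
  rows <- lapply(names(annotation), function(tm) {
    set <- intersect(unique(toupper(annotation[[tm]])), universe)
    K <- length(set)
    k <- length(intersect(targets, set))
    if (k == 0) return(NULL)
    data.frame(
      term = tm,
      name = if (!is.null(desc) && tm %in% names(desc)) desc[[tm]] else tm,
      k = k, n = n, K = K, N = N,
      fold_enrichment = (k / n) / (K / N),
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(term = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      method = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (method == "BH") {
    bh_adjust(out$p_value)
  } else {
    pmin(1, out$p_value * nrow(out))
  }
  out$method <- method
  out <- out[order(-out$fold_enrichment, out$p_value, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top enriched terms by fold enrichment
#'
#' Significant terms (`p_adjusted < alpha`) ranked by fold enrichment
#' descending; ties are broken by smaller p-value, then term id. Returns at
#' most `m` terms (all significant ones if fewer).
#'
#' @param results an [enrich_targets()] result.
#' @param m maximum number of terms (positive).
#' @param alpha adjusted-p threshold.
#' @return the selected rows, in rank order.
#' @export
top_terms <- function(results, m, alpha = 0.05) {
  if (!is.numeric(m) || m <= 0) stop("m must be a positive integer")
  sig <- results[results$p_adjusted < alpha, , drop = FALSE]
  sig <- sig[order(-sig$fold_enrichment, sig$p_value, sig$term), ,
             drop = FALSE]
  out <- utils::head(sig, m)
  rownames(out) <- NULL
  out
}
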