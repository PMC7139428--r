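#' Select validation candidates from the hub set
#'
#' Implements the hub-selection rule used to pick qRT-PCR validation
#' targets: every hub with negative node strength (miRNA regulation
#' predicted to push expression down on balance) is selected
#' unconditionally; positive-strength hubs are ranked by the best (highest)
#' fold enrichment among the significant GO terms that annotate them, and
#' the top `n_positive` are added. Ties are broken by the annotating term's
#' smaller p-value, then by gene symbol, so the selection is deterministic
#' and invariant to input order.
#'
#' @param hubs a [find_hubs()] report (non-empty).
#' @param net the [build_network()] result the hubs came from.
#' @param enrichment an [enrich_targets()] result computed on the full
#'   predicted target set.
#' @param annotation named list `term -> genes` used for the enrichment
#'   (needed to know which terms annotate which hub).
#' @param n_positive number of positive-strength hubs to select
#'   (default 3).
#' @param alpha adjusted-p threshold defining "significant" terms.
#' @return object of class `selection_report`: list with
#'   `hubs_considered` (gene/degree/strength), `selected_negative`,
#'   `selected_positive`, `selected_total` (ordered: negative hubs by gene,
#'   then positive hubs by rank) and `rationale` (named character, one
#'   provenance string per selected gene).
#' @export
#' @examples
#' # see the package vignette for a full worked example
select_candidates <- function(hubs, net, enrichment, annotation,
                              n_positive = 3, alpha = 0.05) {
  stopifnot(inherits(hubs, "hub_report"), inherits(net, "signed_network"))
  if (n_positive < 0) stop("n_positive must be non-negative")
  hub_df <- hubs$hubs
  if (nrow(hub_df) == 0) stop("empty hub report")

  neg <- hub_df[hub_df$strength < 0, , drop = FALSE]
  neg <- neg[order(neg$gene), , drop = FALSE]

  pos <- hub_df[hub_df$strength > 0, , drop = FALSE]
  sig_terms <- enrichment[enrichment$p_adjusted < alpha, , drop = FALSE]
  ann_up <- lapply(annotation, toupper)

  score_hub <- function(gene) {
    # best significant term annotating this gene
    has <- vapply(ann_up[sig_terms$term], function(gs) gene %in% gs, TRUE)
    if (!any(has)) return(NULL)
    cand <- sig_terms[has, , drop = FALSE]
    cand <- cand[order(-cand$fold_enrichment, cand$p_value, cand$term), ,
                 drop = FALSE]
    cand[1, , drop = FALSE]
  }
  best <- lapply(pos$gene, score_hub)
  qualifies <- !vapply(best, is.null, TRUE)
  pos_q <- pos[qualifies, , drop = FALSE]
  best_q <- do.call(rbind, best[qualifies])
  if (nrow(pos_q)) {
    ord <- order(-best_q$fold_enrichment, best_q$p_value, pos_q$gene)
    pos_q <- pos_q[ord, , drop = FALSE]
    best_q <- best_q[ord, , drop = FALSE]
  }
  if (nrow(pos_q) < n_positive) {
    warning(sprintf(
      "only %d positive-strength hub(s) are annotated to a significant term; selecting all",
      nrow(pos_q)))
  }
  take <- seq_len(min(n_positive, nrow(pos_q)))
  sel_pos <- pos_q[take, , drop = FALSE]
  best_taken <- best_q[take, , drop = FALSE]

  rationale <- c(
    stats::setNames(
      sprintf("node strength %d < 0: selected unconditionally", neg$strength),
      neg$gene),
    stats::setNames(
      sprintf("node strength +%d; best significant term %s (fold enrichment %.3g, p_adj %.3g)",
              sel_pos$strength, best_taken$term,
              best_taken$fold_enrichment, best_taken$p_adjusted),
      sel_pos$gene)
  )
  structure(list(
    hubs_considered = hub_df,
    selected_negative = neg$gene,
    selected_positive = sel_pos$gene,
    selected_total = c(neg$gene, sel_pos$gene),
    rationale = rationale
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report:", length(x$selected_total), "candidate(s)\n")
  for (g in x$selected_total) cat("  ", g, "-", x$rationale[[g]], "\n")
  invisible(x)
}

#' Write a selection report as JSON and a marks table as TSV
#'
#' The TSV mirrors the shape of a published hub table: one row per
#' selected gene, one column per DE miRNA with a `+` mark where the
#' network contains the edge, plus the node strength.
#'
#' @param report a [select_candidates()] result.
#' @param net the underlying `signed_network`.
#' @param path_tsv,path_json output files (either may be `NULL`).
#' @return invisible list of the written paths.
#' @export
write_selection <- function(report, net, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    mirnas <- net$mirnas$mirna
    marks <- vapply(mirnas, function(m) {
      ifelse(paste(m, report$selected_total) %in%
               paste(net$edges$mirna, net$edges$gene), "+", "")
    }, character(length(report$selected_total)))
    marks <- matrix(marks, nrow = length(report$selected_total),
                    dimnames = list(NULL, mirnas))
    tab <- data.frame(gene = report$selected_total, marks,
                      strength = vapply(report$selected_total,
                                        function(g) node_strength(net, g),
                                        1L),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(selected_total = report$selected_total,
           selected_negative = report$selected_negative,
           selected_positive = report$selected_positive,
           rationale = as.list(report$rationale)),
      path_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(tsv = path_tsv, json = path_json))
}
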