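#' Normalize a mature miRNA name
#'
#' Case-folds the species prefix and the miR stem to one canonical
#' lower-case form while preserving the numeric id and the -3p/-5p arm
#' suffix (arms are distinct mature sequences and are never stripped).
#' Idempotent.
#'
#' @param raw character vector of miRNA names (non-empty strings).
#' @return normalized names.
#' @export
#' @examples
#' normalize_mirna_name("RNO-MIR-141-3P") == normalize_mirna_name("rno-miR-141-3p")
normalize_mirna_name <- function(raw) {
  if (!is.character(raw) || any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("miRNA names must be non-empty strings")
  }
  tolower(trimws(raw))
}

#' Read one interaction table
#'
#' Expects tab-separated columns `mirna`, `gene`, and either `score`
#' (predicted sources) or `evidence` (curated source); a `source` column in
#' the file wins over the argument. Malformed rows (missing miRNA or gene,
#' unparseable score for a predicted source) are skipped with a warning
#' reporting the skip count.
#'
#' @param path TSV file.
#' @param source one of `predicted_scoreA` (0-100 prediction score),
#'   `predicted_scoreB` (mirSVR-style regression score, <= 0), `curated`.
#' @return data.frame with columns `mirna`, `gene`, `score` (NA for
#'   curated), `evidence`, `source`.
#' @export
read_interaction_table <- function(path,
                                   source = c("predicted_scoreA",
                                              "predicted_scoreB", "curated")) {
  source <- match.arg(source)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("source" %in% names(raw)) source <- raw$source[1]
  as_interaction_table(raw, source)
}

# Validate/coerce an in-memory interaction table; skips malformed rows.
as_interaction_table <- function(raw, source) {
  if (!all(c("mirna", "gene") %in% names(raw))) {
    stop("interaction table needs 'mirna' and 'gene' columns")
  }
  score <- if ("score" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$score))
  } else rep(NA_real_, nrow(raw))
  evidence <- if ("evidence" %in% names(raw)) {
    as.character(raw$evidence)
  } else rep(NA_character_, nrow(raw))
  ok_id <- !is.na(raw$mirna) & nzchar(trimws(raw$mirna)) &
    !is.na(raw$gene) & nzchar(trimws(raw$gene))
  ok <- ok_id & if (source == "curated") TRUE else !is.na(score)
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warning(sprintf("skipped %d malformed row(s) in %s table", n_skip, source))
  }
  data.frame(
    mirna = if (any(ok)) normalize_mirna_name(raw$mirna[ok]) else character(0),
    gene = toupper(trimws(raw$gene[ok])),
    score = score[ok],
    evidence = evidence[ok],
    source = rep(source, sum(ok)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# The filter contract for a single source.
.passes_filter <- function(source, score, score_cutoff, mirsvr_cutoff) {
  switch(source,
    predicted_scoreA = !is.na(score) & score > score_cutoff,
    predicted_scoreB = !is.na(score) & score < mirsvr_cutoff,
    curated = rep(TRUE, length(score)),
    stop("unknown interaction source: ", source)
  )
}

#' Integrate predicted and curated miRNA-target interactions
#'
#' Restricts the three interaction sources to significantly differentially
#' expressed miRNAs, applies each source's filter (prediction score
#' strictly above `score_cutoff`; regression score strictly below
#' `mirsvr_cutoff`; curated interactions accepted unconditionally), and
#' unions the passing records, deduplicating `(mirna, gene)` pairs while
#' recording every contributing source.
#'
#' @param predicted_a,predicted_b,curated interaction tables (data.frames
#'   with `mirna`, `gene` and `score`/`evidence`, e.g. from
#'   [read_interaction_table()] or [simulate_target_databases()]).
#' @param de a `de_result` (or a named direction vector from
#'   [de_directions()]); only its significant miRNAs are kept.
#' @param score_cutoff strict lower cutoff for the prediction score
#'   (default 80).
#' @param mirsvr_cutoff strict upper cutoff for the regression score
#'   (default -1.2).
#' @param alpha FDR threshold used to call significance from `de`.
#' @return data.frame of class `interaction_set`, sorted by
#'   `(gene, mirna)`, with columns `mirna`, `gene`, `sources`
#'   (comma-joined), `n_sources`, `best_score` (prediction score if
#'   present, else regression score, else NA) and `evidence`.
#' @export
integrate_targets <- function(predicted_a, predicted_b, curated, de,
                              score_cutoff = 80, mirsvr_cutoff = -1.2,
                              alpha = 0.05) {
  dirs <- if (is.character(de)) de else de_directions(de, alpha)
  if (!length(dirs)) stop("no significantly DE miRNA to integrate over")
  tabs <- list(
    as_interaction_table(predicted_a, "predicted_scoreA"),
    as_interaction_table(predicted_b, "predicted_scoreB"),
    as_interaction_table(curated, "curated")
  )
  recs <- do.call(rbind, tabs)
  recs <- recs[recs$mirna %in% names(dirs), , drop = FALSE]
  pass <- logical(nrow(recs))
  for (s in unique(recs$source)) {
    i <- recs$source == s
    pass[i] <- .passes_filter(s, recs$score[i], score_cutoff, mirsvr_cutoff)
  }
  recs <- recs[pass, , drop = FALSE]
  if (nrow(recs) == 0) {
    out <- data.frame(mirna = character(0), gene = character(0),
                      sources = character(0), n_sources = integer(0),
                      best_score = numeric(0), evidence = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("interaction_set", "data.frame")
    return(out)
  }
  key <- paste(recs$mirna, recs$gene, sep = "\r")
  split_idx <- split(seq_len(nrow(recs)), key)
  rows <- lapply(split_idx, function(i) {
    r <- recs[i, , drop = FALSE]
    srcs <- sort(unique(r$source))
    sa <- r$score[r$source == "predicted_scoreA"]
    sb <- r$score[r$source == "predicted_scoreB"]
    best <- if (length(sa)) max(sa) else if (length(sb)) min(sb) else NA_real_
    ev <- r$evidence[!is.na(r$evidence)]
    data.frame(mirna = r$mirna[1], gene = r$gene[1],
               sources = paste(srcs, collapse = ","),
               n_sources = length(srcs),
               best_score = best,
               evidence = if (length(ev)) ev[1] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  out
}
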