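#' Pipeline configuration
#'
#' Collects all file paths and tunable parameters for [run_pipeline()].
#' Referenced input files must exist.
#'
#' @param counts counts TSV (see [read_count_matrix()]).
#' @param predicted_a,predicted_b,curated the three interaction TSVs.
#' @param annotation GMT annotation file.
#' @param cp_table optional Cp TSV; the qPCR stage runs only when given.
#' @param primers,transcripts optional primer TSV and transcript FASTA;
#'   the amplicon-check stage runs only when both are given.
#' @param out_dir output directory (created if needed).
#' @param alpha DE significance (FDR) threshold.
#' @param enrich_alpha adjusted-p threshold for enrichment/selection.
#' @param min_total detectability filter threshold.
#' @param score_cutoff,mirsvr_cutoff integration cutoffs (strict).
#' @param hub_policy `"max_degree"` or `"threshold"`; `hub_k` for the
#'   latter.
#' @param hub_k degree threshold when `hub_policy = "threshold"`.
#' @param n_positive positive-strength hubs to select.
#' @param correction `"BH"` or `"bonferroni"` for enrichment.
#' @param reference_gene qPCR reference gene.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when inputs are simulated).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, predicted_a, predicted_b, curated,
                            annotation, cp_table = NULL, primers = NULL,
                            transcripts = NULL, out_dir = "mirnethub_out",
                            alpha = 0.05, enrich_alpha = 0.05,
                            min_total = 1, score_cutoff = 80,
                            mirsvr_cutoff = -1.2,
                            hub_policy = "max_degree", hub_k = NULL,
                            n_positive = 3, correction = "BH",
                            reference_gene = "HPRT", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, enrich_alpha > 0, enrich_alpha < 1,
            is.finite(score_cutoff), is.finite(mirsvr_cutoff),
            n_positive >= 0)
  paths <- c(counts = counts, predicted_a = predicted_a,
             predicted_b = predicted_b, curated = curated,
             annotation = annotation, cp_table = cp_table,
             primers = primers, transcripts = transcripts)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing)) {
    stop("input file(s) not found: ",
         paste(names(missing), missing, sep = " = ", collapse = ", "))
  }
  structure(list(
    counts = counts, predicted_a = predicted_a, predicted_b = predicted_b,
    curated = curated, annotation = annotation, cp_table = cp_table,
    primers = primers, transcripts = transcripts, out_dir = out_dir,
    alpha = alpha, enrich_alpha = enrich_alpha, min_total = min_total,
    score_cutoff = score_cutoff, mirsvr_cutoff = mirsvr_cutoff,
    hub_policy = hub_policy, hub_k = hub_k, n_positive = n_positive,
    correction = correction, reference_gene = reference_gene,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order: read and filter counts, differential expression, target
#' integration, signed network with hub report, GO enrichment of the full
#' predicted target set, candidate selection, and (when inputs are
#' provided) qPCR statistics and in-silico amplicon checks. Every stage
#' writes its table to `out_dir` and logs a row-count summary, so the
#' analysis funnel (miRNAs kept by the detectability filter, significant
#' miRNAs, integrated interactions, hubs, selected candidates) is
#' machine-readable on any input. A `manifest.json` records input
#' checksums, parameters and the package version; given identical inputs
#' the run is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisible list with the in-memory stage results (`counts`,
#'   `de`, `interactions`, `network`, `hubs`, `enrichment`, `selection`,
#'   `qpcr`, `amplicons`, `funnel`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[mirnethub] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "read_counts"
  res <- tryCatch({
    cm <- read_count_matrix(config$counts)
    n_total <- nrow(cm$counts)
    cm <- filter_detectable(cm, config$min_total)
    say("counts: ", n_total, " miRNAs, ", nrow(cm$counts),
        " detectable (min_total = ", config$min_total, ")")

    stage <- "differential_expression"
    de <- test_de(cm, alpha = config$alpha)
    write_de_table(de, out("de_results.tsv"))
    n_sig <- sum(de$direction != "ns")
    say("DE: ", n_sig, " significant miRNA(s) at FDR < ", config$alpha,
        " (", sum(de$direction == "up"), " up / ",
        sum(de$direction == "down"), " down)")

    stage <- "target_integration"
    ints <- integrate_targets(
      read_interaction_table(config$predicted_a, "predicted_scoreA"),
      read_interaction_table(config$predicted_b, "predicted_scoreB"),
      read_interaction_table(config$curated, "curated"),
      de, score_cutoff = config$score_cutoff,
      mirsvr_cutoff = config$mirsvr_cutoff, alpha = config$alpha)
    write_interaction_table(ints, out("interactions.tsv"))
    say("integration: ", nrow(ints), " interaction(s), ",
        length(unique(ints$gene)), " predicted target gene(s)")

    stage <- "signed_network"
    net <- build_network(ints, de, alpha = config$alpha)
    write_network_sif(net, out("network.sif"))
    write_network_graphml(net, out("network.graphml"))
    write_gene_stats(net, out("gene_stats.tsv"))
    hubs <- find_hubs(net, policy = config$hub_policy, k = config$hub_k)
    utils::write.table(hubs$hubs, out("hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("network: ", nrow(net$edges), " edges; max target degree ",
        hubs$max_degree, "; ", nrow(hubs$hubs), " hub(s)")

    stage <- "go_enrichment"
    annotation <- read_gmt(config$annotation)
    universe <- unique(unlist(annotation, use.names = FALSE))
    targets <- intersect(unique(net$genes$gene), universe)
    dropped <- setdiff(unique(net$genes$gene), universe)
    if (length(dropped)) {
      say("enrichment: dropping ", length(dropped),
          " target(s) absent from the annotation universe")
    }
    enr <- enrich_targets(targets, annotation, universe = universe,
                          method = config$correction)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("enrichment: ", nrow(enr), " term(s) tested, ",
        sum(enr$p_adjusted < config$enrich_alpha), " significant")

    stage <- "prioritization"
    sel <- select_candidates(hubs, net, enr, annotation,
                             n_positive = config$n_positive,
                             alpha = config$enrich_alpha)
    write_selection(sel, net, out("selection.tsv"), out("selection.json"))
    say("selection: ", length(sel$selected_total), " candidate(s): ",
        paste(sel$selected_total, collapse = ", "))

    qpcr <- NULL
    if (!is.null(config$cp_table)) {
      stage <- "qpcr_validation"
      cp <- read_cp_table(config$cp_table)
      qpcr <- ddcp_all(cp, config$reference_gene)
      utils::write.table(qpcr, out("qpcr_results.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      say("qPCR: ", sum(qpcr$significant, na.rm = TRUE), " of ",
          nrow(qpcr), " target(s) significant")
    }
    amplicons <- NULL
    if (!is.null(config$primers) && !is.null(config$transcripts)) {
      stage <- "amplicon_check"
      pr <- read_primer_table(config$primers)
      fa <- Biostrings::readDNAStringSet(config$transcripts)
      amplicons <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
        hit <- which(grepl(pr$accession[i], names(fa), fixed = TRUE) |
                       grepl(pr$gene[i], names(fa), ignore.case = TRUE))
        size <- if (length(hit)) {
          tryCatch(verify_amplicon(pr[i, ], fa[[hit[1]]]),
                   error = function(e) NA_integer_)
        } else NA_integer_
        data.frame(gene = pr$gene[i], expected = pr$product_size[i],
                   observed = size, stringsAsFactors = FALSE)
      }))
      utils::write.table(amplicons, out("amplicons.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    inputs <- Filter(Negate(is.null),
                     list(counts = config$counts,
                          predicted_a = config$predicted_a,
                          predicted_b = config$predicted_b,
                          curated = config$curated,
                          annotation = config$annotation,
                          cp_table = config$cp_table,
                          primers = config$primers,
                          transcripts = config$transcripts))
    manifest <- list(
      package = "mirnethub",
      version = as.character(utils::packageVersion("mirnethub")),
      inputs = lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      parameters = config[setdiff(names(config),
                                  c(names(inputs), "out_dir"))],
      funnel = list(
        mirnas_total = n_total,
        mirnas_detectable = nrow(cm$counts),
        mirnas_significant = n_sig,
        interactions = nrow(ints),
        target_genes = length(unique(ints$gene)),
        max_degree = hubs$max_degree,
        hubs = nrow(hubs$hubs),
        selected = length(sel$selected_total)
      )
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(counts = cm, de = de, interactions = ints, network = net,
         hubs = hubs, enrichment = enr, selection = sel, qpcr = qpcr,
         amplicons = amplicons, funnel = manifest$funnel)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Simulate a full input set and write it to disk
#'
#' Convenience wrapper tying the generators together: writes the counts
#' TSV, the three interaction TSVs, the GMT annotation, the Cp table and
#' the ground truth JSON into a directory, ready for [pipeline_config()].
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return named list of written file paths plus the `truth` object.
#' @export
simulate_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_counts(config)
  write_count_matrix(sim$counts, p("counts.tsv"))
  dbs <- simulate_target_databases(config)
  write_interaction_table(dbs$predicted_a, p("predicted_a.tsv"))
  write_interaction_table(dbs$predicted_b, p("predicted_b.tsv"))
  write_interaction_table(dbs$curated, p("curated.tsv"))
  write_gmt(simulate_go_annotation(config), p("annotation.gmt"))
  write_cp_table(simulate_qpcr(config), p("cp_table.tsv"))
  jsonlite::write_json(sim$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(counts = p("counts.tsv"), predicted_a = p("predicted_a.tsv"),
       predicted_b = p("predicted_b.tsv"), curated = p("curated.tsv"),
       annotation = p("annotation.gmt"), cp_table = p("cp_table.tsv"),
       ground_truth = p("ground_truth.json"), truth = sim$truth)
}
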