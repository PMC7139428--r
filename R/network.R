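#' Build the signed bipartite miRNA-target network
#'
#' miRNAs and target genes are nodes; each predicted interaction is an edge
#' whose weight is +1 when the regulating miRNA is upregulated and -1 when
#' it is downregulated. Per-gene degree is the number of incident edges and
#' node strength is the sum of incident weights, so a target regulated by
#' three miRNAs of which one moves opposite to the other two has degree 3
#' and strength +1 or -1.
#'
#' @param interactions data.frame with columns `mirna`, `gene` (e.g. an
#'   [integrate_targets()] result). Parallel edges are collapsed.
#' @param de a `de_result` or a named `mirna -> "up"/"down"` vector; every
#'   interaction miRNA must be significantly DE here, otherwise an error is
#'   raised (the integration step upstream guarantees this).
#' @param alpha FDR threshold when `de` is a `de_result`.
#' @param genes optional extra gene symbols to include as isolated nodes
#'   (degree and strength 0), e.g. to pad the network to a fixed universe.
#' @return object of class `signed_network`: list with `edges`
#'   (mirna/gene/weight), `genes` (gene/degree/strength), `mirnas`
#'   (mirna/direction/out_degree/out_strength).
#' @export
#' @examples
#' net <- table2_network()
#' net$genes
build_network <- function(interactions, de, alpha = 0.05, genes = NULL) {
  dirs <- if (is.character(de)) de else de_directions(de, alpha)
  if (nrow(interactions) == 0) {
    empty_genes <- data.frame(gene = character(0), degree = integer(0),
                              strength = integer(0),
                              stringsAsFactors = FALSE)
    if (!is.null(genes)) {
      empty_genes <- data.frame(gene = sort(unique(toupper(genes))),
                                degree = 0L, strength = 0L,
                                stringsAsFactors = FALSE)
    }
    return(structure(list(
      edges = data.frame(mirna = character(0), gene = character(0),
                         weight = integer(0), stringsAsFactors = FALSE),
      genes = empty_genes,
      mirnas = data.frame(mirna = character(0), direction = character(0),
                          out_degree = integer(0), out_strength = integer(0),
                          stringsAsFactors = FALSE)
    ), class = "signed_network"))
  }
  mirna <- normalize_mirna_name(interactions$mirna)
  gene <- toupper(trimws(interactions$gene))
  unknown <- setdiff(unique(mirna), names(dirs))
  if (length(unknown)) {
    stop("interaction miRNA(s) without a significant DE direction: ",
         paste(unknown, collapse = ", "))
  }
  edges <- unique(data.frame(mirna = mirna, gene = gene,
                             stringsAsFactors = FALSE))
  edges$weight <- ifelse(dirs[edges$mirna] == "up", 1L, -1L)
  edges <- edges[order(edges$gene, edges$mirna), , drop = FALSE]
  rownames(edges) <- NULL

  gene_ids <- sort(unique(c(edges$gene,
                            if (!is.null(genes)) toupper(genes))))
  deg <- tapply(edges$weight, edges$gene, length)
  stren <- tapply(edges$weight, edges$gene, sum)
  genes <- data.frame(gene = gene_ids, stringsAsFactors = FALSE)
  d <- deg[gene_ids]
  d[is.na(d)] <- 0L
  s <- stren[gene_ids]
  s[is.na(s)] <- 0L
  genes$degree <- as.integer(d)
  genes$strength <- as.integer(s)
  mirnas <- data.frame(
    mirna = sort(unique(edges$mirna)),
    stringsAsFactors = FALSE
  )
  mirnas$direction <- unname(dirs[mirnas$mirna])
  mirnas$out_degree <- as.integer(tapply(edges$weight, edges$mirna,
                                         length)[mirnas$mirna])
  mirnas$out_strength <- as.integer(tapply(edges$weight, edges$mirna,
                                           sum)[mirnas$mirna])
  structure(list(edges = edges, genes = genes, mirnas = mirnas),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("signed_network:", nrow(x$mirnas), "miRNAs,", nrow(x$genes),
      "target genes,", nrow(x$edges), "signed edges\n")
  invisible(x)
}

#' Node strength of a target gene
#'
#' Sum of the signed weights of the edges incident to a target node.
#'
#' @param net a [build_network()] result.
#' @param gene gene symbol (case-insensitive).
#' @return integer strength in `[-degree, degree]`.
#' @export
node_strength <- function(net, gene) {
  stopifnot(inherits(net, "signed_network"))
  gene <- toupper(trimws(gene))
  i <- match(gene, net$genes$gene)
  if (is.na(i)) stop("gene not present in the network: ", gene)
  net$genes$strength[i]
}

#' Identify target hubs
#'
#' Under the default `max_degree` policy, hubs are the target genes whose
#' degree equals the maximal observed target degree (i.e. the targets hit
#' by the largest number of differentially expressed miRNAs). The
#' `threshold` policy returns all genes with degree at least `k`.
#'
#' @param net a [build_network()] result with at least one gene node.
#' @param policy `"max_degree"` or `"threshold"`.
#' @param k degree threshold (required for `policy = "threshold"`).
#' @return object of class `hub_report`: list with `max_degree`, `policy`
#'   and `hubs` (data.frame gene/degree/strength, sorted by gene).
#' @export
find_hubs <- function(net, policy = c("max_degree", "threshold"), k = NULL) {
  stopifnot(inherits(net, "signed_network"))
  policy <- match.arg(policy)
  if (nrow(net$genes) == 0) stop("empty network: no target nodes")
  max_degree <- max(net$genes$degree)
  hubs <- switch(policy,
    max_degree = net$genes[net$genes$degree == max_degree, , drop = FALSE],
    threshold = {
      if (is.null(k)) stop("threshold policy needs k")
      net$genes[net$genes$degree >= k, , drop = FALSE]
    }
  )
  hubs <- hubs[order(hubs$gene), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(max_degree = max_degree, policy = policy, k = k,
                 hubs = hubs),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("hub_report (", x$policy, "): max degree", x$max_degree, "-",
      nrow(x$hubs), "hub(s)\n")
  print(x$hubs)
  invisible(x)
}

#' Write a network as SIF (`mirna regulates gene`)
#' @param net a `signed_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(net, path) {
  rel <- ifelse(net$edges$weight > 0, "activates_expression_with",
                "represses_expression_with")
  writeLines(paste(net$edges$mirna, rel, net$edges$gene, sep = "\t"), path)
  invisible(path)
}

#' Write a network as GraphML with weight and direction attributes
#' @param net a `signed_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "weight")],
    directed = TRUE,
    vertices = data.frame(
      name = c(net$mirnas$mirna, net$genes$gene),
      type = c(rep("mirna", nrow(net$mirnas)),
               rep("gene", nrow(net$genes))),
      direction = c(net$mirnas$direction, rep(NA_character_,
                                              nrow(net$genes))),
      strength = c(net$mirnas$out_strength, net$genes$strength),
      stringsAsFactors = FALSE
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write per-gene degree and strength as TSV
#' @param net a `signed_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(net, path) {
  utils::write.table(net$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
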