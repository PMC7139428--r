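# Packaged worked-example tables from a published two-group cardiac
# small-RNA study in a rat prediabetes model: the five differentially
# expressed left-ventricle miRNAs, their five selected target-hub genes
# with per-miRNA interaction marks, and the qRT-PCR primer pairs used for
# validation. They make the network arithmetic and the qPCR machinery
# checkable end to end without any download.

.extdata <- function(file) {
  system.file("extdata", file, package = "mirnethub", mustWork = TRUE)
}

#' Bundled differentially expressed miRNA table
#'
#' Five differentially expressed cardiac miRNAs (two up, three down at
#' FDR < 0.05) with log2 fold changes. Censored printed values such as
#' `<0.001` are parsed to their bound, with `p_censored`/`fdr_censored`
#' flags set (the bound is an upper bound on the true value).
#'
#' @return data.frame with columns `mirna`, `logFC`, `p_value`, `fdr`,
#'   `direction`, `p_censored`, `fdr_censored`.
#' @export
#' @examples
#' de_summary(fixture_table1())
fixture_table1 <- function() {
  raw <- utils::read.delim(.extdata("table1_de_mirnas.tsv"),
                           stringsAsFactors = FALSE)
  parse_cens <- function(x) {
    cens <- grepl("^<", x)
    list(value = as.numeric(sub("^<", "", x)), censored = cens)
  }
  p <- parse_cens(raw$p_value)
  f <- parse_cens(raw$fdr)
  data.frame(
    mirna = raw$mirna,
    logFC = as.numeric(raw$logFC),
    p_value = p$value,
    fdr = f$value,
    direction = raw$expression_change,
    p_censored = p$censored,
    fdr_censored = f$censored,
    stringsAsFactors = FALSE
  )
}

#' Bundled target-hub interaction marks
#'
#' Tidy transcription of the selected target-gene table: one row per
#' predicted miRNA-target interaction mark (15 marks over 5 genes; every
#' gene is hit by exactly three differentially expressed miRNAs).
#'
#' @return data.frame with columns `gene`, `gene_name`, `mirna`.
#' @export
fixture_table2 <- function() {
  utils::read.delim(.extdata("table2_target_hubs.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled qRT-PCR primer table
#'
#' Six primer pairs (five targets plus the HPRT reference) with transcript
#' accessions and expected product sizes.
#'
#' @return data.frame with columns `gene`, `accession`, `forward`,
#'   `reverse`, `product_size`.
#' @export
fixture_table3 <- function() {
  read_primer_table(.extdata("table3_primers.tsv"))
}

#' Signed network of the bundled worked example
#'
#' Builds the signed bipartite network from the bundled interaction marks
#' ([fixture_table2()]) with miRNA directions taken from the bundled DE
#' table ([fixture_table1()]): 5 target genes, 15 signed edges, maximal
#' target degree 3, node strengths (+1, +1, +1, -1, -1).
#'
#' @return a `signed_network`.
#' @export
#' @examples
#' find_hubs(table2_network())
table2_network <- function() {
  t1 <- fixture_table1()
  dirs <- stats::setNames(t1$direction, normalize_mirna_name(t1$mirna))
  build_network(fixture_table2(), dirs)
}
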