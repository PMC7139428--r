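#' Read a qPCR Cp table
#'
#' @param path TSV with columns `sample`, `group` (`control`/`treated`),
#'   `gene`, `replicate`, `cp`.
#' @return validated data.frame.
#' @export
read_cp_table <- function(path) {
  cp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "replicate", "cp")
  if (!all(need %in% names(cp))) {
    stop("Cp table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(cp$group %in% c("control", "treated"))) {
    stop("group must be 'control' or 'treated'")
  }
  if (any(!is.finite(cp$cp)) || any(cp$cp <= 0)) {
    stop("Cp values must be positive finite cycles")
  }
  cp
}

#' Relative expression by the 2^-ddCp method
#'
#' Duplicate wells are averaged on the Cp scale per `(sample, gene)`. For
#' each sample, `dCp = Cp(target) - Cp(reference)`; `ddCp` is referenced to
#' the mean `dCp` of the control group, and relative expression is
#' `2^-ddCp` (so the control-group mean of `-ddCp` is 0 and its geometric
#' mean expression is 1 by construction). Group means with standard errors
#' and an unpaired two-sample t-test on the per-sample expressions are
#' reported.
#'
#' @param cp a Cp table (see [read_cp_table()] / [simulate_qpcr()]).
#' @param reference_gene reference (housekeeping) gene, measured in every
#'   sample; samples missing it are excluded with a warning.
#' @param target_gene the gene to quantify.
#' @param var_equal `TRUE` for Student's equal-variance t-test (default),
#'   `FALSE` for Welch.
#' @param alpha significance threshold for the `significant` flag.
#' @return object of class `ddcp_result`: list with `gene`, `expression`
#'   (per-sample data.frame: sample, group, dcp, ddcp, expression),
#'   `control_mean`, `treated_mean`, `sem_control`, `sem_treated`, `t`,
#'   `p_value`, `significant`. With fewer than two samples in a group no
#'   test is run (`p_value = NA`, warning); with zero variance in both
#'   groups and equal means the p-value is 1 by convention (warning).
#' @export
#' @examples
#' cp <- simulate_qpcr(simulation_config(qpcr_effects = c(JAZF1 = 0.5),
#'                                       qpcr_noise_sd = 0, rng_seed = 1))
#' ddcp(cp, "HPRT", "JAZF1")$treated_mean
ddcp <- function(cp, reference_gene, target_gene, var_equal = TRUE,
                 alpha = 0.05) {
  stopifnot(all(c("sample", "group", "gene", "cp") %in% names(cp)))
  if (!any(cp$gene == reference_gene)) {
    stop("reference gene not in Cp table: ", reference_gene)
  }
  if (!any(cp$gene == target_gene)) {
    stop("target gene not in Cp table: ", target_gene)
  }
  # mean of duplicate wells on the Cp scale
  agg <- stats::aggregate(cp ~ sample + group + gene, data = cp, FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample", "cp")]
  tgt <- agg[agg$gene == target_gene, c("sample", "group", "cp")]
  missing_ref <- setdiff(tgt$sample, ref$sample)
  if (length(missing_ref)) {
    warning("excluding sample(s) without the reference gene: ",
            paste(missing_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample %in% missing_ref, , drop = FALSE]
  }
  tgt$dcp <- tgt$cp - ref$cp[match(tgt$sample, ref$sample)]
  ctrl_mean_dcp <- mean(tgt$dcp[tgt$group == "control"])
  tgt$ddcp <- tgt$dcp - ctrl_mean_dcp
  tgt$expression <- 2^(-tgt$ddcp)

  xc <- tgt$expression[tgt$group == "control"]
  xt <- tgt$expression[tgt$group == "treated"]
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  tstat <- p <- NA_real_
  if (length(xc) < 2 || length(xt) < 2) {
    warning("fewer than two samples in a group: no test performed")
  } else if (stats::sd(xc) == 0 && stats::sd(xt) == 0) {
    warning("zero variance in both groups: no test performed")
    p <- if (mean(xc) == mean(xt)) 1 else NA_real_
  } else {
    tt <- stats::t.test(xt, xc, var.equal = var_equal)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    gene = target_gene,
    reference_gene = reference_gene,
    expression = tgt[, c("sample", "group", "dcp", "ddcp", "expression")],
    control_mean = mean(xc),
    treated_mean = mean(xt),
    sem_control = sem(xc),
    sem_treated = sem(xt),
    t = tstat,
    p_value = p,
    significant = !is.na(p) && p < alpha
  ), class = "ddcp_result")
}

#' @export
print.ddcp_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: control %.3f +/- %.3f, treated %.3f +/- %.3f (t = %.3f, p = %.3g)%s\n",
    x$gene, x$reference_gene, x$control_mean, x$sem_control,
    x$treated_mean, x$sem_treated, x$t, x$p_value,
    if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' 2^-ddCp statistics for every target gene in a Cp table
#'
#' @param cp a Cp table.
#' @param reference_gene reference gene.
#' @param genes target genes; defaults to all non-reference genes.
#' @param var_equal,alpha passed to [ddcp()].
#' @return data.frame with one row per gene: `gene`, `control_mean`,
#'   `treated_mean`, `sem_control`, `sem_treated`, `t`, `p_value`,
#'   `significant`.
#' @export
ddcp_all <- function(cp, reference_gene, genes = NULL, var_equal = TRUE,
                     alpha = 0.05) {
  if (is.null(genes)) genes <- setdiff(unique(cp$gene), reference_gene)
  rows <- lapply(genes, function(g) {
    r <- ddcp(cp, reference_gene, g, var_equal = var_equal, alpha = alpha)
    data.frame(gene = g, control_mean = r$control_mean,
               treated_mean = r$treated_mean, sem_control = r$sem_control,
               sem_treated = r$sem_treated, t = r$t, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a primer table
#'
#' @param path TSV with columns `gene`, `accession`, `forward`, `reverse`,
#'   `product_size`.
#' @return data.frame (sequences upper-cased and validated over ACGT).
#' @export
read_primer_table <- function(path) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "accession", "forward", "reverse", "product_size")
  if (!all(need %in% names(pr))) {
    stop("primer table needs columns: ", paste(need, collapse = ", "))
  }
  pr$forward <- toupper(pr$forward)
  pr$reverse <- toupper(pr$reverse)
  if (any(grepl("[^ACGT]", c(pr$forward, pr$reverse)))) {
    stop("primer sequences must be over A/C/G/T")
  }
  pr
}

#' In-silico amplicon size for a primer pair on a transcript
#'
#' Locates exact matches of the forward primer and of the reverse
#' complement of the reverse primer on the spliced transcript (cDNA sense
#' strand). The product size is `end(reverse site) - start(forward site)
#' + 1` in 1-based inclusive coordinates. With several compatible site
#' pairs the smallest product is returned with a warning; if either primer
#' is absent, or every reverse site lies upstream of every forward site, a
#' no-amplicon error is raised. Matching is exact-string only (design-time
#' checks such as dimers or self-priming are not re-evaluated here).
#'
#' @param primers list or one-row data.frame with `forward` and `reverse`
#'   sequences (5'->3').
#' @param transcript character string, `DNAString`, or a
#'   `DNAStringSet` of length 1 (e.g. from
#'   [Biostrings::readDNAStringSet()]).
#' @return integer product size in bp.
#' @export
verify_amplicon <- function(primers, transcript) {
  fwd <- toupper(as.character(primers$forward))
  rev <- toupper(as.character(primers$reverse))
  if (!nzchar(fwd) || !nzchar(rev)) stop("both primers are required")
  if (inherits(transcript, "DNAStringSet")) {
    if (length(transcript) != 1) stop("provide a single transcript")
    transcript <- transcript[[1]]
  }
  subject <- if (inherits(transcript, "DNAString")) transcript else
    Biostrings::DNAString(toupper(as.character(transcript)))
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rhits <- Biostrings::matchPattern(rc, subject)
  if (length(fhits) == 0 || length(rhits) == 0) {
    stop("no amplicon: ", if (length(fhits) == 0) "forward" else "reverse",
         " primer has no exact match on the transcript")
  }
  fs <- Biostrings::start(fhits)
  re <- Biostrings::end(rhits)
  rs <- Biostrings::start(rhits)
  sizes <- c()
  for (i in seq_along(fs)) {
    ok <- rs >= fs[i]  # reverse site must not lie upstream of the forward site
    sz <- re[ok] - fs[i] + 1
    sizes <- c(sizes, sz[sz >= max(nchar(fwd), nchar(rev))])
  }
  if (!length(sizes)) {
    stop("no amplicon: every reverse site lies upstream of the forward site")
  }
  if (length(sizes) > 1 || length(fhits) > 1 || length(rhits) > 1) {
    warning("multiple primer sites: reporting the smallest product")
  }
  as.integer(min(sizes))
}
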