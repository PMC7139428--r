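#' Simulation configuration with planted ground truth
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults emulate the study conditions of a two-group cardiac
#' small-RNA experiment: 6 left-ventricle samples per group for sequencing,
#' 7 per group for qPCR, a few hundred detectable mature miRNAs, negative
#' binomial counts with moderate biological dispersion, and a handful of
#' strongly differentially expressed miRNAs.
#'
#' @param n_samples_per_group samples per group for the count matrix.
#' @param n_mirnas number of mature miRNAs simulated.
#' @param n_de_mirnas number of planted differentially expressed miRNAs
#'   (the first `n_de_mirnas` miRNAs, with alternating up/down signs).
#' @param de_log2fc_magnitude absolute planted log2 fold change
#'   (treated vs control). `0` gives a pure null.
#' @param dispersion negative binomial dispersion phi, so that
#'   `Var = mu + phi * mu^2`.
#' @param mean_log_expression_range range (log2 units) of per-miRNA baseline
#'   relative expression, drawn uniformly.
#' @param library_size_range range of per-sample library sizes (reads).
#' @param n_genes size of the simulated target-gene universe.
#' @param planted_hub_spec named list: `gene -> character vector` of
#'   regulating DE miRNA names. Every regulator must be a planted DE miRNA
#'   (see [planted_de()]).
#' @param go_term_blocks named list: `term id -> character vector` of genes,
#'   the enriched annotation blocks planted into the GO annotation.
#' @param n_background_terms number of random background GO terms.
#' @param qpcr_effects named numeric: `gene -> true fold change` planted into
#'   the Cp table (treated vs control). The reference gene is fixed at 1.
#' @param qpcr_noise_sd Gaussian noise SD on the Cp scale (cycles).
#' @param qpcr_samples_per_group samples per group in the Cp table.
#' @param qpcr_reference name of the reference gene (fold change fixed at 1).
#' @param rng_seed integer seed; all generators are deterministic given the
#'   seed (each generator uses its own fixed offset of this seed).
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_target_databases()],
#'   [simulate_qpcr()], [simulate_go_annotation()], [ground_truth()]
#' @export
#' @examples
#' cfg <- simulation_config(n_mirnas = 50, n_de_mirnas = 4, rng_seed = 7)
#' head(planted_de(cfg))
simulation_config <- function(n_samples_per_group = 6L,
                              n_mirnas = 500L,
                              n_de_mirnas = 20L,
                              de_log2fc_magnitude = 2,
                              dispersion = 0.1,
                              mean_log_expression_range = c(1, 8),
                              library_size_range = c(8e5, 1.2e6),
                              n_genes = 2000L,
                              planted_hub_spec = list(),
                              go_term_blocks = list(),
                              n_background_terms = 50L,
                              qpcr_effects = c(JAZF1 = 0.5),
                              qpcr_noise_sd = 0.15,
                              qpcr_samples_per_group = 7L,
                              qpcr_reference = "HPRT",
                              rng_seed = 1L) {
  stopifnot(
    n_samples_per_group >= 1, n_mirnas >= 1, n_genes >= 1,
    de_log2fc_magnitude >= 0, dispersion > 0,
    length(mean_log_expression_range) == 2,
    diff(mean_log_expression_range) > 0,
    length(library_size_range) == 2,
    diff(library_size_range) > 0, library_size_range[1] > 0,
    qpcr_samples_per_group >= 1, qpcr_noise_sd >= 0,
    is.numeric(rng_seed), length(rng_seed) == 1
  )
  if (n_de_mirnas > n_mirnas) {
    stop("invalid config: n_de_mirnas (", n_de_mirnas,
         ") exceeds n_mirnas (", n_mirnas, ")")
  }
  if (length(qpcr_effects) && is.null(names(qpcr_effects))) {
    stop("qpcr_effects must be a named numeric vector")
  }
  cfg <- structure(
    list(
      n_samples_per_group = as.integer(n_samples_per_group),
      n_mirnas = as.integer(n_mirnas),
      n_de_mirnas = as.integer(n_de_mirnas),
      de_log2fc_magnitude = de_log2fc_magnitude,
      dispersion = dispersion,
      mean_log_expression_range = mean_log_expression_range,
      library_size_range = library_size_range,
      n_genes = as.integer(n_genes),
      planted_hub_spec = planted_hub_spec,
      go_term_blocks = go_term_blocks,
      n_background_terms = as.integer(n_background_terms),
      qpcr_effects = qpcr_effects,
      qpcr_noise_sd = qpcr_noise_sd,
      qpcr_samples_per_group = as.integer(qpcr_samples_per_group),
      qpcr_reference = qpcr_reference,
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_config"
  )
  de_names <- names(planted_de(cfg))
  for (g in names(planted_hub_spec)) {
    regs <- planted_hub_spec[[g]]
    bad <- setdiff(normalize_mirna_name(regs), de_names)
    if (length(bad)) {
      stop("planted_hub_spec regulator(s) not among planted DE miRNAs: ",
           paste(bad, collapse = ", "))
    }
  }
  for (tm in names(go_term_blocks)) {
    extra <- setdiff(toupper(go_term_blocks[[tm]]),
                     c(gene_universe(cfg), toupper(names(planted_hub_spec))))
    if (length(extra)) {
      stop("go_term_blocks['", tm, "'] contains genes outside the universe: ",
           paste(extra, collapse = ", "))
    }
  }
  cfg
}

#' Simulated mature miRNA names
#'
#' Names follow the mature-arm convention (`rno-miR-<id>-3p/5p`) so that
#' name-normalization code paths are exercised downstream.
#'
#' @param config a `sim_config`.
#' @return character vector of length `config$n_mirnas`.
#' @export
mirna_names <- function(config) {
  i <- seq_len(config$n_mirnas)
  sprintf("rno-miR-%d-%s", 100L + i, ifelse(i %% 2 == 1, "3p", "5p"))
}

#' Simulated target-gene universe
#' @param config a `sim_config`.
#' @return character vector of gene symbols (upper case), including any
#'   planted hub genes.
#' @export
gene_universe <- function(config) {
  unique(c(sprintf("GENE%04d", seq_len(config$n_genes)),
           toupper(names(config$planted_hub_spec))))
}

#' Planted differentially expressed miRNAs
#'
#' Deterministic given the configuration: the first `n_de_mirnas` miRNAs
#' carry a log2 fold change of `+/- de_log2fc_magnitude` with alternating
#' signs (odd-indexed up, even-indexed down).
#'
#' @param config a `sim_config`.
#' @return named numeric vector of signed log2 fold changes (normalized
#'   miRNA names).
#' @export
planted_de <- function(config) {
  n <- config$n_de_mirnas
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  lfc <- config$de_log2fc_magnitude * rep_len(c(1, -1), n)
  stats::setNames(lfc, normalize_mirna_name(mirna_names(config)[seq_len(n)]))
}

#' Full planted ground truth for a configuration
#'
#' @param config a `sim_config`.
#' @return list with `de_mirnas` (named signed log2FC), `hub_genes`
#'   (data.frame gene / degree / strength, where strength is the sum of the
#'   signs of the planted regulators), `enriched_terms`, and
#'   `qpcr_fold_changes`.
#' @export
ground_truth <- function(config) {
  de <- planted_de(config)
  spec <- config$planted_hub_spec
  hub_genes <- data.frame(
    gene = toupper(names(spec)),
    degree = vapply(spec, length, 1L),
    strength = vapply(spec, function(regs) {
      as.integer(sum(sign(de[normalize_mirna_name(regs)])))
    }, 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    de_mirnas = de,
    hub_genes = hub_genes,
    enriched_terms = names(config$go_term_blocks),
    qpcr_fold_changes = config$qpcr_effects
  )
}

#' Simulate a two-group miRNA count matrix
#'
#' Counts are negative binomial: each miRNA gets a baseline relative
#' abundance `2^u`, `u ~ U(mean_log_expression_range)`; the per-sample mean
#' is `library_size * relative abundance`, and planted DE miRNAs have their
#' treated-group mean multiplied by `2^(+/- de_log2fc_magnitude)`. Counts
#' are drawn with `Var = mu + phi * mu^2`.
#'
#' @param config a `sim_config`.
#' @return list with `counts` (a [count_matrix()]) and `truth`
#'   (see [ground_truth()]). Deterministic given `config$rng_seed`.
#' @export
#' @examples
#' sim <- simulate_counts(simulation_config(n_mirnas = 30, n_de_mirnas = 2,
#'                                          rng_seed = 3))
#' dim(sim$counts$counts)
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- ground_truth(config)
  n <- config$n_samples_per_group
  G <- config$n_mirnas
  counts <- withr::with_seed(config$rng_seed, {
    u <- stats::runif(G, config$mean_log_expression_range[1],
                      config$mean_log_expression_range[2])
    prop <- 2^u / sum(2^u)
    lib <- round(stats::runif(2L * n, config$library_size_range[1],
                              config$library_size_range[2]))
    mu <- outer(prop, lib)
    lfc <- numeric(G)
    if (config$n_de_mirnas > 0) {
      lfc[seq_len(config$n_de_mirnas)] <- unname(truth$de_mirnas)
    }
    treated <- c(rep(FALSE, n), rep(TRUE, n))
    mu[, treated] <- mu[, treated] * 2^lfc
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow = G)
  })
  rownames(counts) <- mirna_names(config)
  colnames(counts) <- c(sprintf("control_%d", seq_len(n)),
                        sprintf("treated_%d", seq_len(n)))
  group <- factor(rep(c("control", "treated"), each = n),
                  levels = c("control", "treated"))
  list(counts = count_matrix(counts, group), truth = truth)
}

.curated_evidence_types <- c("Luciferase reporter assay", "Western blot",
                             "qRT-PCR", "Microarray", "CLIP-Seq")

#' Simulate the three target-interaction tables
#'
#' Emulates the structure of the three integrated interaction sources: a
#' predicted-score table (0-100, higher = stronger prediction), a
#' regression-score table (mirSVR-style, more negative = stronger predicted
#' repression), and a curated-evidence table. Every planted hub edge is
#' emitted in exactly one of the three tables with a score that passes its
#' filter (score > 80, mirSVR < -1.2, or curated evidence), rotating over
#' the tables in edge order. Decoy edges carry failing scores (including a
#' few exactly at each cutoff, which the strict filters must reject);
#' curated decoys involve only non-DE miRNAs, so the significance
#' restriction removes them downstream.
#'
#' @param config a `sim_config` with `planted_hub_spec` defined.
#' @param n_decoys decoy rows per table.
#' @return list of three data.frames (`predicted_a`, `predicted_b`,
#'   `curated`) with columns `mirna`, `gene`, `score`/`evidence`, `source`.
#' @export
simulate_target_databases <- function(config, n_decoys = 200L) {
  stopifnot(inherits(config, "sim_config"))
  de_names <- names(planted_de(config))
  all_mirnas <- normalize_mirna_name(mirna_names(config))
  non_de <- setdiff(all_mirnas, de_names)
  genes <- gene_universe(config)

  withr::with_seed(config$rng_seed + 1L, {
    a <- b <- cc <- list()
    idx <- 0L
    for (g in names(config$planted_hub_spec)) {
      for (m in config$planted_hub_spec[[g]]) {
        idx <- idx + 1L
        row <- list(mirna = normalize_mirna_name(m), gene = toupper(g))
        switch((idx - 1L) %% 3L + 1L,
          a[[length(a) + 1L]] <- c(row, score = stats::runif(1, 80.5, 99.5)),
          b[[length(b) + 1L]] <- c(row, score = stats::runif(1, -4, -1.3)),
          cc[[length(cc) + 1L]] <- c(row, evidence =
            sample(.curated_evidence_types, 1L))
        )
      }
    }
    decoy_pairs <- function(pool, n) {
      data.frame(mirna = sample(pool, n, replace = TRUE),
                 gene = sample(genes, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    da <- decoy_pairs(all_mirnas, n_decoys)
    da$score <- stats::runif(n_decoys, 0, 79.9)
    da$score[seq_len(min(5L, n_decoys))] <- 80.0   # boundary decoys
    db <- decoy_pairs(all_mirnas, n_decoys)
    db$score <- stats::runif(n_decoys, -1.19, -0.01)
    db$score[seq_len(min(5L, n_decoys))] <- -1.2   # boundary decoys
    dc <- if (length(non_de)) {
      d <- decoy_pairs(non_de, n_decoys)
      d$evidence <- sample(.curated_evidence_types, n_decoys, replace = TRUE)
      d
    } else {
      data.frame(mirna = character(0), gene = character(0),
                 evidence = character(0), stringsAsFactors = FALSE)
    }
    bind_rows_ <- function(planted, decoys) {
      planted <- if (length(planted)) {
        do.call(rbind, lapply(planted, function(r) {
          as.data.frame(r, stringsAsFactors = FALSE)
        }))
      } else NULL
      out <- rbind(planted, decoys)
      rownames(out) <- NULL
      out
    }
    list(
      predicted_a = cbind(bind_rows_(a, da), source = "predicted_scoreA",
                          stringsAsFactors = FALSE),
      predicted_b = cbind(bind_rows_(b, db), source = "predicted_scoreB",
                          stringsAsFactors = FALSE),
      curated = cbind(bind_rows_(cc, dc), source = "curated",
                      stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a qPCR Cp table with planted fold changes
#'
#' Per well, `Cp = baseline(gene) + loading(sample) - log2(fold change) +
#' noise`, with the fold-change shift applied only to treated samples and
#' the reference gene fixed at fold change 1. Every reaction is emitted in
#' duplicate. The per-sample loading offset cancels exactly in the delta-Cp
#' normalization against the reference gene, which is what makes
#' reference-gene normalization meaningful on these data.
#'
#' @param config a `sim_config` with `qpcr_effects` defined.
#' @return data.frame with columns `sample`, `group`, `gene`, `replicate`,
#'   `cp`. Deterministic given `config$rng_seed`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  effects <- config$qpcr_effects
  if (config$qpcr_reference %in% names(effects) &&
      effects[[config$qpcr_reference]] != 1) {
    stop("the reference gene's fold change is fixed at 1")
  }
  effects[config$qpcr_reference] <- 1
  genes <- names(effects)
  n <- config$qpcr_samples_per_group
  samples <- c(sprintf("control_%d", seq_len(n)),
               sprintf("treated_%d", seq_len(n)))
  groups <- rep(c("control", "treated"), each = n)

  withr::with_seed(config$rng_seed + 2L, {
    baseline <- stats::setNames(stats::runif(length(genes), 20, 26), genes)
    loading <- stats::setNames(stats::rnorm(length(samples), 0, 0.3), samples)
    grid <- expand.grid(replicate = 1:2, gene = genes, sample = samples,
                        stringsAsFactors = FALSE)
    grid$group <- groups[match(grid$sample, samples)]
    shift <- ifelse(grid$group == "treated", -log2(effects[grid$gene]), 0)
    grid$cp <- baseline[grid$gene] + loading[grid$sample] + shift +
      stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd)
    out <- grid[, c("sample", "group", "gene", "replicate", "cp")]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a gene -> GO-term annotation
#'
#' The planted `go_term_blocks` are kept verbatim (these are the terms a
#' downstream over-representation analysis should flag when the target list
#' covers their genes); background terms draw random gene subsets from the
#' universe.
#'
#' @param config a `sim_config`.
#' @param term_size_range size range for background terms.
#' @return named list `term id -> character vector of genes`, suitable for
#'   [write_gmt()].
#' @export
simulate_go_annotation <- function(config, term_size_range = c(10L, 50L)) {
  stopifnot(inherits(config, "sim_config"))
  genes <- unique(c(gene_universe(config),
                    toupper(unlist(config$go_term_blocks, use.names = FALSE))))
  ann <- lapply(config$go_term_blocks, toupper)
  withr::with_seed(config$rng_seed + 3L, {
    for (i in seq_len(config$n_background_terms)) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      ann[[sprintf("GO:B%04d", i)]] <- sample(genes, min(size, length(genes)))
    }
  })
  ann
}
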