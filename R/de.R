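#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count libraries. The reference sample
#' is the one whose 75th count-proportion percentile is closest to the
#' mean; for every other sample, per-miRNA log2 ratios (M) and average log2
#' abundances (A) against the reference are computed on miRNAs observed in
#' both, the most extreme 30% of M values and 5% of A values are trimmed
#' (two-sided, by rank), and the factor is the precision-weighted mean of
#' the remaining M values (inverse asymptotic binomial variances as
#' weights). Factors are rescaled so their geometric mean is 1.
#'
#' @param cm a [count_matrix()] or a non-negative count matrix.
#' @param logratio_trim two-sided trim fraction on M values.
#' @param sum_trim two-sided trim fraction on A values.
#' @return named numeric vector of strictly positive per-sample factors
#'   with geometric mean 1.
#' @export
#' @examples
#' m <- matrix(rpois(40, 100), 10, 4,
#'             dimnames = list(paste0("mir", 1:10), paste0("s", 1:4)))
#' normalize_tmm(m)
normalize_tmm <- function(cm, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  f75 <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], logratio_trim, sum_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# One sample against the reference.
.tmm_pair <- function(obs, ref, logratio_trim, sum_trim) {
  n_o <- sum(obs)
  n_r <- sum(ref)
  m <- log2((obs / n_o) / (ref / n_r))
  a <- (log2(obs / n_o) + log2(ref / n_r)) / 2
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- 2^(sum(m[keep] / v[keep], na.rm = TRUE) /
            sum(1 / v[keep], na.rm = TRUE))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' returned in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group negative binomial differential expression test
#'
#' Per-miRNA negative binomial GLM with a treated/control factor and a log
#' offset equal to the log effective library size (library size times TMM
#' factor). A single common dispersion is estimated by maximizing the
#' Cox-Reid adjusted profile likelihood (see
#' [estimate_common_dispersion()]); each miRNA is then tested with a
#' likelihood ratio test of the group coefficient against chi-squared(1).
#' Reported log2 fold changes are computed from group-mean CPM with a
#' pseudo-count of 0.5 added to each group mean, so they are finite at zero
#' counts. P-values are Benjamini-Hochberg adjusted over all tested miRNAs
#' and directions are called at `fdr < alpha`.
#'
#' @param cm a [count_matrix()] with at least two samples per group.
#' @param alpha FDR threshold for the up/down call.
#' @param dispersion optional fixed common dispersion (skips estimation).
#' @return data.frame of class `de_result` with columns `mirna`, `logFC`,
#'   `p_value`, `fdr`, `direction` (`up`/`down`/`ns`) and `flagged`
#'   (non-finite fit, reported as `p = 1`, `logFC = 0`). Attributes:
#'   `dispersion`, `norm_factors`, `alpha`.
#' @export
#' @examples
#' sim <- simulate_counts(simulation_config(n_mirnas = 60, n_de_mirnas = 4,
#'                                          rng_seed = 2))
#' de <- test_de(sim$counts)
#' head(de[order(de$fdr), ])
test_de <- function(cm, alpha = 0.05, dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(table(cm$group) < 2)) stop("each group needs at least two samples")
  if (nrow(cm$counts) == 0) stop("empty count matrix")
  y <- cm$counts
  treated <- cm$group == "treated"
  nf <- normalize_tmm(cm)
  eff_lib <- colSums(y) * nf
  offset <- log(eff_lib)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(cm, offset = offset)
  }
  full <- .nb_fit_full(y, treated, offset, dispersion)
  null <- .nb_fit_null(y, offset, dispersion)
  lrt <- pmax(2 * (full$loglik - null$loglik), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  cpm <- sweep(y, 2, eff_lib, "/") * 1e6
  mean_c <- rowMeans(cpm[, !treated, drop = FALSE])
  mean_t <- rowMeans(cpm[, treated, drop = FALSE])
  logfc <- log2((mean_t + 0.5) / (mean_c + 0.5))

  flagged <- !is.finite(p) | !is.finite(logfc)
  p[flagged] <- 1
  logfc[flagged] <- 0
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < alpha & logfc > 0, "up",
                      ifelse(fdr < alpha & logfc < 0, "down", "ns"))
  out <- data.frame(mirna = rownames(y), logFC = logfc, p_value = p,
                    fdr = fdr, direction = direction, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- dispersion
  attr(out, "norm_factors") <- nf
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", "data.frame")
  out
}

#' Count up/down calls in a differential expression table
#'
#' @param de a data.frame with columns `logFC` and `fdr` (e.g. a
#'   [test_de()] result or [fixture_table1()]).
#' @param alpha FDR threshold.
#' @return named integer vector with elements `up`, `down`, `ns`.
#' @export
de_summary <- function(de, alpha = 0.05) {
  stopifnot(all(c("logFC", "fdr") %in% names(de)))
  sig <- de$fdr < alpha
  c(up = sum(sig & de$logFC > 0),
    down = sum(sig & de$logFC < 0),
    ns = sum(!sig | de$logFC == 0))
}

#' Significantly differentially expressed miRNAs with directions
#'
#' @param de a `de_result` (or any data.frame with `mirna`, `logFC`,
#'   `fdr`).
#' @param alpha FDR threshold.
#' @return named character vector `mirna -> "up"/"down"` (normalized
#'   miRNA names).
#' @export
de_directions <- function(de, alpha = 0.05) {
  sig <- de[de$fdr < alpha & de$logFC != 0, , drop = FALSE]
  stats::setNames(ifelse(sig$logFC > 0, "up", "down"),
                  normalize_mirna_name(sig$mirna))
}
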