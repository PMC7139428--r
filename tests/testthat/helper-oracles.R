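# Independent brute-force oracles and shared fixture builders.

# Step-up BH by its definition: for sorted p(1) <= ... <= p(m),
# adj(i) = min(1, min_{j >= i} m * p(j) / j), mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# n-subsets of an N-gene universe whose first K genes carry the term.
hyper_exhaustive <- function(k, K, N, n) {
  combs <- utils::combn(N, n)
  mean(apply(combs, 2, function(s) sum(s <= K) >= k))
}

# Random two-group count matrix (Poisson background, no structure).
random_count_matrix <- function(n_mirna = 20, n_per_group = 4,
                                lambda = 60) {
  m <- matrix(stats::rpois(n_mirna * 2 * n_per_group, lambda), n_mirna,
              dimnames = list(
                sprintf("rno-miR-%d-3p", 500 + seq_len(n_mirna)),
                c(sprintf("control_%d", seq_len(n_per_group)),
                  sprintf("treated_%d", seq_len(n_per_group)))))
  count_matrix(m, rep(c("control", "treated"), each = n_per_group))
}

# Random signed bipartite fixture: edge list + direction map.
random_bipartite <- function(n_mirna = 6, n_gene = 15, n_edge = 30) {
  mirnas <- sprintf("rno-mir-%d-5p", 300 + seq_len(n_mirna))
  dirs <- stats::setNames(sample(c("up", "down"), n_mirna, replace = TRUE),
                          mirnas)
  edges <- unique(data.frame(
    mirna = sample(mirnas, n_edge, replace = TRUE),
    gene = sample(sprintf("G%03d", seq_len(n_gene)), n_edge,
                  replace = TRUE),
    stringsAsFactors = FALSE))
  list(interactions = edges, dirs = dirs)
}

# Per-gene degree/strength by naive summation over the edge list.
strength_brute <- function(interactions, dirs) {
  w <- ifelse(dirs[interactions$mirna] == "up", 1L, -1L)
  genes <- sort(unique(interactions$gene))
  data.frame(
    gene = genes,
    degree = vapply(genes, function(g) sum(interactions$gene == g), 1L),
    strength = vapply(genes, function(g)
      as.integer(sum(w[interactions$gene == g])), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Eleven-hub selection fixture: 2 hubs of strength -1, 9 of strength +1,
# each hub hit by 3 of 5 DE miRNAs; a high-fold significant term annotates
# exactly three positive hubs.
prioritization_fixture <- function() {
  dirs <- c("rno-mir-1-3p" = "up", "rno-mir-2-3p" = "up",
            "rno-mir-3-3p" = "down", "rno-mir-4-3p" = "down",
            "rno-mir-5-3p" = "down")
  ups <- names(dirs)[dirs == "up"]
  downs <- names(dirs)[dirs == "down"]
  genes <- sprintf("HUB%02d", 1:11)
  regs <- c(
    lapply(1:2, function(i) c(ups[1], downs[1:2])),          # +1 -1 -1 = -1
    lapply(3:11, function(i) c(ups[1:2], downs[1 + i %% 3])) # +1 +1 -1 = +1
  )
  interactions <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(mirna = regs[[i]], gene = genes[i],
               stringsAsFactors = FALSE)
  }))
  net <- build_network(interactions, dirs)
  annotation <- list(
    "GO:TOP" = c("HUB03", "HUB04", "HUB05", "GENE001", "GENE002"),
    "GO:MID" = c("HUB06", "HUB07", "HUB08", "GENE003", "GENE004",
                 "GENE005", "GENE006"),
    "GO:NS" = c("HUB09", "HUB10", "HUB11", sprintf("GENE%03d", 7:40))
  )
  enrichment <- data.frame(
    term = c("GO:TOP", "GO:MID", "GO:NS"),
    name = c("GO:TOP", "GO:MID", "GO:NS"),
    k = c(3L, 3L, 3L), n = 11L, K = c(5L, 7L, 37L), N = 500L,
    fold_enrichment = c(27.3, 19.5, 3.7),
    p_value = c(1e-6, 1e-4, 0.2),
    p_adjusted = c(3e-6, 1.5e-4, 0.2),
    method = "BH", stringsAsFactors = FALSE)
  class(enrichment) <- c("enrichment_result", "data.frame")
  list(net = net, hubs = find_hubs(net), enrichment = enrichment,
       annotation = annotation, dirs = dirs)
}
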