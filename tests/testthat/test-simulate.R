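test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_mirnas = 40, n_de_mirnas = 4, n_genes = 50,
                           planted_hub_spec = list(
                             G1 = c("rno-miR-101-3p", "rno-miR-102-5p")),
                           qpcr_effects = c(G1 = 0.5), rng_seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(simulate_target_databases(cfg),
                   simulate_target_databases(cfg))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  expect_identical(simulate_go_annotation(cfg),
                   simulate_go_annotation(cfg))
})

test_that("zero effect magnitude plants a pure null", {
  cfg <- simulation_config(n_mirnas = 30, n_de_mirnas = 5,
                           de_log2fc_magnitude = 0, rng_seed = 3)
  expect_true(all(ground_truth(cfg)$de_mirnas == 0))
  expect_true(all(simulate_counts(cfg)$truth$de_mirnas == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_mirnas = 5, n_de_mirnas = 6),
               "n_de_mirnas")
  expect_error(simulation_config(
    n_mirnas = 10, n_de_mirnas = 2,
    planted_hub_spec = list(G1 = "rno-miR-199-3p")),
    "not among planted DE")
  expect_error(simulation_config(dispersion = 0))
})

test_that("counts follow negative binomial moments", {
  # Poisson limit: tiny dispersion, variance/mean ratio near 1
  cfg <- simulation_config(n_samples_per_group = 500, n_mirnas = 10,
                           n_de_mirnas = 0, dispersion = 1e-6,
                           mean_log_expression_range = c(4, 6),
                           library_size_range = c(1e6, 1e6 + 1),
                           rng_seed = 21)
  y <- simulate_counts(cfg)$counts$counts
  ratio <- apply(y, 1, stats::var) / rowMeans(y)
  expect_true(all(abs(ratio - 1) < 0.25))

  # moderate dispersion: Var close to mu + phi * mu^2 at 1e4 draws
  phi <- 0.4
  cfg2 <- simulation_config(n_samples_per_group = 5000, n_mirnas = 8,
                            n_de_mirnas = 0, dispersion = phi,
                            mean_log_expression_range = c(3, 7),
                            library_size_range = c(1e6, 1e6 + 1),
                            rng_seed = 22)
  y2 <- simulate_counts(cfg2)$counts$counts
  mu <- rowMeans(y2)
  v_expect <- mu + phi * mu^2
  expect_true(all(abs(apply(y2, 1, stats::var) / v_expect - 1) < 0.15))
})

test_that("planted hub edges pass their filters and decoys do not", {
  hub_spec <- list(
    HUBA = c("rno-miR-101-3p", "rno-miR-102-5p", "rno-miR-103-3p"),
    HUBB = c("rno-miR-101-3p", "rno-miR-104-5p"))
  cfg <- simulation_config(n_mirnas = 60, n_de_mirnas = 6, n_genes = 80,
                           planted_hub_spec = hub_spec, rng_seed = 9)
  dbs <- simulate_target_databases(cfg)
  dirs <- stats::setNames(
    ifelse(planted_de(cfg) > 0, "up", "down"), names(planted_de(cfg)))
  ints <- integrate_targets(dbs$predicted_a, dbs$predicted_b,
                            dbs$curated, dirs)
  # integration restricted to planted hubs reproduces the hub spec exactly
  for (g in names(hub_spec)) {
    got <- sort(ints$mirna[ints$gene == toupper(g)])
    expect_identical(got, sort(normalize_mirna_name(hub_spec[[g]])))
  }
  # after integration, the planted hub degree is exact
  net <- build_network(ints, dirs)
  expect_identical(net$genes$degree[net$genes$gene == "HUBA"], 3L)

  # empty hub spec: nothing passes once restricted to DE miRNAs, because
  # decoy scores fail and curated decoys involve non-DE miRNAs only
  cfg0 <- simulation_config(n_mirnas = 60, n_de_mirnas = 6, n_genes = 80,
                            rng_seed = 9)
  dbs0 <- simulate_target_databases(cfg0)
  expect_true(all(dbs0$predicted_a$score <= 80))
  expect_true(all(dbs0$predicted_b$score >= -1.2))
  expect_false(any(dbs0$curated$mirna %in% names(planted_de(cfg0))))
  ints0 <- integrate_targets(dbs0$predicted_a, dbs0$predicted_b,
                             dbs0$curated, dirs)
  expect_identical(nrow(ints0), 0L)
})

test_that("planted qPCR fold changes flow through the ddCp chain", {
  # noiseless: neutral gene gives exactly 1, halved gene exactly 0.5
  cfg <- simulation_config(qpcr_effects = c(GA = 1, GB = 0.5),
                           qpcr_noise_sd = 0, rng_seed = 13)
  cp <- simulate_qpcr(cfg)
  suppressWarnings({
    ra <- ddcp(cp, "HPRT", "GA")
    rb <- ddcp(cp, "HPRT", "GB")
  })
  expect_equal(ra$expression$expression, rep(1, 14), tolerance = 1e-12)
  expect_equal(rb$treated_mean, 0.5, tolerance = 1e-12)
  expect_equal(rb$control_mean, 1, tolerance = 1e-12)

  # noisy: mean of per-seed treated means recovers 0.5 within 3 SEM
  means <- vapply(1:100, function(s) {
    cfg_s <- simulation_config(qpcr_effects = c(GB = 0.5),
                               qpcr_noise_sd = 0.1, rng_seed = 1000 + s)
    ddcp(simulate_qpcr(cfg_s), "HPRT", "GB")$treated_mean
  }, 0)
  sem <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * sem)
})

test_that("ground truth strength equals the sum of regulator signs", {
  hub_spec <- list(GX = c("rno-miR-101-3p", "rno-miR-102-5p",
                          "rno-miR-103-3p"))
  cfg <- simulation_config(n_mirnas = 20, n_de_mirnas = 4,
                           planted_hub_spec = hub_spec, rng_seed = 2)
  gt <- ground_truth(cfg)
  # regulators 1 and 3 planted up, 2 planted down
  expect_identical(gt$hub_genes$strength, 1L)
  expect_identical(gt$hub_genes$degree, 3L)
  expect_true(all(abs(gt$hub_genes$strength) <= gt$hub_genes$degree))
})
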