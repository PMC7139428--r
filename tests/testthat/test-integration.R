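dirs5 <- c("rno-mir-1-3p" = "up", "rno-mir-2-3p" = "down")

tab <- function(source, ...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df$source <- source
  df
}

test_that("miRNA name normalization is case-folding and idempotent", {
  expect_identical(normalize_mirna_name("rno-miR-141-3p"),
                   normalize_mirna_name("RNO-MIR-141-3P"))
  once <- normalize_mirna_name("rno-miR-141-3p")
  expect_identical(normalize_mirna_name(once), once)
  # the mature arm is a distinct sequence and is never stripped
  expect_false(normalize_mirna_name("rno-miR-141-3p") ==
                 normalize_mirna_name("rno-miR-141-5p"))
  expect_error(normalize_mirna_name(""), "non-empty")
})

test_that("score cutoffs are strict on both predicted sources", {
  a <- tab("predicted_scoreA",
           list(mirna = "rno-miR-1-3p", gene = "g1", score = 80.0),
           list(mirna = "rno-miR-1-3p", gene = "g2", score = 80.01))
  b <- tab("predicted_scoreB",
           list(mirna = "rno-miR-2-3p", gene = "g3", score = -1.2),
           list(mirna = "rno-miR-2-3p", gene = "g4", score = -1.21))
  cc <- tab("curated",
            list(mirna = "rno-miR-2-3p", gene = "g5",
                 evidence = "Luciferase reporter assay"))
  ints <- integrate_targets(a, b, cc, dirs5)
  expect_setequal(ints$gene, c("G2", "G4", "G5"))
})

test_that("duplicate pairs collapse to one record with all sources", {
  a <- tab("predicted_scoreA",
           list(mirna = "rno-miR-1-3p", gene = "Tgt", score = 91))
  b <- tab("predicted_scoreB",
           list(mirna = "RNO-MIR-1-3P", gene = "tgt", score = -2.5))
  cc <- tab("curated",
            list(mirna = "rno-mir-1-3p", gene = "TGT",
                 evidence = "Western blot"))
  ints <- integrate_targets(a, b, cc, dirs5)
  expect_identical(nrow(ints), 1L)
  expect_identical(ints$n_sources, 3L)
  expect_identical(ints$sources,
                   "curated,predicted_scoreA,predicted_scoreB")
  expect_identical(ints$best_score, 91)
})

test_that("integration restricts to significant miRNAs and dedups", {
  cfg <- simulation_config(
    n_mirnas = 50, n_de_mirnas = 4, n_genes = 60,
    planted_hub_spec = list(
      H1 = c("rno-miR-101-3p", "rno-miR-102-5p", "rno-miR-103-3p")),
    rng_seed = 19)
  dbs <- simulate_target_databases(cfg)
  dirs <- stats::setNames(ifelse(planted_de(cfg) > 0, "up", "down"),
                          names(planted_de(cfg)))
  ints <- integrate_targets(dbs$predicted_a, dbs$predicted_b,
                            dbs$curated, dirs)
  expect_identical(anyDuplicated(paste(ints$mirna, ints$gene)), 0L)
  expect_true(all(ints$mirna %in% names(dirs)))
  # filter idempotence on the pair set: re-integrating the passing
  # records under the same cutoffs changes nothing
  a2 <- data.frame(mirna = ints$mirna, gene = ints$gene,
                   score = ifelse(grepl("scoreA", ints$sources),
                                  ints$best_score, NA),
                   stringsAsFactors = FALSE)
  a2 <- a2[!is.na(a2$score), ]
  b2 <- data.frame(mirna = ints$mirna, gene = ints$gene,
                   score = ifelse(ints$sources == "predicted_scoreB",
                                  ints$best_score, NA),
                   stringsAsFactors = FALSE)
  b2 <- b2[!is.na(b2$score), ]
  c2 <- data.frame(mirna = ints$mirna, gene = ints$gene,
                   evidence = ints$evidence, stringsAsFactors = FALSE)
  c2 <- c2[!is.na(c2$evidence), ]
  ints2 <- integrate_targets(a2, b2, c2, dirs)
  expect_identical(paste(ints2$mirna, ints2$gene),
                   paste(ints$mirna, ints$gene))
})

test_that("malformed rows are skipped with a warning", {
  a <- tab("predicted_scoreA",
           list(mirna = "rno-miR-1-3p", gene = "g1", score = 95),
           list(mirna = "rno-miR-1-3p", gene = "g2", score = "oops"))
  b <- tab("predicted_scoreB", list(mirna = "rno-miR-2-3p", gene = "g3",
                                    score = -2))
  cc <- tab("curated", list(mirna = "rno-miR-2-3p", gene = "",
                            evidence = "x"))
  expect_warning(
    expect_warning(ints <- integrate_targets(a, b, cc, dirs5),
                   "skipped 1 malformed"),
    "skipped 1 malformed")
  expect_setequal(ints$gene, c("G1", "G3"))
})

test_that("reading interaction tables round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  a <- tab("predicted_scoreA",
           list(mirna = "rno-miR-1-3p", gene = "G1", score = 95.5))
  write_interaction_table(a, path)
  back <- read_interaction_table(path, "predicted_scoreA")
  expect_identical(back$gene, "G1")
  expect_identical(back$score, 95.5)
  expect_identical(back$source, "predicted_scoreA")
})
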