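cp_row <- function(sample, group, gene, rep, cp) {
  data.frame(sample = sample, group = group, gene = gene,
             replicate = rep, cp = cp, stringsAsFactors = FALSE)
}

test_that("the ddCp chain reproduces hand-computed fold changes", {
  # target Cp 24 (treated) vs 25 (control), reference 20 everywhere:
  # dCp = 4 vs 5, ddCp(treated) = -1, expression = 2
  cp <- rbind(
    cp_row("c1", "control", "TGT", 1, 25),
    cp_row("c1", "control", "REF", 1, 20),
    cp_row("t1", "treated", "TGT", 1, 24),
    cp_row("t1", "treated", "REF", 1, 20))
  expect_warning(r <- ddcp(cp, "REF", "TGT"), "fewer than two")
  expect_equal(r$treated_mean, 2)
  expect_equal(r$control_mean, 1)
  expect_true(is.na(r$p_value))
})

test_that("identical Cp everywhere gives unit expression and p = 1", {
  cp <- do.call(rbind, lapply(c("c1", "c2", "t1", "t2"), function(s) {
    g <- if (grepl("^c", s)) "control" else "treated"
    rbind(cp_row(s, g, "TGT", 1:2, 22), cp_row(s, g, "REF", 1:2, 20))
  }))
  expect_warning(r <- ddcp(cp, "REF", "TGT"), "zero variance")
  expect_equal(r$expression$expression, rep(1, 4))
  expect_equal(r$p_value, 1)
})

test_that("duplicate wells are averaged on the Cp scale", {
  cp <- rbind(
    cp_row("c1", "control", "TGT", 1:2, c(24, 26)),  # mean Cp 25
    cp_row("c1", "control", "REF", 1:2, 20),
    cp_row("t1", "treated", "TGT", 1:2, c(23, 25)),  # mean Cp 24
    cp_row("t1", "treated", "REF", 1:2, 20))
  suppressWarnings(r <- ddcp(cp, "REF", "TGT"))
  expect_equal(r$treated_mean, 2)  # not mean(2^-ddcp of single wells)
})

test_that("adding a constant to every Cp cancels exactly", {
  cfg <- simulation_config(qpcr_effects = c(GB = 0.5),
                           qpcr_noise_sd = 0.2, rng_seed = 8)
  cp <- simulate_qpcr(cfg)
  r1 <- ddcp(cp, "HPRT", "GB")
  cp2 <- cp
  cp2$cp <- cp2$cp + 3.7
  r2 <- ddcp(cp2, "HPRT", "GB")
  expect_equal(r1$expression$expression, r2$expression$expression,
               tolerance = 1e-12)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("swapping group labels inverts the fold change", {
  cfg <- simulation_config(qpcr_effects = c(GB = 0.25),
                           qpcr_noise_sd = 0, rng_seed = 4)
  cp <- simulate_qpcr(cfg)
  suppressWarnings(r <- ddcp(cp, "HPRT", "GB"))
  swapped <- cp
  swapped$group <- ifelse(cp$group == "control", "treated", "control")
  suppressWarnings(r2 <- ddcp(swapped, "HPRT", "GB"))
  expect_equal(r$treated_mean, 0.25, tolerance = 1e-12)
  expect_equal(r2$treated_mean, 4, tolerance = 1e-12)
})

test_that("the t statistic matches its closed form", {
  cfg <- simulation_config(qpcr_effects = c(GB = 0.5),
                           qpcr_noise_sd = 0.15, rng_seed = 12)
  cp <- simulate_qpcr(cfg)
  r <- ddcp(cp, "HPRT", "GB")
  x <- r$expression$expression[r$expression$group == "treated"]
  y <- r$expression$expression[r$expression$group == "control"]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  t_ref <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  expect_equal(r$t, t_ref, tolerance = 1e-12)
  expect_equal(r$p_value,
               2 * stats::pt(-abs(t_ref), length(x) + length(y) - 2),
               tolerance = 1e-12)
  # SEM definition
  expect_equal(r$sem_treated, sd(x) / sqrt(length(x)), tolerance = 1e-12)
})

test_that("samples missing the reference gene are excluded with warning", {
  cp <- rbind(
    cp_row(c("c1", "c2", "c3"), "control", "TGT", 1, c(25, 25, 25)),
    cp_row(c("c1", "c2"), "control", "REF", 1, 20),
    cp_row(c("t1", "t2"), "treated", "TGT", 1, c(24, 24.2)),
    cp_row(c("t1", "t2"), "treated", "REF", 1, 20))
  expect_warning(r <- ddcp(cp, "REF", "TGT"), "without the reference")
  expect_identical(nrow(r$expression), 4L)
})

test_that("amplicon sizes come from exact primer placement", {
  fwd <- "ACGTACGTACGTACGTACGT"
  rev <- "TTGCAGGCATTGCAGGCATT"
  rc_rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  filler <- function(n) paste(rep("A", n), collapse = "")
  # forward at position 1, reverse-complement site ending at 144
  tpl <- paste0(fwd, filler(144 - 20 - 20), rc_rev, filler(356))
  expect_identical(verify_amplicon(list(forward = fwd, reverse = rev),
                                   tpl), 144L)
  # reverse-complemented template with swapped primers: same product
  tpl_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tpl)))
  expect_identical(verify_amplicon(list(forward = rev, reverse = fwd),
                                   tpl_rc), 144L)
  # missing reverse site and upstream reverse site are no-amplicon errors
  expect_error(verify_amplicon(list(forward = fwd, reverse = rev),
                               paste0(fwd, filler(100))), "no amplicon")
  expect_error(verify_amplicon(list(forward = fwd, reverse = rev),
                               paste0(rc_rev, filler(100), fwd)),
               "no amplicon")
  # multiple sites: smallest product, with a warning
  tpl_multi <- paste0(fwd, filler(60), rc_rev, filler(50), rc_rev)
  expect_warning(sz <- verify_amplicon(list(forward = fwd, reverse = rev),
                                       tpl_multi), "multiple")
  expect_identical(sz, 100L)
})

test_that("bundled primers amplify a synthetic transcript at Table size", {
  pr <- fixture_table3()
  expect_identical(nrow(pr), 6L)
  hprt <- pr[pr$gene == "HPRT", ]
  rc_rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(hprt$reverse)))
  inner <- hprt$product_size - nchar(hprt$forward) - nchar(rc_rev)
  synthetic <- paste0(paste(rep("G", 25), collapse = ""), hprt$forward,
                      paste(rep("C", inner), collapse = ""), rc_rev,
                      paste(rep("G", 30), collapse = ""))
  expect_identical(verify_amplicon(hprt, synthetic),
                   as.integer(hprt$product_size))
})

test_that("ddcp_all covers every non-reference gene", {
  cfg <- simulation_config(qpcr_effects = c(GA = 1, GB = 0.5, GC = 2),
                           qpcr_noise_sd = 0.1, rng_seed = 6)
  res <- ddcp_all(simulate_qpcr(cfg), "HPRT")
  expect_setequal(res$gene, c("GA", "GB", "GC"))
  expect_true(all(is.finite(res$p_value)))
})
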