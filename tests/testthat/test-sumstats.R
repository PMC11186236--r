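test_that("read/write round-trip preserves validated tables", {
  rec <- mk_records(c("rs1", "rs2", "rs3"), pos = c(100L, 200L, 300L),
                    beta = c(0.11, -0.052, 0.0031),
                    se = c(0.01, 0.02, 0.013))
  ss <- SumStats(rec, "prot_a")
  expect_equal(nrow(records(ss)), 3L)
  expect_equal(ss@metadata$n_dropped, 0)
  f <- tempfile(fileext = ".tsv")
  writeSumStats(ss, f)
  back <- readSumStats(f, traitId = "prot_a")
  expect_equal(records(back), records(ss), tolerance = 1e-9)
})

test_that("invalid rows are dropped and counted", {
  rec <- mk_records(paste0("rs", 1:5), pos = (1:5) * 100L,
                    beta = rep(0.1, 5), se = c(0.01, 0, 0.01, 0.01, 0.01))
  rec$pval <- c(0.5, 0.5, 1.5, 0.5, 0.5)
  rec$beta <- rec$se * 0.6        # keep supplied p consistent with beta/se
  rec$effect_allele[4] <- "AT"    # indel
  ss <- SumStats(rec, "x")
  expect_equal(nrow(records(ss)), 2L)
  expect_equal(ss@metadata$n_dropped, 3)
  expect_true("indel_or_multiallelic" %in% names(ss@metadata$drop_reasons))
})

test_that("missing p-values are filled from the normal tail of beta/se", {
  rec <- mk_records("rs1", pos = 100L, beta = 1.96, se = 1)
  ss <- SumStats(rec, "x")
  expect_equal(records(ss)$pval, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_equal(round(records(ss)$pval, 4), 0.05)
  # file without a pval column goes through the same fill
  f <- tempfile(fileext = ".tsv")
  write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(records(readSumStats(f, "x"))$pval, 2 * pnorm(-1.96),
               tolerance = 1e-9)
})

test_that("a discordant supplied p-value warns but is never dropped", {
  rec <- mk_records("rs1", pos = 100L, beta = 0.5, se = 0.01, pval = 0.5)
  expect_warning(ss <- SumStats(rec, "x"), "orders of magnitude")
  expect_equal(nrow(records(ss)), 1L)
})

test_that("missing mandatory columns are named in the error", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(variant_id = "rs1", beta = 0.1), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readSumStats(f, "x"), "se")
})

test_that("column maps adapt foreign headers", {
  rec <- mk_records("rs1", pos = 100L, beta = 0.1, se = 0.05)
  names(rec)[names(rec) == "beta"] <- "Effect"
  f <- tempfile(fileext = ".tsv")
  write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  mapf <- tempfile()
  writeLines("beta=Effect", mapf)
  ss <- readSumStats(f, "x", columnMap = mapf)
  expect_equal(records(ss)$beta, 0.1)
})

test_that("harmonize aligns swapped alleles with a sign flip", {
  exp <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "G",
                             eaf = 0.7, beta = 0.2, se = 0.02), "exp")
  out <- SumStats(mk_records("rs1", pos = 100L, ea = "G", oa = "A",
                             eaf = 0.30, beta = -0.10, se = 0.02), "out")
  h <- pairsTable(harmonize(exp, out))
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$beta_out, 0.10)
  expect_equal(h$eaf_out, 0.70)
})

test_that("ambiguous palindromic variants are dropped", {
  exp <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "T",
                             eaf = 0.50, beta = 0.2, se = 0.02), "exp")
  out <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "T",
                             eaf = 0.50, beta = 0.1, se = 0.02), "out")
  expect_warning(h <- harmonize(exp, out), "no variants")
  expect_equal(pairsTable(h)$action, "dropped_palindromic")
})

test_that("informative palindromic variants are aligned by frequency", {
  exp <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "T",
                             eaf = 0.2, beta = 0.2, se = 0.02), "exp")
  # other strand, frequency says the coding is flipped
  out <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "T",
                             eaf = 0.8, beta = 0.1, se = 0.02), "out")
  h <- pairsTable(harmonize(exp, out))
  expect_equal(h$action, "freq_inferred")
  expect_equal(h$beta_out, -0.1)
  expect_equal(h$eaf_out, 0.2)
})

test_that("irreconcilable allele sets are dropped as mismatch", {
  exp <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "G",
                             beta = 0.2, se = 0.02), "exp")
  out <- SumStats(mk_records("rs1", pos = 100L, ea = "A", oa = "C",
                             beta = 0.1, se = 0.02), "out")
  expect_warning(h <- harmonize(exp, out))
  expect_equal(pairsTable(h)$action, "dropped_mismatch")
})

test_that("harmonizing a table against itself keeps everything unchanged", {
  reg <- simulateRegion(simScenario("causal", m = 50L, seed = 41))
  tab <- reg$prot
  # keep palindromic frequencies informative so self-harmonization is exact
  rec <- records(tab)
  rec$eaf <- pmin(rec$eaf, 0.40)
  tab <- SumStats(rec, "self")
  h <- pairsTable(harmonize(tab, tab))
  expect_true(all(h$action == "kept"))
  expect_equal(h$beta_out, h$beta_exp)
})

test_that("harmonize is idempotent on its kept output", {
  reg <- simulateRegion(simScenario("causal", m = 60L, seed = 42))
  h1 <- keptPairs(harmonize(reg$prot, reg$outcome))
  exp2 <- omicsMR:::.pairs_to_sumstats(h1, "exp", "e", "quantitative")
  out2 <- omicsMR:::.pairs_to_sumstats(h1, "out", "o", "binary")
  h2 <- keptPairs(harmonize(exp2, out2))
  expect_equal(h2@pairs[, c("variant_id", "beta_exp", "beta_out")],
               h1@pairs[, c("variant_id", "beta_exp", "beta_out")])
})

test_that("allele-coding flips leave the harmonized effect product invariant", {
  reg <- simulateRegion(simScenario("causal", m = 40L, seed = 43))
  base <- keptPairs(harmonize(reg$prot, reg$outcome))@pairs
  flip_complement <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in c(3L, 17L, 29L)) {
    rec <- records(reg$prot)
    tmp <- rec$effect_allele[i]
    rec$effect_allele[i] <- rec$other_allele[i]
    rec$other_allele[i] <- tmp
    rec$beta[i] <- -rec$beta[i]
    rec$eaf[i] <- 1 - rec$eaf[i]
    flipped <- SumStats(rec, "flipped")
    h <- keptPairs(harmonize(flipped, reg$outcome))@pairs
    v <- rec$variant_id[i]
    if (v %in% h$variant_id && v %in% base$variant_id) {
      expect_equal(h$beta_exp[h$variant_id == v] * h$beta_out[h$variant_id == v],
                   base$beta_exp[base$variant_id == v] *
                     base$beta_out[base$variant_id == v],
                   tolerance = 1e-12)
    }
  }
})

test_that("cis windows are inclusive at both flank boundaries", {
  gene <- list(gene_id = "g", chrom = "2", start = 2e6, end = 2.01e6)
  tab <- SumStats(mk_records(paste0("rs", 1:4), chrom = "2",
                             pos = c(1500000L, 1000000L, 3010000L, 3010001L),
                             beta = rep(0.1, 4), se = rep(0.01, 4)), "x")
  sub <- cisWindow(gene, tab)
  expect_setequal(records(sub)$variant_id, c("rs1", "rs2", "rs3"))
  far <- SumStats(mk_records("rs9", chrom = "2", pos = 3600000L,
                             beta = 0.1, se = 0.01), "x")
  expect_equal(nrow(records(cisWindow(gene, far))), 0L)
  off <- SumStats(mk_records("rs9", chrom = "7", pos = 2e6L,
                             beta = 0.1, se = 0.01), "x")
  expect_warning(empty <- cisWindow(gene, off), "not present")
  expect_equal(nrow(records(empty)), 0L)
})

test_that("gene annotations convert BED coordinates when declared", {
  f <- tempfile()
  write.table(data.frame("1", 999L, 2000L, "g1"), f, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  g0 <- readGeneAnnotations(f)
  g1 <- readGeneAnnotations(f, zeroBasedHalfOpen = TRUE)
  expect_equal(g0$start, 999L)
  expect_equal(g1$start, 1000L)
  expect_equal(g1$end, 2000L)
})
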