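test_that("BH q-values match hand arithmetic and enforce monotonicity", {
  expect_equal(bhFDR(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bhFDR(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bhFDR(numeric(0)), numeric(0))
  # permutation invariance up to matching
  set.seed(12)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhFDR(p)[perm], bhFDR(p[perm]))
})

test_that("BH keeps the false-discovery proportion controlled under the null", {
  fdp <- vapply(1:200, function(i) {
    set.seed(i)
    q <- bhFDR(runif(10000))
    d <- sum(q < 0.05)
    if (d == 0) 0 else 1   # all hypotheses are null
  }, 0)
  # under the global null mean FDP equals the nominal level; allow the
  # exact Monte-Carlo error of 200 Bernoulli(0.05) replicates (99% bound)
  expect_lte(mean(fdp), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("fixed-effect meta matches the closed-form oracle", {
  m <- fixedEffectMeta(c(0.2, 0.4), c(0.1, 0.1))
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, sqrt(1 / 200), tolerance = 1e-12)
  single <- fixedEffectMeta(0.2, 0.1)
  expect_equal(single$beta, 0.2)
  expect_equal(single$se, 0.1)
  for (i in 1:10) {
    set.seed(400 + i)
    b <- rnorm(5); s <- runif(5, 0.05, 0.3)
    got <- fixedEffectMeta(b, s)
    expect_equal(got$beta, sum(b / s^2) / sum(1 / s^2), tolerance = 1e-12)
    expect_equal(got$se, sqrt(1 / sum(1 / s^2)), tolerance = 1e-12)
    expect_lte(got$se, min(s))
  }
})

test_that("replication counting applies polarity and significance jointly", {
  panel <- data.frame(outcome_id = c("egfr", "egfr2", "ckd2"),
                      polarity = c(-1, -1, 1),
                      beta = c(-0.2, -0.2, 0.1),
                      pval = c(0.001, 0.2, 0.01))
  # harmful protein: negative filtration-rate effect counts when significant
  expect_equal(countReplications(0.3, panel), 2L)
  # protective protein: none of these are concordant
  expect_equal(countReplications(-0.3, panel), 0L)
  # missing results are skipped
  panel$beta[3] <- NA
  expect_equal(countReplications(0.3, panel), 1L)
  # nothing significant, nothing counted
  panel$pval <- 0.5
  expect_equal(countReplications(0.3, panel), 0L)
})

test_that("a protein with 3 + 8 concordant significant outcomes counts 11", {
  panel <- data.frame(outcome_id = paste0("o", 1:17),
                      polarity = c(rep(1, 3), rep(-1, 8), rep(1, 6)),
                      beta = c(rep(-0.2, 3), rep(0.2, 8), rep(0.2, 6)),
                      pval = c(rep(0.001, 11), rep(0.5, 6)))
  expect_equal(countReplications(-0.3, panel), 11L)
})

test_that("tier assignment is exhaustively correct over all flag combinations", {
  grid <- expand.grid(mr = c(TRUE, FALSE), smr = c(TRUE, FALSE),
                      coloc = c(TRUE, FALSE))
  want <- with(grid, ifelse(!mr, "none",
                            ifelse(smr & coloc, "1",
                                   ifelse(smr | coloc, "2", "3"))))
  got <- mapply(assignTier, grid$mr, grid$smr, grid$coloc)
  expect_equal(unname(got), want)
})

test_that("direction consistency distinguishes consistent, opposite and mixed", {
  expect_equal(directionConsistency(-0.2, c(blood = -0.1))$summary,
               "consistent")
  expect_equal(directionConsistency(-0.2, c(blood = 0.1, kidney = 0.2))$summary,
               "opposite")
  expect_equal(directionConsistency(-0.2, c(blood = -0.1, kidney = 0.2))$summary,
               "mixed")
  expect_true(is.na(directionConsistency(-0.2, c(blood = NA))$summary))
})

test_that("evidence-table assembly orders by tier and round-trips as TSV", {
  mrs <- list(
    s1 = data.frame(protein_id = c("p1", "p2", "p3"), q = c(0.01, 0.2, 0.03)),
    s2 = data.frame(protein_id = c("p1", "p2", "p3"), q = c(0.5, 0.01, 0.6)))
  combined <- data.frame(protein_id = c("p1", "p2", "p3"),
                         beta = c(0.2, -0.1, 0.05), se = c(0.02, 0.02, 0.02),
                         pval = c(1e-8, 1e-4, 0.01),
                         or = exp(c(0.2, -0.1, 0.05)), or_low = 1,
                         or_high = 1.5, n_sources_used = 2L)
  smr <- data.frame(protein_id = c("p1", "p2", "p3"),
                    p_smr = c(0.001, 0.5, 0.2), heidi_p = c(0.5, 0.5, 0.5),
                    passed_smr = c(TRUE, FALSE, FALSE))
  coloc <- data.frame(protein_id = c("p1", "p2", "p3"),
                      pph4 = c(0.95, 0.7, 0.1),
                      call = c("colocalized", "moderate", "none"),
                      passed_coloc = c(TRUE, TRUE, FALSE))
  repl <- data.frame(protein_id = c("p1", "p2", "p3"),
                     replication_count = c(11L, 3L, 0L))
  dir <- data.frame(protein_id = c("p1", "p2", "p3"),
                    direction_consistent = c("consistent", "mixed", NA))
  ev <- buildEvidenceTable(mrs, combined, smr, coloc, repl, dir)
  expect_equal(ev$protein_id, c("p1", "p2", "p3"))
  expect_equal(ev$tier, c("1", "2", "3"))
  expect_equal(ev$replication_count, c(11L, 3L, 0L))
  f <- tempfile(fileext = ".tsv")
  writeEvidenceTable(ev, f)
  back <- readEvidenceTable(f)
  f2 <- tempfile(fileext = ".tsv")
  writeEvidenceTable(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # empty input, empty table
  expect_equal(nrow(buildEvidenceTable(list(),
                                       data.frame(protein_id = character(0)),
                                       smr[0, ], coloc[0, ], repl[0, ],
                                       dir[0, ])), 0L)
  # key collision is a hard error
  expect_error(buildEvidenceTable(mrs, rbind(combined, combined[1, ]),
                                  smr, coloc, repl, dir), "duplicate")
})
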