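test_that("top-eQTL selection honours the 5e-8 threshold and tie rules", {
  tab <- SumStats(mk_records(paste0("rs", 1:3), pos = (1:3) * 1000L,
                             beta = c(0.5, 0.2, 0.1),
                             se = c(0.05, 0.05, 0.05)), "eqtl")
  top <- topEqtl(tab)
  expect_equal(top$variant_id, "rs1")
  weak <- SumStats(mk_records("rs1", pos = 100L, beta = 0.1, se = 0.02,
                              pval = 1e-7), "eqtl")
  expect_null(topEqtl(weak))
  expect_null(topEqtl(selectInstruments(weak, 1e-30)))
})

test_that("SMR statistic, p-value and SE follow the two-z composition", {
  s <- smrTest(0.5, 0.05, 0.05, 0.01)
  expect_equal(s$bSmr, 0.1)
  expect_equal(s$tSmr, 100 * 25 / 125)
  expect_equal(s$pSmr, pchisq(20, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(s$pSmr, 7.744216e-06, tolerance = 1e-6)
  expect_equal(s$seSmr, 0.1 / sqrt(20), tolerance = 1e-12)
  # null outcome: everything collapses to zero / one
  s0 <- smrTest(0.5, 0.05, 0, 0.01)
  expect_equal(s0$bSmr, 0)
  expect_equal(s0$tSmr, 0)
  expect_equal(s0$pSmr, 1)
  expect_error(smrTest(0, 0.05, 0.1, 0.01), "zero")
})

test_that("T_smr is bounded by both single z-statistics and reaches the limit", {
  set.seed(4)
  for (i in 1:50) {
    b1 <- rnorm(1); b2 <- rnorm(1)
    s1 <- runif(1, 0.01, 0.2); s2 <- runif(1, 0.01, 0.2)
    if (b1 == 0) next
    t <- smrTest(b1, s1, b2, s2)$tSmr
    expect_lte(t, min((b1 / s1)^2, (b2 / s2)^2) + 1e-12)
  }
  # z_zx -> infinity: T tends to the outcome chi-square
  t_lim <- smrTest(1, 1e-9, 0.05, 0.01)
  expect_equal(t_lim$tSmr, 25, tolerance = 1e-6)
  expect_equal(t_lim$pSmr, pchisq(25, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("SMR effect is invariant to joint allele flips", {
  a <- smrTest(0.5, 0.05, 0.05, 0.01)
  b <- smrTest(-0.5, 0.05, -0.05, 0.01)
  expect_equal(a$bSmr, b$bSmr)
  expect_equal(a$pSmr, b$pSmr)
})

test_that("HEIDI reports insufficient SNPs when only the top passes filters", {
  reg <- simulateRegion(simScenario("causal", m = 20L, rho = 0, seed = 8))
  h <- harmonize(reg$eqtl, reg$outcome)
  kp <- pairsTable(keptPairs(h))
  top <- kp$variant_id[which.min(kp$p_exp)]
  # rho = 0: no SNP clears the r2 >= 0.05 bound against the top
  res <- heidiTest(h, top, reg$ld)
  expect_equal(res$status, "heidi_insufficient_snps")
  expect_true(is.na(res$heidiP))
})

test_that("the HEIDI tail agrees with an independent inversion oracle", {
  worst <- 0
  for (i in 1:100) {
    set.seed(6000 + i)
    q <- sample(3:10, 1)
    A <- matrix(rnorm(q * q), q)
    C <- cov2cor(crossprod(A) + diag(q) * 0.3)
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    Q <- sum(rnorm(q)^2) * runif(1, 0.5, 2)
    p_pkg <- omicsMR:::.imhof_p(Q, lam)
    p_orc <- wchisq_tail_oracle(Q, lam)
    worst <- max(worst, abs(p_pkg - p_orc))
  }
  expect_lt(worst, 0.005)
  # spot-check the oracle itself against brute-force Monte Carlo
  lam <- c(1.743, 0.9, 0.358)
  expect_equal(wchisq_tail_oracle(3.549, lam),
               wchisq_tail_mc(3.549, lam), tolerance = 0.005)
})

test_that("HEIDI keeps shared-causal loci and flags linkage loci", {
  # shared causal variant: HEIDI should rarely reject at 0.01
  p_shared <- vapply(1:150, function(i) {
    reg <- simulateRegion(simScenario("causal", seed = 7000 + i))
    h <- harmonize(reg$eqtl, reg$outcome)
    kp <- pairsTable(keptPairs(h))
    top <- kp$variant_id[which.min(kp$p_exp)]
    heidiTest(h, top, reg$ld)$heidiP
  }, 0)
  shared_rej <- mean(p_shared < 0.01, na.rm = TRUE)
  expect_lt(shared_rej, 0.05)
  # linkage (distinct causal variants, r2 ~ 0.5): rejection well above null
  p_link <- vapply(1:150, function(i) {
    scn <- simScenario("linkage", c = 0.3, seed = 7500 + i)
    reg <- simulateRegion(scn)
    h <- harmonize(reg$eqtl, reg$outcome)
    kp <- pairsTable(keptPairs(h))
    top <- kp$variant_id[which.min(kp$p_exp)]
    heidiTest(h, top, reg$ld)$heidiP
  }, 0)
  link_rej <- mean(p_link < 0.01, na.rm = TRUE)
  expect_gt(link_rej, shared_rej + 0.1)
})

test_that("runGeneSMR composes statuses and the linkage call", {
  reg <- simulateRegion(simScenario("mediated", seed = 13))
  sr <- runGeneSMR(reg$gene, reg$eqtl, reg$outcome, reg$ld)
  expect_equal(sr@status, "ok")
  expect_lt(sr@pSmr, 0.05)
  expect_gte(sr@heidiNSnps, 3L)
  # no eQTL signal anywhere: no_top_eqtl
  null_eqtl <- simulateRegion(simScenario("reverse", seed = 14))$eqtl
  sr2 <- runGeneSMR(reg$gene, null_eqtl, reg$outcome, reg$ld)
  expect_equal(sr2@status, "no_top_eqtl")
})

test_that("mediated loci pass SMR with high power at realistic sizes", {
  pass <- vapply(1:60, function(i) {
    reg <- simulateRegion(simScenario("mediated", seed = 8000 + i))
    sr <- runGeneSMR(reg$gene, reg$eqtl, reg$outcome, reg$ld)
    sr@status == "ok" && sr@pSmr < 0.05
  }, NA)
  expect_gt(mean(pass), 0.8)
})
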