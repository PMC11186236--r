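test_that("Wald ratio arithmetic and the delta-method SE", {
  r <- waldRatio(0.5, 0.05, 0.1, 0.02)
  expect_equal(r@beta, 0.2)
  expect_equal(r@se, 0.04)
  expect_equal(r@pval, 2 * pnorm(-5))
  expect_true(r@orLow <= r@orPoint && r@orPoint <= r@orHigh)
  # betaExp = 1 reduces to the outcome association
  r1 <- waldRatio(1, 0.05, 0.1, 0.02)
  expect_equal(r1@beta, 0.1)
  expect_equal(r1@se, 0.02)
  expect_error(waldRatio(0, 0.05, 0.1, 0.02), "zero")
})

test_that("second-order delta SE tracks the Monte-Carlo ratio SD", {
  # at denominator CV 10% the truncated third-order terms contribute ~2%,
  # so the delta SE is expected to sit just under the empirical SD
  r2 <- waldRatio(0.5, 0.05, 0.1, 0.02, secondOrder = TRUE)
  set.seed(99)
  n <- 1e6
  ratio <- rnorm(n, 0.1, 0.02) / rnorm(n, 0.5, 0.05)
  expect_lt(abs(r2@se - sd(ratio)) / sd(ratio), 0.025)
  # at a smaller denominator CV the agreement tightens well below 2%
  r3 <- waldRatio(0.5, 0.01, 0.1, 0.02, secondOrder = TRUE)
  set.seed(100)
  ratio3 <- rnorm(n, 0.1, 0.02) / rnorm(n, 0.5, 0.01)
  expect_lt(abs(r3@se - sd(ratio3)) / sd(ratio3), 0.01)
})

test_that("IVW arithmetic: symmetric two-instrument case and Q", {
  p <- mk_pairs(bx = c(1, 1), sx = c(0.05, 0.05), by = c(0.2, 0.4),
                sy = c(0.1, 0.1))
  r <- mrIVW(p)
  expect_equal(r@beta, 0.3)
  expect_equal(r@se, 1 / sqrt(200), tolerance = 1e-12)
  expect_equal(r@qStat, 2)
  expect_equal(r@qDf, 1L)
  expect_equal(r@qPval, pchisq(2, 1, lower.tail = FALSE))
})

test_that("single-instrument IVW reduces to the Wald ratio", {
  p <- mk_pairs(bx = 0.5, sx = 0.05, by = 0.1, sy = 0.02)
  r <- mrIVW(p)
  expect_equal(r@method, "wald")
  expect_equal(r@beta, 0.2)
  expect_equal(r@se, 0.04)
})

test_that("IVW equals the origin-constrained WLS oracle on random sets", {
  for (i in 1:20) {
    set.seed(2000 + i)
    k <- 5L
    bx <- rnorm(k, 0.3, 0.1); sx <- runif(k, 0.01, 0.05)
    by <- rnorm(k, 0.06, 0.05); sy <- runif(k, 0.01, 0.05)
    r <- mrIVW(mk_pairs(bx, sx, by, sy))
    o <- wls_oracle(bx, by, 1 / sy^2, intercept = FALSE)
    expect_equal(unname(r@beta), unname(o$coef), tolerance = 1e-10)
    expect_equal(unname(r@se), unname(o$se / o$sigma), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relation with zero residual", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.1 + 0.5 * bx
  r <- mrEgger(mk_pairs(bx, rep(0.01, 4), by, rep(0.02, 4)))
  expect_equal(r@eggerIntercept, 0.1, tolerance = 1e-10)
  expect_equal(r@beta, 0.5, tolerance = 1e-10)
  expect_lt(r@pval, 1e-12)
})

test_that("Egger needs at least three instruments", {
  r <- mrEgger(mk_pairs(c(0.1, 0.2), c(0.01, 0.01), c(0.1, 0.2),
                        c(0.02, 0.02)))
  expect_equal(r@status, "not_computable")
})

test_that("Egger matches the generic weighted-regression oracle", {
  for (i in 1:20) {
    set.seed(3000 + i)
    k <- 6L
    bx <- abs(rnorm(k, 0.3, 0.1)); sx <- runif(k, 0.01, 0.05)
    by <- 0.02 + 0.2 * bx + rnorm(k, 0, 0.03); sy <- runif(k, 0.01, 0.05)
    r <- mrEgger(mk_pairs(bx, sx, by, sy))
    o <- wls_oracle(bx, by, 1 / sy^2)
    expect_equal(unname(r@eggerIntercept), unname(o$coef[1]), tolerance = 1e-10)
    expect_equal(unname(r@beta), unname(o$coef[2]), tolerance = 1e-10)
    expect_equal(unname(r@se), unname(o$se[2]), tolerance = 1e-10)
    expect_equal(unname(r@eggerInterceptP), unname(o$p[1]), tolerance = 1e-10)
    expect_equal(unname(r@pval), unname(o$p[2]), tolerance = 1e-10)
  }
})

test_that("IVW and Egger are invariant to joint allele-coding flips", {
  set.seed(77)
  k <- 8L
  bx <- rnorm(k, 0.3, 0.1); sx <- runif(k, 0.01, 0.05)
  by <- rnorm(k, 0.06, 0.05); sy <- runif(k, 0.01, 0.05)
  flip <- sample(c(-1, 1), k, replace = TRUE)
  a <- mrIVW(mk_pairs(bx, sx, by, sy))
  b <- mrIVW(mk_pairs(flip * bx, sx, flip * by, sy))
  expect_equal(a@beta, b@beta, tolerance = 1e-12)
  expect_equal(a@se, b@se, tolerance = 1e-12)
  ae <- mrEgger(mk_pairs(bx, sx, by, sy))
  be <- mrEgger(mk_pairs(flip * bx, sx, flip * by, sy))
  expect_equal(ae@beta, be@beta, tolerance = 1e-12)
  expect_equal(ae@eggerIntercept, be@eggerIntercept, tolerance = 1e-12)
})

test_that("Q is zero when all per-instrument ratios agree", {
  bx <- c(0.2, 0.4, 0.6)
  r <- mrIVW(mk_pairs(bx, rep(0.01, 3), 0.3 * bx, rep(0.02, 3)))
  expect_equal(r@qStat, 0, tolerance = 1e-20)
})

test_that("runProteinMR dispatches by instrument count", {
  reg <- simulateRegion(simScenario("causal", m = 40L, seed = 11))
  h <- keptPairs(harmonize(reg$prot, reg$outcome))
  one <- new("HarmonizedPairs", pairs = h@pairs[1, , drop = FALSE],
             metadata = list())
  b1 <- runProteinMR(InstrumentSet("p", one, reg$ld, "s"))
  expect_equal(b1$primary@method, "wald")
  expect_null(b1$egger)
  four <- new("HarmonizedPairs", pairs = h@pairs[1:4, , drop = FALSE],
              metadata = list())
  b4 <- runProteinMR(InstrumentSet("p", four, reg$ld, "s"))
  expect_equal(b4$primary@method, "ivw")
  expect_s4_class(b4$egger, "MRResult")
  empty <- new("HarmonizedPairs", pairs = h@pairs[0, , drop = FALSE],
               metadata = list())
  b0 <- runProteinMR(InstrumentSet("p", empty, NULL, "s"))
  expect_equal(b0$status, "no_instruments")
})

test_that("IVW recovers the causal effect from independent-instrument loci", {
  est <- vapply(1:100, function(i) {
    scn <- simScenario("causal", m = 5L, rho = 0, aIdx = 1:5,
                       nCase = 50000, nCtrl = 50000, seed = 5000 + i)
    reg <- simulateRegion(scn)
    mrIVW(keptPairs(harmonize(reg$prot, reg$outcome)))@beta
  }, 0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), 3 * mc_se)
})
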