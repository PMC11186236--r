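# Independent oracles and small fixture builders used across the suite.

# weighted least squares through lm(); returns coefficients, classical SEs
# and the residual scale so both fixed-weight (sigma = 1) and estimated-
# variance conventions can be checked against.
wls_oracle <- function(x, y, w, intercept = TRUE) {
  fit <- if (intercept) stats::lm(y ~ x, weights = w)
  else stats::lm(y ~ 0 + x, weights = w)
  s <- summary(fit)
  co <- s$coefficients
  list(coef = co[, "Estimate"], se = co[, "Std. Error"], sigma = s$sigma,
       p = co[, "Pr(>|t|)"])
}

# plain-loop greedy clumping, written independently of the package code
greedy_clump_oracle <- function(pval, chrom, pos, r2, r2max, window_bp) {
  n <- length(pval)
  remaining <- seq_len(n)
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(pval[remaining], chrom[remaining], pos[remaining])]
    idx <- o[1]
    kept <- c(kept, idx)
    remaining <- setdiff(remaining, idx)
    drop <- remaining[chrom[remaining] == chrom[idx] &
                        abs(pos[remaining] - pos[idx]) <= window_bp &
                        r2[remaining, idx] > r2max]
    remaining <- setdiff(remaining, drop)
  }
  sort(kept)
}

# Upper tail of sum(lam_i * chisq_1) by hand-coded composite-Simpson
# characteristic-function inversion (independent of stats::integrate):
# u mapped to (0, 1) via u = t/(1-t).
wchisq_tail_oracle <- function(q, lam, n_panels = 40000L) {
  t <- seq(1e-9, 1 - 1e-7, length.out = 2L * n_panels + 1L)
  u <- t / (1 - t)
  jac <- 1 / (1 - t)^2
  theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * q * u
  lrho <- 0.25 * colSums(log1p(outer(lam^2, u^2)))
  f <- sin(theta) / (u * exp(lrho)) * jac
  h <- t[2] - t[1]
  wts <- rep(c(4, 2), n_panels)[seq_len(2L * n_panels - 1L)]
  simpson <- h / 3 * (f[1] + sum(wts * f[2:(2L * n_panels)]) +
                        f[2L * n_panels + 1L])
  min(max(0.5 + simpson / pi, 0), 1)
}

# plain Monte-Carlo tail estimate, for spot-checking the oracle itself
wchisq_tail_mc <- function(q, lam, n = 4e5, seed = 1) {
  set.seed(seed)
  draws <- colSums(lam * matrix(rchisq(n * length(lam), df = 1),
                                nrow = length(lam)))
  mean(draws > q)
}

# log approximate Bayes factor by direct numeric quadrature of the
# two-normal marginal-likelihood ratio
labf_quadrature <- function(beta, se, w) {
  num <- stats::integrate(function(b)
    stats::dnorm(beta, mean = b, sd = se) * stats::dnorm(b, 0, w),
    lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log(num) - stats::dnorm(beta, 0, se, log = TRUE)
}

# bare-hands colocalization enumeration in probability space (no log-sum-exp)
coloc_enum_oracle <- function(bf1, bf2, p1, p2, p12) {
  m <- length(bf1)
  s1 <- sum(bf1); s2 <- sum(bf2)
  s12 <- sum(bf1 * bf2)
  h <- c(1, p1 * s1, p2 * s2,
         p1 * p2 * (s1 * s2 - s12), p12 * s12)
  h / sum(h)
}

# quick builder for harmonized instrument tables
mk_pairs <- function(bx, sx, by, sy, n_exp = 1e5, n_out = 1e5) {
  k <- length(bx)
  df <- data.frame(variant_id = paste0("v", seq_len(k)), chrom = "1",
                   pos = seq_len(k) * 1000L, effect_allele = "A",
                   other_allele = "C", beta_exp = bx, se_exp = sx,
                   p_exp = 2 * pnorm(-abs(bx / sx)), n_exp = n_exp,
                   eaf_exp = 0.3, beta_out = by, se_out = sy,
                   p_out = 2 * pnorm(-abs(by / sy)), n_out = n_out,
                   eaf_out = 0.3, action = "kept",
                   stringsAsFactors = FALSE)
  new("HarmonizedPairs", pairs = df, metadata = list())
}

# minimal canonical sumstats data.frame
mk_records <- function(variant_id, chrom = "1", pos, ea = "A", oa = "C",
                       eaf = 0.3, beta, se, pval = NULL, n = 1e5,
                       ncase = NA, nctrl = NA) {
  df <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                   effect_allele = ea, other_allele = oa, eaf = eaf,
                   beta = beta, se = se, n = n, ncase = ncase,
                   nctrl = nctrl, stringsAsFactors = FALSE)
  if (!is.null(pval)) df$pval <- pval
  df
}
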