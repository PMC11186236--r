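#' @include AllClasses.R
NULL

#' SMR / HEIDI configuration
#'
#' Defaults follow common summary-data-based-MR practice: the instrument is
#' the top cis-eQTL at p < 5e-8; HEIDI draws additional SNPs associated with
#' expression at p < 1.57e-3 (z^2 > 10) whose r-squared with the top SNP
#' lies in [0.05, 0.9] -- the lower bound removes uninformative SNPs, the
#' upper bound near-collinear ones -- using at most 20 and at least 3 SNPs
#' (top included); a HEIDI p below 0.01 is called linkage.
#'
#' @param pTop top-eQTL selection threshold.
#' @param pEqtlInclusion eQTL p-value ceiling for HEIDI candidate SNPs.
#' @param r2Min,r2Max bounds on r-squared with the top SNP for candidates.
#' @param maxSnps,minSnps HEIDI SNP-count cap and floor (top included).
#' @param heidiP linkage-call threshold on the HEIDI p-value.
#' @param cisFlank cis-window flank in base pairs.
#' @return list of settings.
#' @export
smrConfig <- function(pTop = 5e-8, pEqtlInclusion = 1.57e-3,
                      r2Min = 0.05, r2Max = 0.9,
                      maxSnps = 20L, minSnps = 3L, heidiP = 0.01,
                      cisFlank = 1e6) {
  list(pTop = pTop, pEqtlInclusion = pEqtlInclusion, r2Min = r2Min,
       r2Max = r2Max, maxSnps = as.integer(maxSnps),
       minSnps = as.integer(minSnps), heidiP = heidiP, cisFlank = cisFlank)
}

#' Top cis-eQTL of a gene
#'
#' Returns the minimum-p record of the cis region if it clears the
#' selection threshold, else NULL. Ties on p are broken by larger |z| then
#' (chrom, pos) order.
#'
#' @param cisEqtl \linkS4class{SumStats} cis-window subset.
#' @param pTop selection threshold (default 5e-8).
#' @return one-row data.frame (a variant association) or NULL.
#' @export
topEqtl <- function(cisEqtl, pTop = 5e-8) {
  rec <- cisEqtl@records
  if (nrow(rec) == 0L) return(NULL)
  z <- abs(rec$beta / rec$se)
  ord <- order(rec$pval, -z, rec$chrom, rec$pos)
  top <- rec[ord[1], , drop = FALSE]
  if (top$pval >= pTop) return(NULL)
  rownames(top) <- NULL
  top
}

#' SMR test statistic for one gene
#'
#' With z_zx = b_zx/se_zx (top-eQTL effect on expression) and z_zy =
#' b_zy/se_zy (same variant's effect on the outcome), the causal estimate is
#' b_smr = b_zy / b_zx (outcome per SD expression) and the test statistic
#' T_smr = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2), referred to chi-square(1).
#' The SE is recovered as |b_smr| / sqrt(T_smr).
#'
#' @param bZx,seZx eQTL effect and SE (alleles already harmonized with the
#'   outcome record).
#' @param bZy,seZy outcome effect and SE at the same variant.
#' @return list(bSmr, seSmr, pSmr, tSmr).
#' @export
smrTest <- function(bZx, seZx, bZy, seZy) {
  if (bZx == 0) stop("SMR undefined: eQTL effect is zero")
  z1 <- (bZx / seZx)^2
  z2 <- (bZy / seZy)^2
  t_smr <- if (z2 == 0) 0 else z1 * z2 / (z1 + z2)
  b_smr <- bZy / bZx
  p_smr <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  se_smr <- if (t_smr > 0) abs(b_smr) / sqrt(t_smr) else NA_real_
  list(bSmr = b_smr, seSmr = se_smr, pSmr = p_smr, tSmr = t_smr)
}

## Satterthwaite two-moment approximation to the upper tail of a weighted
## sum of independent chi-square(1) variables with weights lam.  Fast but
## can err by several percent mid-distribution; used only as a fallback.
.satterthwaite_p <- function(q, lam) {
  lam <- lam[lam > 1e-12]
  s1 <- sum(lam)
  s2 <- sum(lam^2)
  scale <- s2 / s1
  df <- s1^2 / s2
  pchisq(q / scale, df = df, lower.tail = FALSE)
}

## Imhof's numerical inversion of the characteristic function:
## P(sum lam_i chi2_1 > q) = 1/2 + (1/pi) int_0^inf sin(theta(u))/(u rho(u)) du
## with theta(u) = 0.5 sum atan(lam_i u) - 0.5 q u and
## rho(u) = prod (1 + lam_i^2 u^2)^(1/4).  Exact up to quadrature error.
.imhof_p <- function(q, lam) {
  lam <- lam[abs(lam) > 1e-12]
  if (length(lam) == 0L) return(1)
  p_satt <- .satterthwaite_p(q, lam)
  ## deep in the tail the inversion integral is hopelessly oscillatory and
  ## the absolute error of the moment approximation is already negligible
  if (p_satt < 1e-9) return(p_satt)
  ## truncate where the envelope of one half-oscillation is negligible
  env <- function(u) exp(-log(u) - 0.25 * sum(log1p(lam^2 * u^2)))
  U <- 10
  while (env(U) * (2 * pi / max(q, 0.1)) > 1e-10 && U < 2e5) U <- U * 2
  fvals <- function(u) {
    th <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * q * u
    lr <- 0.25 * colSums(log1p(outer(lam^2, u^2)))
    f <- sin(th) / (u * exp(lr))
    f[u == 0] <- 0.5 * (sum(lam) - q)   # analytic limit at u = 0
    f
  }
  simpson <- function(a, b, half) {
    u <- seq(a, b, length.out = 2L * half + 1L)
    f <- fvals(u)
    w <- rep(c(4, 2), half)[seq_len(2L * half - 1L)]
    (u[2] - u[1]) / 3 * (f[1] + sum(w * f[2:(2L * half)]) + f[2L * half + 1L])
  }
  ## dense head segment resolves the atan/log features near the origin;
  ## the tail segment is gridded to the sin(q u / 2) oscillation period
  uA <- min(U, 100)
  val <- simpson(0, uA, 20000L)
  if (U > uA) {
    h_tail <- (4 * pi / max(q, 0.5)) / 24
    half_tail <- min(ceiling((U - uA) / h_tail / 2), 400000L)
    val <- val + simpson(uA, U, half_tail)
  }
  if (!is.finite(val)) return(p_satt)
  min(max(0.5 + val / pi, 0), 1)
}

#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Tests whether the expression-outcome association at a locus is driven by
#' a single shared causal variant (null) or by linkage of distinct variants
#' (alternative). Candidate SNPs around the already-chosen top eQTL are
#' selected by eQTL p-value and LD bounds; for each candidate the deviation
#' d_i of its ratio estimate b_zy(i)/b_zx(i) from the top SNP's ratio is
#' formed, the covariance of the d vector is obtained by first-order delta
#' propagation using within-cohort LD-induced covariances
#' (cov(b_zy(i), b_zy(j)) ~ r_ij se_zy(i) se_zy(j), analogously for the
#' eQTL cohort; the two cohorts are independent so there are no cross
#' terms), and the statistic sum(z_d^2) is referred to its null -- a
#' weighted sum of independent chi-square(1) with weights equal to the
#' eigenvalues of the correlation matrix of z_d -- by Imhof's numerical
#' inversion of the characteristic function (a Satterthwaite two-moment
#' scaled chi-square stands in if the quadrature fails to converge).
#'
#' @param regionPairs \linkS4class{HarmonizedPairs} of the cis region
#'   (eQTL as exposure, outcome as outcome), containing the top SNP.
#' @param topVariant variant_id of the top eQTL.
#' @param ld \linkS4class{LDMatrix}; candidates absent from it are excluded
#'   (and recorded in the return value).
#' @param cfg settings from \code{\link{smrConfig}}.
#' @return list(heidiP, nSnps, status, excluded). \code{nSnps} counts the
#'   SNPs used including the top; with fewer than \code{minSnps} the status
#'   is \code{heidi_insufficient_snps} and heidiP is NA.
#' @export
heidiTest <- function(regionPairs, topVariant, ld, cfg = smrConfig()) {
  p <- keptPairs(regionPairs)@pairs
  ti <- match(topVariant, p$variant_id)
  if (is.na(ti)) stop("top variant '", topVariant, "' not in harmonized region")
  excluded <- setdiff(p$variant_id, ld@variantIds)
  p <- p[p$variant_id %in% ld@variantIds, , drop = FALSE]
  ti <- match(topVariant, p$variant_id)
  if (is.na(ti))
    return(list(heidiP = NA_real_, nSnps = 0L,
                status = "heidi_insufficient_snps", excluded = excluded))
  ridx <- match(p$variant_id, ld@variantIds)
  r_top <- ld@r[ridx, ridx[ti]]
  cand <- which(seq_len(nrow(p)) != ti &
                  p$p_exp < cfg$pEqtlInclusion &
                  r_top^2 >= cfg$r2Min & r_top^2 <= cfg$r2Max)
  cand <- cand[order(p$p_exp[cand])]
  if (length(cand) > cfg$maxSnps - 1L) cand <- cand[seq_len(cfg$maxSnps - 1L)]
  n_snps <- length(cand) + 1L
  if (n_snps < cfg$minSnps)
    return(list(heidiP = NA_real_, nSnps = n_snps,
                status = "heidi_insufficient_snps", excluded = excluded))
  sel <- c(ti, cand)
  bzx <- p$beta_exp[sel]; sezx <- p$se_exp[sel]
  bzy <- p$beta_out[sel]; sezy <- p$se_out[sel]
  rr <- ld@r[ridx[sel], ridx[sel], drop = FALSE]
  ## delta-propagated covariance of the ratio estimates
  cy <- rr * tcrossprod(sezy)
  cx <- rr * tcrossprod(sezx)
  g_y <- 1 / bzx                  # d b_xy / d b_zy
  g_x <- -bzy / bzx^2             # d b_xy / d b_zx
  K <- tcrossprod(g_y) * cy + tcrossprod(g_x) * cx
  q <- length(sel) - 1L
  idx <- seq_len(q) + 1L
  d <- bzy[idx] / bzx[idx] - bzy[1] / bzx[1]
  V <- K[idx, idx, drop = FALSE] - outer(K[idx, 1], rep(1, q)) -
    outer(rep(1, q), K[1, idx]) + K[1, 1]
  sd_d <- sqrt(pmax(diag(V), 1e-300))
  z_d <- d / sd_d
  C <- V / tcrossprod(sd_d)
  C <- 0.5 * (C + t(C))
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  heidi_p <- .imhof_p(sum(z_d^2), lam)
  list(heidiP = heidi_p, nSnps = n_snps, status = "ok", excluded = excluded)
}

#' Run SMR + HEIDI for one gene
#'
#' Composes cis-window extraction, top-eQTL selection, allele harmonization
#' against the outcome, the SMR test and the HEIDI linkage test. A gene
#' "passes SMR" iff its SMR p is below the chosen significance threshold
#' AND its HEIDI p is at or above the linkage threshold (default 0.01).
#'
#' @param gene one-row gene annotation (gene_id, chrom, start, end).
#' @param eqtlTable \linkS4class{SumStats} of the expression trait.
#' @param outcome \linkS4class{SumStats} of the outcome.
#' @param ld \linkS4class{LDMatrix} for the region.
#' @param cfg settings from \code{\link{smrConfig}}.
#' @param tissueLabel expression-dataset label.
#' @return an \linkS4class{SMRResult}.
#' @export
runGeneSMR <- function(gene, eqtlTable, outcome, ld, cfg = smrConfig(),
                       tissueLabel = "blood") {
  gene_id <- if (!is.null(gene$gene_id)) gene$gene_id else "gene"
  empty <- function(status) new("SMRResult", geneId = gene_id,
                                tissueLabel = tissueLabel, topVariant = NA_character_,
                                bZx = NA_real_, seZx = NA_real_,
                                bZy = NA_real_, seZy = NA_real_,
                                bSmr = NA_real_, seSmr = NA_real_,
                                pSmr = NA_real_, heidiP = NA_real_,
                                heidiNSnps = 0L, status = status,
                                metadata = list())
  cis <- cisWindow(gene, eqtlTable, flank = cfg$cisFlank)
  top <- topEqtl(cis, cfg$pTop)
  if (is.null(top)) return(empty("no_top_eqtl"))
  h <- suppressWarnings(harmonize(cis, outcome))
  p <- keptPairs(h)@pairs
  row <- p[p$variant_id == top$variant_id, , drop = FALSE]
  if (nrow(row) == 0L) return(empty("no_top_eqtl"))
  core <- smrTest(row$beta_exp, row$se_exp, row$beta_out, row$se_out)
  hd <- heidiTest(h, top$variant_id, ld, cfg)
  status <- if (hd$status == "heidi_insufficient_snps") "heidi_insufficient_snps"
  else if (!is.na(hd$heidiP) && hd$heidiP < cfg$heidiP) "heidi_linkage"
  else "ok"
  new("SMRResult", geneId = gene_id, tissueLabel = tissueLabel,
      topVariant = top$variant_id,
      bZx = row$beta_exp, seZx = row$se_exp,
      bZy = row$beta_out, seZy = row$se_out,
      bSmr = core$bSmr, seSmr = core$seSmr, pSmr = core$pSmr,
      heidiP = hd$heidiP, heidiNSnps = as.integer(hd$nSnps),
      status = status,
      metadata = list(t_smr = core$tSmr, heidi_excluded = hd$excluded))
}
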