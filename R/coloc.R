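#' @include AllClasses.R
NULL

#' Colocalization priors and effect scales
#'
#' Per-variant prior probabilities of association with trait 1 only (p1),
#' trait 2 only (p2) and both traits (p12), plus the prior standard
#' deviations of true effect sizes used by the approximate Bayes factors
#' (0.15 for quantitative traits, 0.2 on the log-odds scale for
#' case-control traits).
#'
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param wQuant,wCc prior effect-size SDs for quantitative and
#'   case-control traits.
#' @return list of settings.
#' @export
colocConfig <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        wQuant = 0.15, wCc = 0.2) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 < 1)
  list(p1 = p1, p2 = p2, p12 = p12, wQuant = wQuant, wCc = wCc)
}

#' Log approximate Bayes factor of a single association
#'
#' Wakefield-style asymptotic Bayes factor comparing a normal effect prior
#' N(0, w^2) against the point null, given an estimate and its standard
#' error: with V = se^2, z = beta/se and shrinkage r = w^2/(w^2 + V),
#' \code{lABF = 0.5 (log(1 - r) + r z^2)}.
#'
#' @param beta,se estimate and standard error (vectorized).
#' @param w prior effect-size standard deviation.
#' @return numeric vector of log Bayes factors.
#' @export
labf <- function(beta, se, w) {
  stopifnot(all(se > 0), w > 0)
  V <- se^2
  z2 <- (beta / se)^2
  r <- w^2 / (w^2 + V)
  0.5 * (log1p(-r) + r * z2)
}

.lse <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log-sum-exp over all ordered pairs (i, j) with i != j of l1[i] + l2[j],
## evaluated explicitly (no catastrophic subtraction of nearly equal sums).
.lse_offdiag <- function(l1, l2) {
  M <- outer(l1, l2, "+")
  diag(M) <- -Inf
  .lse(M)
}

#' Bayesian colocalization of two regional association signals
#'
#' Enumerates per-variant approximate Bayes factors for both traits over
#' the variants shared by the two (allele-harmonized) regional tables and
#' returns the posterior probabilities of the five hypotheses: H0 neither
#' trait associated, H1/H2 one trait only, H3 two distinct causal variants,
#' H4 a single shared causal variant. All mass arithmetic is done in log
#' space with log-sum-exp; the H3 mass is accumulated over explicit ordered
#' variant pairs i != j rather than by subtraction. A posterior PPH4 above
#' 0.8 is called colocalized; above 0.5, moderate.
#'
#' @param trait1,trait2 aligned \linkS4class{SumStats} regional subsets
#'   sharing effect-allele orientation; the variant intersection is used.
#' @param cfg priors from \code{\link{colocConfig}}.
#' @return a \linkS4class{ColocResult}. With fewer than 2 shared variants
#'   H3 is undefined; posteriors are computed over the remaining hypotheses
#'   and the status notes the degeneracy.
#' @export
colocalize <- function(trait1, trait2, cfg = colocConfig()) {
  stopifnot(is(trait1, "SumStats"), is(trait2, "SumStats"))
  r1 <- trait1@records
  r2 <- trait2@records
  shared <- intersect(r1$variant_id, r2$variant_id)
  r1 <- r1[match(shared, r1$variant_id), , drop = FALSE]
  r2 <- r2[match(shared, r2$variant_id), , drop = FALSE]
  m <- length(shared)
  if (m == 0L) stop("no shared variants between the two regions")
  w1 <- if (trait1@traitType == "binary") cfg$wCc else cfg$wQuant
  w2 <- if (trait2@traitType == "binary") cfg$wCc else cfg$wQuant
  l1 <- labf(r1$beta, r1$se, w1)
  l2 <- labf(r2$beta, r2$se, w2)
  s1 <- .lse(l1)
  s2 <- .lse(l2)
  s12 <- .lse(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(cfg$p1) + s1,
          h2 = log(cfg$p2) + s2,
          h3 = if (m >= 2L) log(cfg$p1) + log(cfg$p2) + .lse_offdiag(l1, l2)
               else NA_real_,
          h4 = log(cfg$p12) + s12)
  ok <- !is.na(lh)
  denom <- .lse(lh[ok])
  pp <- rep(NA_real_, 5)
  pp[ok] <- exp(lh[ok] - denom)
  names(pp) <- paste0("pph", 0:4)
  call <- if (pp["pph4"] > 0.8) "colocalized"
  else if (pp["pph4"] > 0.5) "moderate" else "none"
  new("ColocResult", pph = pp, nVariants = as.integer(m), call = call,
      status = if (m >= 2L) "ok" else "h3_undefined",
      metadata = list(priors = cfg[c("p1", "p2", "p12")],
                      w = c(trait1 = w1, trait2 = w2),
                      trait1 = trait1@traitId, trait2 = trait2@traitId))
}
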