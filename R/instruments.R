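#' @include AllClasses.R
NULL

#' Select instruments by association p-value
#'
#' Retains cis records whose p-value falls below the source-specific
#' genome-wide threshold (e.g. 1.8e-9 for the Iceland/deCODE pQTLs,
#' 1.004e-11 for Fenland, 1.7e-11 for UKB-PPP), preserving record order.
#'
#' @param cisTable \linkS4class{SumStats}, typically a cis-window subset.
#' @param pThreshold retention threshold (strict \code{pval < pThreshold}).
#' @return \linkS4class{SumStats} subset (possibly empty; an empty set means
#'   the protein is skipped, not an error).
#' @export
selectInstruments <- function(cisTable, pThreshold) {
  stopifnot(is(cisTable, "SumStats"), pThreshold > 0)
  out <- cisTable
  out@records <- cisTable@records[cisTable@records$pval < pThreshold, ,
                                  drop = FALSE]
  rownames(out@records) <- NULL
  out@metadata$p_threshold <- pThreshold
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the lowest-p remaining variant and discards all
#' remaining variants lying within \code{windowKb} kilobases of it AND in LD
#' with it at r-squared above \code{r2Max}. Ties on p-value are broken by
#' (chrom, pos) order. The defaults mirror the common sensitivity-analysis
#' setting clump_kb = 10,000 / clump_r2 = 0.01.
#'
#' @param candidates \linkS4class{SumStats} subset; every variant must be
#'   present in \code{ld}.
#' @param ld \linkS4class{LDMatrix}.
#' @param r2Max maximum allowed squared correlation with a retained index
#'   variant (default 0.01).
#' @param windowKb window in kilobases (default 10000).
#' @return \linkS4class{SumStats} subset in the input's record order.
#' @export
clumpVariants <- function(candidates, ld, r2Max = 0.01, windowKb = 10000) {
  stopifnot(is(candidates, "SumStats"), is(ld, "LDMatrix"))
  rec <- candidates@records
  if (nrow(rec) == 0L) return(candidates)
  miss <- setdiff(rec$variant_id, ld@variantIds)
  if (length(miss))
    stop("variant(s) missing from LD matrix: ", paste(miss, collapse = ", "))
  sub <- .ld_subset(ld, rec$variant_id)
  r2 <- sub@r^2
  ord <- order(rec$pval, rec$chrom, rec$pos)
  alive <- rep(TRUE, nrow(rec))
  keep <- logical(nrow(rec))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- alive & rec$chrom == rec$chrom[i] &
      abs(rec$pos - rec$pos[i]) <= windowKb * 1000 & r2[, i] > r2Max
    alive[near] <- FALSE
  }
  out <- candidates
  out@records <- rec[keep, , drop = FALSE]
  rownames(out@records) <- NULL
  out@metadata$clump <- list(r2_max = r2Max, window_kb = windowKb,
                             n_in = nrow(rec), n_kept = sum(keep))
  out
}

#' Approximate instrument F-statistic
#'
#' For a variant-exposure association with estimate \code{beta} and standard
#' error \code{se}, the single-instrument F-statistic is approximated as
#' \code{(beta/se)^2}. Instruments with F at or below 10 are flagged weak
#' (the conventional no-weak-instrument-bias threshold).
#'
#' @param beta,se numeric vectors (recycled).
#' @return data.frame(f, weak).
#' @export
fStatistic <- function(beta, se) {
  stopifnot(all(se > 0))
  f <- (beta / se)^2
  data.frame(f = f, weak = f <= 10)
}

#' Steiger directionality filter
#'
#' Guards against reverse causation by removing instruments that explain
#' more variance in the outcome than in the exposure. Per variant a
#' pseudo-variance-explained is computed on each side as
#' \code{r2 = t^2 / (t^2 + n - 2)} with \code{t = beta/se}; the variant is
#' retained iff \code{r2_exposure > r2_outcome} (strict; ties are dropped as
#' a conservative choice). The same approximation is applied to quantitative
#' and binary traits.
#'
#' @param pairs a \linkS4class{HarmonizedPairs} (aligned variants only are
#'   considered; rows already dropped at harmonization are ignored).
#' @return list with \code{kept} (\linkS4class{HarmonizedPairs}) and
#'   \code{report} (data.frame variant_id, r2_exp, r2_out, retained,
#'   reason). Variants with n <= 2 on either side are dropped with reason
#'   \code{n_too_small}.
#' @export
steigerFilter <- function(pairs) {
  stopifnot(is(pairs, "HarmonizedPairs"))
  p <- keptPairs(pairs)@pairs
  if (nrow(p) == 0L)
    return(list(kept = keptPairs(pairs),
                report = data.frame(variant_id = character(0),
                                    r2_exp = numeric(0), r2_out = numeric(0),
                                    retained = logical(0),
                                    reason = character(0))))
  pseudo_r2 <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  bad_n <- is.na(p$n_exp) | is.na(p$n_out) | p$n_exp <= 2 | p$n_out <= 2
  r2e <- ifelse(bad_n, NA, pseudo_r2(p$beta_exp, p$se_exp, p$n_exp))
  r2o <- ifelse(bad_n, NA, pseudo_r2(p$beta_out, p$se_out, p$n_out))
  retained <- !bad_n & r2e > r2o
  reason <- ifelse(bad_n, "n_too_small",
                   ifelse(retained, "", "outcome_variance_not_smaller"))
  report <- data.frame(variant_id = p$variant_id, r2_exp = r2e, r2_out = r2o,
                       retained = retained, reason = reason,
                       stringsAsFactors = FALSE)
  kept <- new("HarmonizedPairs", pairs = p[retained, , drop = FALSE],
              metadata = c(pairs@metadata,
                           list(steiger = "pseudo-r2 t2/(t2+n-2)")))
  rownames(kept@pairs) <- NULL
  list(kept = kept, report = report)
}

#' Assemble an instrument set
#'
#' Bundles the harmonized instruments for one exposure with the regional LD
#' matrix and per-variant F-statistics.
#'
#' @param id protein or gene identifier.
#' @param pairs \linkS4class{HarmonizedPairs} of retained instruments.
#' @param ld \linkS4class{LDMatrix} (may be over a superset of variants; it
#'   is subset to the instruments).
#' @param sourceLabel dataset label.
#' @return an \linkS4class{InstrumentSet}.
#' @export
InstrumentSet <- function(id, pairs, ld = NULL, sourceLabel = "unknown") {
  kp <- keptPairs(pairs)
  p <- kp@pairs
  if (is.null(ld)) {
    ld <- LDMatrix(diag(nrow(p)), p$variant_id)
  } else {
    ld <- .ld_subset(ld, p$variant_id)
  }
  fs <- if (nrow(p)) cbind(variant_id = p$variant_id,
                           fStatistic(p$beta_exp, p$se_exp))
        else data.frame(variant_id = character(0), f = numeric(0),
                        weak = logical(0))
  new("InstrumentSet", id = id, pairs = kp, ld = ld,
      sourceLabel = sourceLabel, fStats = fs)
}
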