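#' @include AllClasses.R
NULL

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced), applied
#' within each protein dataset separately in the pipeline. Significance is
#' declared at q < 0.05.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bhFDR <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-dataset estimates of the same protein-outcome effect:
#' \code{beta = sum(b_i/se_i^2) / sum(1/se_i^2)},
#' \code{se = sqrt(1/sum(1/se_i^2))}. A single estimate passes through
#' unchanged. Odds ratio and 95% CI follow by exponentiation for binary
#' outcomes.
#'
#' @param beta,se numeric vectors of estimates and standard errors.
#' @return list(beta, se, pval, or, orLow, orHigh, k).
#' @export
fixedEffectMeta <- function(beta, se) {
  keep <- is.finite(beta) & is.finite(se) & se > 0
  beta <- beta[keep]; se <- se[keep]
  if (length(beta) == 0L) stop("no usable estimates to combine")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  list(beta = b, se = s, pval = 2 * pnorm(-abs(b / s)),
       or = exp(b), orLow = exp(b - qnorm(0.975) * s),
       orHigh = exp(b + qnorm(0.975) * s), k = length(beta))
}

#' Count concordant replications across an outcome panel
#'
#' A panel outcome replicates the principal finding when its MR p-value is
#' below 0.05 AND its effect, mapped through the outcome's polarity onto
#' the disease-risk direction, has the same sign as the principal estimate.
#' Polarity is -1 for outcomes where a negative beta means increased risk
#' (eGFR and annualized eGFR slope) and +1 otherwise; with a panel of
#' 3 disease replications + 4 kidney-function outcomes + 4 eGFR-slope
#' strata + 6 clinical types the count is bounded by 17.
#'
#' @param principalBeta the principal (disease) causal estimate.
#' @param panel data.frame with columns \code{outcome_id}, \code{polarity}
#'   (+1/-1), \code{beta}, \code{pval}; rows with missing results are
#'   skipped, never counted.
#' @param alpha per-outcome significance level (default 0.05).
#' @return integer replication count.
#' @export
countReplications <- function(principalBeta, panel, alpha = 0.05) {
  stopifnot(all(panel$polarity %in% c(-1, 1)))
  ok <- is.finite(panel$beta) & is.finite(panel$pval)
  hit <- ok & panel$pval < alpha &
    sign(panel$beta) * panel$polarity == sign(principalBeta)
  sum(hit)
}

#' Evidence-tier assignment
#'
#' Tier 1: MR-significant and passed both SMR and colocalization; tier 2:
#' MR-significant plus exactly one of the two; tier 3: MR-significant only;
#' proteins without MR significance get no tier.
#'
#' @param mrSig logical; q < 0.05 in at least one protein dataset.
#' @param passedSmr,passedColoc logical flags.
#' @return character: \code{"1"}, \code{"2"}, \code{"3"} or \code{"none"}.
#' @export
assignTier <- function(mrSig, passedSmr, passedColoc) {
  stopifnot(is.logical(mrSig), is.logical(passedSmr), is.logical(passedColoc))
  if (!mrSig) return("none")
  n <- sum(passedSmr, passedColoc)
  c("3", "2", "1")[n + 1L]
}

#' Protein/gene direction consistency across tissues
#'
#' Compares the sign of the protein-level causal estimate with the signs of
#' the gene-expression (SMR) estimates per tissue: consistent when all
#' agree, opposite when none do, mixed ("-/+") otherwise.
#'
#' @param proteinBeta protein-level causal estimate.
#' @param geneBetas named numeric vector of per-tissue SMR estimates (NAs
#'   ignored).
#' @return list(perTissue = named logical, summary = character).
#' @export
directionConsistency <- function(proteinBeta, geneBetas) {
  geneBetas <- geneBetas[is.finite(geneBetas)]
  if (length(geneBetas) == 0L)
    return(list(perTissue = logical(0), summary = NA_character_))
  agree <- sign(geneBetas) == sign(proteinBeta)
  summary <- if (all(agree)) "consistent"
  else if (!any(agree)) "opposite" else "mixed"
  list(perTissue = agree, summary = summary)
}

#' Assemble the per-protein evidence table
#'
#' Joins per-source MR results and q-values, the combined (meta-analyzed)
#' effect, SMR/HEIDI and colocalization outcomes, panel replication counts
#' and direction consistency into one row per protein, assigns tiers, and
#' orders rows by (tier, combined q). Protein ids must be unique across the
#' inputs.
#'
#' @param mrBySource named list (source -> data.frame with protein_id,
#'   beta, se, pval, q, n_instruments, status).
#' @param combined data.frame(protein_id, beta, se, pval, or, or_low,
#'   or_high, n_sources_used).
#' @param smr data.frame(protein_id, b_smr, p_smr, heidi_p, status,
#'   passed_smr) -- one row per protein (blood), plus optionally a named
#'   list column or extra tissues handled upstream.
#' @param coloc data.frame(protein_id, pph4, call, passed_coloc).
#' @param replication data.frame(protein_id, replication_count).
#' @param direction data.frame(protein_id, direction_consistent).
#' @return data.frame, one row per protein.
#' @export
buildEvidenceTable <- function(mrBySource, combined, smr, coloc,
                               replication, direction) {
  ids <- unique(c(combined$protein_id,
                  unlist(lapply(mrBySource, function(x) x$protein_id),
                         use.names = FALSE)))
  for (tab in list(combined, smr, coloc, replication, direction))
    if (anyDuplicated(tab$protein_id))
      stop("duplicate protein_id key in evidence inputs")
  if (length(ids) == 0L)
    return(data.frame(protein_id = character(0)))
  look <- function(tab, col, id, default = NA) {
    i <- match(id, tab$protein_id)
    if (is.na(i)) default else tab[[col]][i]
  }
  rows <- lapply(ids, function(id) {
    qs <- vapply(mrBySource, function(x) look(x, "q", id, NA_real_), 0)
    n_sig <- sum(qs < 0.05, na.rm = TRUE)
    mr_sig <- n_sig >= 1L
    p_smr <- look(smr, "passed_smr", id, NA)
    p_col <- look(coloc, "passed_coloc", id, NA)
    data.frame(
      protein_id = id,
      combined_beta = look(combined, "beta", id, NA_real_),
      combined_se = look(combined, "se", id, NA_real_),
      combined_pval = look(combined, "pval", id, NA_real_),
      combined_or = look(combined, "or", id, NA_real_),
      combined_or_low = look(combined, "or_low", id, NA_real_),
      combined_or_high = look(combined, "or_high", id, NA_real_),
      q_min = if (all(is.na(qs))) NA_real_ else min(qs, na.rm = TRUE),
      n_sig_sources = n_sig,
      smr_p = look(smr, "p_smr", id, NA_real_),
      heidi_p = look(smr, "heidi_p", id, NA_real_),
      passed_smr = isTRUE(p_smr),
      pph4 = look(coloc, "pph4", id, NA_real_),
      coloc_call = look(coloc, "call", id, NA_character_),
      passed_coloc = isTRUE(p_col),
      replication_count = look(replication, "replication_count", id, 0L),
      direction_consistent = look(direction, "direction_consistent", id,
                                  NA_character_),
      tier = assignTier(mr_sig, isTRUE(p_smr), isTRUE(p_col)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tier_rank <- match(out$tier, c("1", "2", "3", "none"))
  out <- out[order(tier_rank, out$q_min, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an evidence table
#'
#' TSV round-trip at 10 significant digits; \code{readEvidenceTable}
#' restores column types so write-read-write is byte-identical.
#'
#' @param x evidence data.frame.
#' @param path file path.
#' @return invisibly the path (write) / the data.frame (read).
#' @export
writeEvidenceTable <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], function(col) ifelse(is.na(col), NA, signif(col, 10)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeEvidenceTable
#' @export
readEvidenceTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
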