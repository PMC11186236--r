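#' @import methods
#' @importFrom stats pnorm pchisq pt qnorm p.adjust setNames rnorm runif complete.cases
#' @importFrom utils read.delim write.table head
NULL

.CANONICAL_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n", "ncase", "nctrl")
.MANDATORY_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                     "beta", "se")
.BASES <- c("A", "C", "G", "T")

#' GWAS summary-statistics table for one trait
#'
#' Container for variant-level marginal association statistics of a single
#' trait (a plasma protein, a gene-expression level, or a disease outcome).
#' Each record carries the variant identity and position, the effect and
#' other allele, the effect-allele frequency, the marginal effect estimate
#' per effect-allele copy (log-odds for binary traits, SD units for
#' quantitative traits), its standard error, p-value and sample size.
#'
#' @slot traitId character scalar naming the trait.
#' @slot traitType either \code{"quantitative"} or \code{"binary"}.
#' @slot records data.frame with the canonical columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n},
#'   \code{ncase}, \code{nctrl}, sorted by (chrom, pos).
#' @slot metadata list of provenance entries (rows dropped at validation,
#'   reasons, source path).
#' @exportClass SumStats
setClass("SumStats",
         representation(traitId = "character",
                        traitType = "character",
                        records = "data.frame",
                        metadata = "list"))

setValidity("SumStats", function(object) {
  msg <- character(0)
  rec <- object@records
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (!all(.CANONICAL_COLS %in% names(rec)))
    msg <- c(msg, paste("records missing columns:",
                        paste(setdiff(.CANONICAL_COLS, names(rec)), collapse = ", ")))
  if (length(msg) == 0L && nrow(rec) > 0L) {
    if (anyDuplicated(rec$variant_id))
      msg <- c(msg, "variant_id values must be unique")
    if (any(rec$se <= 0, na.rm = TRUE)) msg <- c(msg, "all se must be > 0")
    if (any(rec$pval <= 0 | rec$pval > 1, na.rm = TRUE))
      msg <- c(msg, "pval must lie in (0, 1]")
    if (any(rec$eaf < 0 | rec$eaf > 1, na.rm = TRUE))
      msg <- c(msg, "eaf must lie in [0, 1] when present")
    bad_allele <- !(rec$effect_allele %in% .BASES) | !(rec$other_allele %in% .BASES) |
      rec$effect_allele == rec$other_allele
    if (any(bad_allele))
      msg <- c(msg, "alleles must be distinct single bases A/C/G/T")
    ord <- order(rec$chrom, rec$pos)
    if (!identical(ord, seq_len(nrow(rec))))
      msg <- c(msg, "records must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Regional linkage-disequilibrium matrix
#'
#' Square matrix of pairwise variant correlations (r, not r-squared) used by
#' LD clumping, the HEIDI test, and the regional summary-statistics
#' simulator.
#'
#' @slot variantIds ordered character vector labelling rows/columns.
#' @slot r numeric matrix of correlations in [-1, 1], symmetric with unit
#'   diagonal, near-positive-semidefinite (smallest eigenvalue >= -1e-8).
#' @exportClass LDMatrix
setClass("LDMatrix",
         representation(variantIds = "character", r = "matrix"))

setValidity("LDMatrix", function(object) {
  msg <- character(0)
  r <- object@r
  m <- length(object@variantIds)
  if (!is.numeric(r)) msg <- c(msg, "r must be numeric")
  if (nrow(r) != m || ncol(r) != m)
    msg <- c(msg, "dimensions of r must match length of variantIds")
  if (length(msg) == 0L && m > 0L) {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "r must have unit diagonal")
    if (max(abs(r)) > 1 + 1e-8) msg <- c(msg, "correlations must lie in [-1, 1]")
    if (m <= 600) {
      ev <- eigen(0.5 * (r + t(r)), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        msg <- c(msg, "r must be near positive semidefinite (min eigenvalue >= -1e-8)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Allele-harmonized exposure-outcome variant pairs
#'
#' Result of aligning an exposure table (pQTL or eQTL) with an outcome table
#' onto a shared effect-allele orientation. One row per shared variant with
#' both sides' statistics and the action that was taken
#' (\code{kept}, \code{sign_flipped}, \code{freq_inferred},
#' \code{dropped_palindromic}, \code{dropped_mismatch}).
#'
#' @slot pairs data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{beta_exp}, \code{se_exp}, \code{p_exp}, \code{n_exp},
#'   \code{eaf_exp}, \code{beta_out}, \code{se_out}, \code{p_out},
#'   \code{n_out}, \code{eaf_out}, \code{action}.
#' @slot metadata list (counts per action, trait ids).
#' @exportClass HarmonizedPairs
setClass("HarmonizedPairs",
         representation(pairs = "data.frame", metadata = "list"))

.PAIR_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta_exp", "se_exp", "p_exp", "n_exp", "eaf_exp",
                "beta_out", "se_out", "p_out", "n_out", "eaf_out", "action")

setValidity("HarmonizedPairs", function(object) {
  if (!all(.PAIR_COLS %in% names(object@pairs)))
    return(paste("pairs missing columns:",
                 paste(setdiff(.PAIR_COLS, names(object@pairs)), collapse = ", ")))
  ok_actions <- c("kept", "sign_flipped", "freq_inferred",
                  "dropped_palindromic", "dropped_mismatch")
  if (nrow(object@pairs) && !all(object@pairs$action %in% ok_actions))
    return("unknown action code")
  TRUE
})

#' Instrument set for one protein or gene
#'
#' The harmonized instruments retained for one exposure after threshold
#' selection, optional LD clumping, and filtering, together with the
#' regional LD matrix and per-variant instrument strength (F-statistics).
#'
#' @slot id protein or gene identifier.
#' @slot pairs \linkS4class{HarmonizedPairs} of the retained instruments.
#' @slot ld \linkS4class{LDMatrix} covering (at least) the instruments.
#' @slot sourceLabel name of the originating dataset.
#' @slot fStats data.frame(variant_id, f, weak) of instrument strengths.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         representation(id = "character",
                        pairs = "HarmonizedPairs",
                        ld = "LDMatrix",
                        sourceLabel = "character",
                        fStats = "data.frame"))

setValidity("InstrumentSet", function(object) {
  v <- object@pairs@pairs$variant_id
  if (length(object@ld@variantIds) && !all(v %in% object@ld@variantIds))
    return("every instrument variant must be present in the LD matrix")
  if (nrow(object@fStats) && any(object@fStats$f < 0))
    return("all F-statistics must be >= 0")
  TRUE
})

#' Two-sample MR estimate for one exposure-outcome pair
#'
#' @slot id exposure (protein) identifier.
#' @slot outcomeId outcome identifier.
#' @slot method one of \code{"wald"}, \code{"ivw"}, \code{"egger"}.
#' @slot beta,se,pval causal estimate per SD exposure (log-OR scale for
#'   binary outcomes), its standard error and two-sided p-value.
#' @slot nInstruments number of instruments used.
#' @slot orPoint,orLow,orHigh exponentiated point estimate and 95% CI
#'   (binary outcomes; NA otherwise).
#' @slot qStat,qDf,qPval Cochran's Q heterogeneity statistic, its degrees of
#'   freedom (k - 1) and chi-square upper-tail p (NA when k < 2).
#' @slot eggerIntercept,eggerInterceptP MR-Egger intercept and its two-sided
#'   p-value (egger method only).
#' @slot status \code{"ok"}, \code{"not_computable"} or
#'   \code{"no_instruments"}.
#' @slot metadata list of provenance entries.
#' @exportClass MRResult
setClass("MRResult",
         representation(id = "character", outcomeId = "character",
                        method = "character",
                        beta = "numeric", se = "numeric", pval = "numeric",
                        nInstruments = "integer",
                        orPoint = "numeric", orLow = "numeric", orHigh = "numeric",
                        qStat = "numeric", qDf = "integer", qPval = "numeric",
                        eggerIntercept = "numeric", eggerInterceptP = "numeric",
                        status = "character", metadata = "list"))

setValidity("MRResult", function(object) {
  if (!object@method %in% c("wald", "ivw", "egger", "none"))
    return("method must be wald/ivw/egger/none")
  if (object@status == "ok") {
    if (!is.na(object@orPoint) &&
        !(object@orLow <= object@orPoint && object@orPoint <= object@orHigh))
      return("odds-ratio CI must bracket the point estimate")
    if (object@method == "ivw" && !is.na(object@qStat) &&
        object@qDf != object@nInstruments - 1L)
      return("q_df must equal n_instruments - 1 for IVW")
  }
  TRUE
})

#' Summary-data-based MR (SMR) result for one gene
#'
#' @slot geneId,tissueLabel gene and expression-dataset identifiers.
#' @slot topVariant id of the top cis-eQTL used as the instrument.
#' @slot bZx,seZx eQTL effect (SD expression per allele) and SE.
#' @slot bZy,seZy outcome effect per allele and SE.
#' @slot bSmr,seSmr,pSmr outcome effect per SD expression, delta-method SE,
#'   chi-square(1) p of the SMR statistic.
#' @slot heidiP,heidiNSnps HEIDI linkage-test p-value and the number of SNPs
#'   (top included) it used.
#' @slot status one of \code{ok}, \code{no_top_eqtl},
#'   \code{heidi_insufficient_snps}, \code{heidi_linkage}.
#' @slot metadata list.
#' @exportClass SMRResult
setClass("SMRResult",
         representation(geneId = "character", tissueLabel = "character",
                        topVariant = "character",
                        bZx = "numeric", seZx = "numeric",
                        bZy = "numeric", seZy = "numeric",
                        bSmr = "numeric", seSmr = "numeric", pSmr = "numeric",
                        heidiP = "numeric", heidiNSnps = "integer",
                        status = "character", metadata = "list"))

setValidity("SMRResult", function(object) {
  ok <- c("ok", "no_top_eqtl", "heidi_insufficient_snps", "heidi_linkage")
  if (!object@status %in% ok) return("unknown status")
  if (!is.na(object@pSmr) && (object@pSmr <= 0 || object@pSmr > 1))
    return("p_smr must lie in (0, 1]")
  if (!is.na(object@heidiP) && object@heidiNSnps < 3L)
    return("heidi_n_snps must be >= 3 when a HEIDI p-value is present")
  TRUE
})

#' Bayesian colocalization result
#'
#' Posterior probabilities of the five colocalization hypotheses for two
#' regional association signals: H0 no association, H1/H2 association with
#' one trait only, H3 distinct causal variants, H4 one shared causal
#' variant.
#'
#' @slot pph named numeric of posteriors (pph0..pph4; pph3 NA when fewer
#'   than two shared variants make H3 undefined).
#' @slot nVariants number of shared variants used.
#' @slot call \code{"colocalized"} (PPH4 > 0.8), \code{"moderate"}
#'   (0.5 < PPH4 <= 0.8) or \code{"none"}.
#' @slot status \code{"ok"} or \code{"h3_undefined"}.
#' @slot metadata list (priors used, trait ids).
#' @exportClass ColocResult
setClass("ColocResult",
         representation(pph = "numeric", nVariants = "integer",
                        call = "character", status = "character",
                        metadata = "list"))

setValidity("ColocResult", function(object) {
  pp <- object@pph
  if (!identical(names(pp), c("pph0", "pph1", "pph2", "pph3", "pph4")))
    return("pph must be named pph0..pph4")
  pv <- pp[!is.na(pp)]
  if (any(pv < -1e-12 | pv > 1 + 1e-12)) return("posteriors must lie in [0, 1]")
  if (abs(sum(pv) - 1) > 1e-12) return("posteriors must sum to 1 within 1e-12")
  expect_call <- if (is.na(pp["pph4"])) "none"
  else if (pp["pph4"] > 0.8) "colocalized"
  else if (pp["pph4"] > 0.5) "moderate" else "none"
  if (object@call != expect_call) return("call inconsistent with pph4")
  TRUE
})

#' Generative scenario for one synthetic locus
#'
#' Describes the causal architecture under which regional summary statistics
#' for a protein, a gene-expression trait and a binary outcome are
#' simulated. Supported architectures: \code{null} (instruments exist,
#' protein has no outcome effect), \code{causal}/\code{mediated} (shared
#' causal variant acting through the molecular trait), \code{linkage}
#' (distinct causal variants for molecular trait and outcome), \code{pleiotropy}
#' (one variant with a direct outcome effect beside the mediated path), and
#' \code{reverse} (an outcome-driven variant with a back-effect on the
#' protein).
#'
#' @slot name scenario name.
#' @slot m number of variants in the locus.
#' @slot rho AR(1) LD decay parameter, |rho| < 1.
#' @slot nProt,nEqtl sample sizes of the protein and expression GWAS.
#' @slot nCase,nCtrl case/control counts of the binary outcome GWAS; the
#'   effective sample size 4/(1/nCase + 1/nCtrl) sets the log-odds variance.
#' @slot theta causal effect of the protein on the outcome (log-OR per SD).
#' @slot a,e variant effect on protein / expression (SD per allele,
#'   standardized scale).
#' @slot c direct variant-outcome effect used by the linkage and pleiotropy
#'   architectures.
#' @slot causalIdx,secondIdx positions of the primary and (linkage)
#'   secondary causal variants.
#' @slot aIdx indices of protein-effect variants (defaults to causalIdx;
#'   several independent instruments can be requested for calibration
#'   studies).
#' @slot palFrac fraction of variants assigned palindromic (A/T) alleles to
#'   exercise harmonization.
#' @slot seed integer seed; identical scenarios reproduce byte-identical
#'   tables.
#' @exportClass SimScenario
setClass("SimScenario",
         representation(name = "character", m = "integer", rho = "numeric",
                        nProt = "numeric", nEqtl = "numeric",
                        nCase = "numeric", nCtrl = "numeric",
                        theta = "numeric", a = "numeric", e = "numeric",
                        c = "numeric",
                        causalIdx = "integer", secondIdx = "integer",
                        aIdx = "integer", palFrac = "numeric",
                        seed = "integer"))

setValidity("SimScenario", function(object) {
  msg <- character(0)
  if (!object@name %in% c("null", "causal", "linkage", "pleiotropy",
                          "reverse", "mediated"))
    msg <- c(msg, "unknown scenario name")
  if (object@m < 2L) msg <- c(msg, "m must be >= 2")
  if (abs(object@rho) >= 1) msg <- c(msg, "|rho| must be < 1")
  if (min(object@nProt, object@nEqtl, object@nCase + object@nCtrl) < 100)
    msg <- c(msg, "sample sizes must be >= 100")
  if (object@causalIdx < 1L || object@causalIdx > object@m)
    msg <- c(msg, "causalIdx out of range")
  if (object@name == "linkage" && object@secondIdx == object@causalIdx)
    msg <- c(msg, "secondIdx must differ from causalIdx")
  if (any(object@aIdx < 1L | object@aIdx > object@m))
    msg <- c(msg, "aIdx out of range")
  if (object@palFrac < 0 || object@palFrac > 1)
    msg <- c(msg, "palFrac must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
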