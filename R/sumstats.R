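#' @include AllClasses.R
NULL

## Row-level validation applied before a SumStats object is built.  Returns a
## character reason per row ("" = clean).  Reasons mirror the record
## invariants: positive SE, p in (0,1], eaf in [0,1], biallelic SNP alleles.
.validate_rows <- function(rec) {
  reason <- character(nrow(rec))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & reason == ""] <<- why
  }
  bad(is.na(rec$variant_id) | rec$variant_id == "", "missing_variant_id")
  bad(is.na(rec$beta) | is.na(rec$se), "missing_beta_se")
  bad(rec$se <= 0, "nonpositive_se")
  bad(!is.na(rec$pval) & (rec$pval <= 0 | rec$pval > 1), "pval_out_of_range")
  bad(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1), "eaf_out_of_range")
  snp <- rec$effect_allele %in% .BASES & rec$other_allele %in% .BASES
  bad(!snp, "indel_or_multiallelic")
  bad(snp & rec$effect_allele == rec$other_allele, "identical_alleles")
  reason
}

.empty_records <- function() {
  data.frame(variant_id = character(0), chrom = character(0),
             pos = integer(0), effect_allele = character(0),
             other_allele = character(0), eaf = numeric(0), beta = numeric(0),
             se = numeric(0), pval = numeric(0), n = numeric(0),
             ncase = numeric(0), nctrl = numeric(0),
             stringsAsFactors = FALSE)
}

.coerce_records <- function(rec) {
  for (col in setdiff(.CANONICAL_COLS, names(rec))) rec[[col]] <- NA
  rec <- rec[, .CANONICAL_COLS]
  rec$variant_id <- as.character(rec$variant_id)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "ncase", "nctrl"))
    rec[[col]] <- as.numeric(rec[[col]])
  rec
}

#' Construct a validated summary-statistics table
#'
#' Coerces a data.frame of variant associations to the canonical column set,
#' drops rows violating the record invariants (counting them in the object's
#' metadata), fills missing p-values from the two-sided normal tail of
#' beta/se, sorts by (chrom, pos) and checks p-value/z-score consistency
#' (warn-only, since many sources round p).
#'
#' @param records data.frame with at least \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}; optionally \code{eaf}, \code{pval}, \code{n}, \code{ncase},
#'   \code{nctrl}.
#' @param traitId trait name.
#' @param traitType \code{"quantitative"} or \code{"binary"}.
#' @param pvalTolerance orders of magnitude by which a supplied p-value may
#'   disagree with the normal tail of beta/se before a warning is raised.
#' @return a \linkS4class{SumStats} object.
#' @export
SumStats <- function(records, traitId, traitType = c("quantitative", "binary"),
                     pvalTolerance = 2) {
  traitType <- match.arg(traitType)
  rec <- .coerce_records(as.data.frame(records, stringsAsFactors = FALSE))
  reason <- .validate_rows(rec)
  dropped <- table(reason[reason != ""])
  rec <- rec[reason == "", , drop = FALSE]
  if (anyDuplicated(rec$variant_id)) {
    dup <- duplicated(rec$variant_id)
    dropped <- c(dropped, c(duplicate_variant_id = sum(dup)))
    rec <- rec[!dup, , drop = FALSE]
  }
  ## p from the two-sided normal tail when absent
  z <- abs(rec$beta / rec$se)
  fill <- is.na(rec$pval)
  rec$pval[fill] <- 2 * pnorm(-z[fill])
  rec$pval[rec$pval > 1] <- 1
  rec$pval[rec$pval == 0] <- .Machine$double.xmin
  ## consistency check on the supplied ones (warn-only)
  have <- !fill & z > 0 & rec$pval < 1
  if (any(have)) {
    lp_obs <- -log10(rec$pval[have])
    lp_exp <- -log10(pmax(2 * pnorm(-z[have]), .Machine$double.xmin))
    n_off <- sum(abs(lp_obs - lp_exp) > pvalTolerance)
    if (n_off > 0)
      warning(sprintf(
        "%d '%s' p-values disagree with |beta/se| by > %g orders of magnitude",
        n_off, traitId, pvalTolerance))
  }
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  new("SumStats", traitId = traitId, traitType = traitType, records = rec,
      metadata = list(n_dropped = sum(dropped),
                      drop_reasons = as.list(dropped)))
}

#' Read a column-map file
#'
#' Plain \code{key=value} text mapping canonical column names (keys) to the
#' header names used by a foreign summary-statistics file.
#'
#' @param path file path.
#' @return named character vector (canonical -> foreign).
#' @export
readColumnMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed column-map line: ", lines[bad][1])
  setNames(trimws(vapply(kv, `[`, "", 2L)), trimws(vapply(kv, `[`, "", 1L)))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated file with a header row, optionally renaming foreign
#' headers through a column map, validates each record and returns a
#' \linkS4class{SumStats}. Rows that violate the record invariants are
#' dropped and counted in the object's metadata. A missing p-value column is
#' reconstructed from the two-sided normal tail of beta/se.
#'
#' @param path file path to delimited text with a header row.
#' @param traitId trait name (defaults to the file base name).
#' @param traitType \code{"quantitative"} or \code{"binary"}.
#' @param columnMap named character vector (canonical name -> file header)
#'   or path to a \code{key=value} map file; \code{NULL} if the file already
#'   uses canonical names.
#' @param sep field separator (default tab).
#' @param ... passed to \code{\link{SumStats}}.
#' @return a \linkS4class{SumStats}.
#' @export
readSumStats <- function(path, traitId = NULL,
                         traitType = c("quantitative", "binary"),
                         columnMap = NULL, sep = "\t", ...) {
  traitType <- match.arg(traitType)
  if (is.null(traitId))
    traitId <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columnMap)) {
    if (is.character(columnMap) && length(columnMap) == 1L && file.exists(columnMap))
      columnMap <- readColumnMap(columnMap)
    for (canon in names(columnMap)) {
      foreign <- columnMap[[canon]]
      if (!foreign %in% names(tab))
        stop("column-map refers to absent column '", foreign, "'")
      names(tab)[names(tab) == foreign] <- canon
    }
  }
  missing_cols <- setdiff(.MANDATORY_COLS, names(tab))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  out <- SumStats(tab, traitId = traitId, traitType = traitType, ...)
  if (nrow(out@records) == 0L)
    stop("no valid records remain after validation of '", path, "'")
  out@metadata$source <- path
  out
}

#' Write a summary-statistics table as TSV
#'
#' Canonical tab-separated output; numeric columns are written at 10
#' significant digits so a read/write cycle is the identity up to float
#' formatting.
#'
#' @param x a \linkS4class{SumStats}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSumStats <- function(x, path) {
  stopifnot(is(x, "SumStats"))
  rec <- x@records
  for (col in c("eaf", "beta", "se", "pval", "n", "ncase", "nctrl"))
    rec[[col]] <- ifelse(is.na(rec[[col]]), NA, signif(rec[[col]], 10))
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene annotations from a BED-like TSV
#'
#' Four-or-more column table (chrom, start, end, gene_id[, symbol]).  BED
#' files use 0-based half-open intervals; set \code{zeroBasedHalfOpen=TRUE}
#' to convert to the 1-based inclusive coordinates used internally.
#'
#' @param path file path.
#' @param zeroBasedHalfOpen logical; declare BED coordinate convention.
#' @param header logical; whether the file has a header row.
#' @return data.frame(gene_id, symbol, chrom, start, end), 1-based inclusive.
#' @export
readGeneAnnotations <- function(path, zeroBasedHalfOpen = FALSE, header = FALSE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("gene annotation file needs >= 4 columns")
  names(tab)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (ncol(tab) >= 5L) names(tab)[5] <- "symbol" else tab$symbol <- tab$gene_id
  out <- data.frame(gene_id = as.character(tab$gene_id),
                    symbol = as.character(tab$symbol),
                    chrom = as.character(tab$chrom),
                    start = as.integer(tab$start), end = as.integer(tab$end),
                    stringsAsFactors = FALSE)
  if (zeroBasedHalfOpen) out$start <- out$start + 1L
  if (any(out$start > out$end)) stop("gene annotation with start > end")
  out
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome tables onto a shared effect allele
#'
#' For every variant present in both tables the outcome record is aligned to
#' the exposure's effect allele: matching allele order is kept; swapped
#' alleles flip the outcome beta sign and replace eaf by 1-eaf; palindromic
#' (A/T, C/G) variants are resolved by allele frequency when both
#' frequencies fall outside the ambiguous band around 0.5, and dropped
#' otherwise; irreconcilable allele sets are dropped as mismatches.
#'
#' @param exposure,outcome \linkS4class{SumStats} tables (the exposure is
#'   typically a cis-window subset).
#' @param palindromeWindow half-width of the ambiguous EAF band around 0.5
#'   (default 0.08, i.e. 0.42-0.58) inside which a palindromic variant's
#'   strand cannot be inferred from frequency.
#' @return a \linkS4class{HarmonizedPairs}; dropped variants are retained in
#'   the table with their \code{action} reason so the log is complete, and
#'   the aligned subset is what downstream estimators consume.
#' @export
harmonize <- function(exposure, outcome, palindromeWindow = 0.08) {
  stopifnot(is(exposure, "SumStats"), is(outcome, "SumStats"))
  ex <- exposure@records
  ou <- outcome@records
  shared <- intersect(ex$variant_id, ou$variant_id)
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  ou <- ou[match(shared, ou$variant_id), , drop = FALSE]
  n <- length(shared)
  action <- character(n)
  beta_out <- ou$beta; eaf_out <- ou$eaf
  ea_out <- ou$effect_allele; oa_out <- ou$other_allele

  same <- ea_out == ex$effect_allele & oa_out == ex$other_allele
  swap <- ea_out == ex$other_allele & oa_out == ex$effect_allele
  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)

  action[same] <- "kept"
  ## swapped non-palindromic: deterministic sign flip
  flip <- swap & !pal
  action[flip] <- "sign_flipped"
  beta_out[flip] <- -beta_out[flip]
  eaf_out[flip] <- 1 - eaf_out[flip]

  ## palindromic: letter identity cannot distinguish strand; use frequency
  pal_any <- pal & (same | swap)
  ambiguous <- function(f) is.na(f) |
    (f > 0.5 - palindromeWindow & f < 0.5 + palindromeWindow)
  amb <- pal_any & (ambiguous(ex$eaf) | ambiguous(ou$eaf))
  action[amb] <- "dropped_palindromic"
  pal_ok <- pal_any & !amb
  if (any(pal_ok)) {
    ## align letters first (swap = flip), then flip again if the
    ## frequencies disagree on which allele is the minor one
    letter_flip <- pal_ok & swap
    beta_out[letter_flip] <- -beta_out[letter_flip]
    eaf_out[letter_flip] <- 1 - eaf_out[letter_flip]
    freq_flip <- pal_ok & ((ex$eaf < 0.5) != (eaf_out < 0.5))
    beta_out[freq_flip] <- -beta_out[freq_flip]
    eaf_out[freq_flip] <- 1 - eaf_out[freq_flip]
    action[pal_ok & (letter_flip | freq_flip)] <- "freq_inferred"
    action[pal_ok & !(letter_flip | freq_flip)] <- "kept"
  }
  action[!(same | swap)] <- "dropped_mismatch"

  out <- data.frame(variant_id = shared, chrom = ex$chrom, pos = ex$pos,
                    effect_allele = ex$effect_allele,
                    other_allele = ex$other_allele,
                    beta_exp = ex$beta, se_exp = ex$se, p_exp = ex$pval,
                    n_exp = ex$n, eaf_exp = ex$eaf,
                    beta_out = beta_out, se_out = ou$se, p_out = ou$pval,
                    n_out = ou$n, eaf_out = eaf_out,
                    action = action, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  kept <- !startsWith(out$action, "dropped")
  if (!any(kept))
    warning("harmonization retained no variants for '", exposure@traitId, "'")
  new("HarmonizedPairs", pairs = out,
      metadata = list(exposure = exposure@traitId, outcome = outcome@traitId,
                      outcome_type = outcome@traitType,
                      n_shared = n, n_kept = sum(kept)))
}

#' Retained (non-dropped) subset of harmonized pairs
#'
#' @param x a \linkS4class{HarmonizedPairs}.
#' @return a \linkS4class{HarmonizedPairs} containing only aligned variants.
#' @export
keptPairs <- function(x) {
  stopifnot(is(x, "HarmonizedPairs"))
  p <- x@pairs[!startsWith(x@pairs$action, "dropped"), , drop = FALSE]
  rownames(p) <- NULL
  new("HarmonizedPairs", pairs = p, metadata = x@metadata)
}

#' Cis-window subset of a summary-statistics table
#'
#' Restricts a table to variants on the gene's chromosome within
#' \code{flank} base pairs of the gene body (start - flank to end + flank,
#' inclusive at both boundaries). The 1 Mb default encodes the usual
#' cis-QTL definition: a variant within 1 Mb of the gene encoding the
#' protein.
#'
#' @param gene one-row data.frame (or list) with \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param table a \linkS4class{SumStats}.
#' @param flank flank in base pairs (default 1e6).
#' @return a \linkS4class{SumStats} subset (possibly empty, with a warning
#'   if the chromosome is absent from the table).
#' @export
cisWindow <- function(gene, table, flank = 1e6) {
  stopifnot(is(table, "SumStats"))
  rec <- table@records
  if (!gene$chrom %in% rec$chrom) {
    warning("chromosome '", gene$chrom, "' not present in table '",
            table@traitId, "'")
    rec <- rec[0, , drop = FALSE]
  } else {
    keep <- rec$chrom == gene$chrom &
      rec$pos >= gene$start - flank & rec$pos <= gene$end + flank
    rec <- rec[keep, , drop = FALSE]
  }
  rownames(rec) <- NULL
  out <- table
  out@records <- rec
  out@metadata$cis_gene <- if (!is.null(gene$gene_id)) gene$gene_id else NA
  out
}

## Convert the exposure side (or outcome side) of harmonized pairs back into
## a SumStats table -- used by idempotence checks and by SMR/coloc, which
## consume aligned regional tables.
.pairs_to_sumstats <- function(x, side = c("exp", "out"), traitId, traitType) {
  side <- match.arg(side)
  p <- x@pairs
  rec <- data.frame(variant_id = p$variant_id, chrom = p$chrom, pos = p$pos,
                    effect_allele = p$effect_allele,
                    other_allele = p$other_allele,
                    eaf = p[[paste0("eaf_", side)]],
                    beta = p[[paste0("beta_", side)]],
                    se = p[[paste0("se_", side)]],
                    pval = p[[paste0("p_", side)]],
                    n = p[[paste0("n_", side)]],
                    ncase = NA, nctrl = NA, stringsAsFactors = FALSE)
  SumStats(rec, traitId = traitId, traitType = traitType)
}
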