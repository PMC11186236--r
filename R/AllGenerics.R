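#' @include AllClasses.R
NULL

#' Accessors for omicsMR containers
#'
#' \code{records} returns the variant table of a \linkS4class{SumStats};
#' \code{traitId}/\code{traitType} its identity; \code{variantIds} the
#' variant labels of an \linkS4class{LDMatrix} (or of any record-bearing
#' object); \code{ldMatrix} the correlation matrix itself; \code{pairsTable} the
#' aligned table inside a \linkS4class{HarmonizedPairs};
#' \code{posteriors} the named PPH vector of a \linkS4class{ColocResult}.
#'
#' @param x the object.
#' @return the underlying vector, matrix or data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("ldMatrix", function(x) standardGeneric("ldMatrix"))
#' @rdname accessors
#' @export
setGeneric("pairsTable", function(x) standardGeneric("pairsTable"))
#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' @rdname accessors
#' @export
setMethod("records", "SumStats", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("traitId", "SumStats", function(x) x@traitId)
#' @rdname accessors
#' @export
setMethod("traitType", "SumStats", function(x) x@traitType)
#' @rdname accessors
#' @export
setMethod("variantIds", "SumStats", function(x) x@records$variant_id)
#' @rdname accessors
#' @export
setMethod("variantIds", "LDMatrix", function(x) x@variantIds)
#' @rdname accessors
#' @export
setMethod("ldMatrix", "LDMatrix", function(x) x@r)
#' @rdname accessors
#' @export
setMethod("pairsTable", "HarmonizedPairs", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("pairsTable", "InstrumentSet", function(x) x@pairs@pairs)
#' @rdname accessors
#' @export
setMethod("posteriors", "ColocResult", function(x) x@pph)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats '%s' (%s): %d variants\n",
              object@traitId, object@traitType, nrow(object@records)))
  if (nrow(object@records)) {
    cat(sprintf("  chrom %s, pos %s-%s\n",
                paste(unique(object@records$chrom), collapse = ","),
                format(min(object@records$pos), big.mark = ","),
                format(max(object@records$pos), big.mark = ",")))
  }
  if (!is.null(object@metadata$n_dropped) && object@metadata$n_dropped > 0)
    cat(sprintf("  %d records dropped at validation\n", object@metadata$n_dropped))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@variantIds)))
})

setMethod("show", "HarmonizedPairs", function(object) {
  tab <- table(object@pairs$action)
  cat(sprintf("HarmonizedPairs: %d variants (%s)\n", nrow(object@pairs),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet '%s' [%s]: %d instruments, min F = %s\n",
              object@id, object@sourceLabel, nrow(object@pairs@pairs),
              if (nrow(object@fStats)) signif(min(object@fStats$f), 4) else NA))
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult %s -> %s [%s, k=%d, %s]\n", object@id, object@outcomeId,
              object@method, object@nInstruments, object@status))
  if (object@status == "ok")
    cat(sprintf("  beta = %.4g (se %.4g), p = %.3g\n",
                object@beta, object@se, object@pval))
})

setMethod("show", "SMRResult", function(object) {
  cat(sprintf("SMRResult %s [%s]: status %s\n",
              object@geneId, object@tissueLabel, object@status))
  if (!is.na(object@pSmr))
    cat(sprintf("  b_smr = %.4g, p_smr = %.3g, heidi_p = %.3g (n = %d)\n",
                object@bSmr, object@pSmr, object@heidiP, object@heidiNSnps))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult over %d variants: call '%s'\n",
              object@nVariants, object@call))
  print(round(object@pph, 4))
})

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario '%s': m=%d rho=%.2f theta=%.3g a=%.3g seed=%d\n",
    object@name, object@m, object@rho, object@theta, object@a, object@seed))
})
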