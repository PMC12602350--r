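#' @rdname accessors
#' @param x an object
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname accessors
#' @export
setGeneric("snpData", function(x) standardGeneric("snpData"))

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))

#' Accessors for TargetMR result objects
#'
#' \code{estimate}, \code{stdError} and \code{pvalue} extract the causal
#' estimate and its uncertainty from an \linkS4class{MRResult};
#' \code{nSnp} the number of SNPs behind a result; \code{snpData} the
#' per-SNP table of a \linkS4class{GwasSumstats},
#' \linkS4class{HarmonizedPair} or \linkS4class{InstrumentSet};
#' \code{posteriors} the five hypothesis posteriors of a
#' \linkS4class{ColocResult}.
#'
#' @name accessors
#' @return the corresponding slot value
NULL

setMethod("estimate", "MRResult", function(x) x@beta)
setMethod("stdError", "MRResult", function(x) x@se)
setMethod("pvalue", "MRResult", function(x) x@pval)
setMethod("nSnp", "MRResult", function(x) x@nSnp)
setMethod("nSnp", "GwasSumstats", function(x) nrow(x@snps))
setMethod("nSnp", "HarmonizedPair", function(x) nrow(x@data))
setMethod("nSnp", "InstrumentSet", function(x) nrow(x@data))
setMethod("nSnp", "ColocResult", function(x) x@nSnp)
setMethod("snpData", "GwasSumstats", function(x) x@snps)
setMethod("snpData", "HarmonizedPair", function(x) x@data)
setMethod("snpData", "InstrumentSet", function(x) x@data)
setMethod("traitName", "GwasSumstats", function(x) x@trait)
setMethod("traitName", "InstrumentSet", function(x) x@trait)
setMethod("posteriors", "ColocResult", function(x) x@pp)
setMethod("pvalue", "HeterogeneityResult", function(x) x@pval)
setMethod("pvalue", "SteigerResult", function(x) x@pval)
setMethod("pvalue", "MediationResult", function(x) x@pval)

#' @export
setMethod("as.data.frame", "GwasSumstats",
    function(x, ...) x@snps)

#' @export
setMethod("as.data.frame", "MRResult", function(x, ...) {
    data.frame(method = x@method, beta = x@beta, se = x@se,
               ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
               n_snp = x@nSnp, stringsAsFactors = FALSE)
})

setMethod("show", "GwasSumstats", function(object) {
    cat(sprintf("GwasSumstats: %s (%s), %d SNPs\n", object@trait,
                object@traitType, nrow(object@snps)))
    if (nrow(object@snps))
        print(head(object@snps, 5L), row.names = FALSE)
    if (nrow(object@snps) > 5L)
        cat(sprintf("  ... and %d more\n", nrow(object@snps) - 5L))
})

setMethod("show", "HarmonizedPair", function(object) {
    cat(sprintf("HarmonizedPair: %s -> %s, %d SNPs (%d dropped)\n",
                object@exposure, object@outcome, nrow(object@data),
                nrow(object@dropped)))
})

setMethod("show", "InstrumentSet", function(object) {
    cat(sprintf("InstrumentSet: %s, %d SNPs across %s\n", object@trait,
                nrow(object@data), paste(object@loci, collapse = " + ")))
    if (is.finite(object@minF))
        cat(sprintf("  set R2 = %.4g, min F = %.2f\n",
                    object@setR2, object@minF))
    if (length(object@cascadeLevel))
        cat(sprintf("  cascade level: %s\n",
                    paste(sprintf("%s=%.3g", names(object@cascadeLevel),
                                  object@cascadeLevel), collapse = ", ")))
})

setMethod("show", "MRResult", function(object) {
    cat(sprintf("MRResult [%s]: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, %d SNPs\n",
                object@method, object@beta, object@se, object@ciLow,
                object@ciHigh, object@pval, object@nSnp))
})

setMethod("show", "HeterogeneityResult", function(object) {
    cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n",
                object@Q, object@df, object@pval))
})

setMethod("show", "SteigerResult", function(object) {
    cat(sprintf("Steiger: r2(exposure) = %.4g, r2(outcome) = %.4g, direction %s, p = %.3g\n",
                object@r2Exposure, object@r2Outcome,
                if (object@directionCorrect) "correct" else "suspect",
                object@pval))
})

setMethod("show", "ColocResult", function(object) {
    cat(sprintf("ColocResult (%d SNPs): %s\n", object@nSnp,
                paste(sprintf("%s=%.3f", names(object@pp), object@pp),
                      collapse = " ")))
    cat(sprintf("  conditional H4 = %s, shared-variant flag (PP.H4>0.60): %s\n",
                ifelse(is.na(object@conditionalH4), "NA",
                       sprintf("%.3f", object@conditionalH4)),
                object@pp["pp_h4"] > 0.60))
})

setMethod("show", "MediationResult", function(object) {
    cat(sprintf("Mediation: total = %.4g, indirect = %.4g (se %.4g), p = %.3g\n",
                object@total, object@indirect, object@seIndirect,
                object@pval))
    if (is.na(object@proportion))
        cat(sprintf("  proportion mediated: not reported (%s)\n",
                    object@reason))
    else
        cat(sprintf("  proportion mediated = %.4g (se %.4g)\n",
                    object@proportion, object@seProportion))
})

setMethod("show", "PrevalenceResult", function(object) {
    cat(sprintf("Carrier prevalence: overall = %.4f across %d instrument sets\n",
                object@overall, nrow(object@perLocus)))
    print(object@perLocus, row.names = FALSE)
})

setMethod("show", "StudyReport", function(object) {
    cat(sprintf("StudyReport: %d result rows, %d coloc rows (seed %s)\n",
                nrow(object@results), nrow(object@coloc),
                format(object@seed)))
})
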