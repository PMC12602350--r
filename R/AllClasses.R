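#' @import methods
#' @importFrom stats pnorm qnorm pchisq qchisq pt qt dnorm rnorm runif
#'   rbinom median mad sd lm coef density setNames weighted.mean ks.test
#'   complete.cases
#' @importFrom utils read.delim write.table head
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols
NULL

.SUMSTATS_COLS <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta",
                    "se", "pval", "n")

#' GWAS summary statistics for one trait
#'
#' Per-SNP association records (identifier, position, alleles, effect-allele
#' frequency, beta, standard error, p-value, sample size) together with trait
#' metadata.  The trait is either quantitative (optionally with a known SD)
#' or case-control (with a case proportion).
#'
#' @slot snps data.frame with columns snp, chrom, pos, ea, oa, eaf, beta,
#'   se, pval, n
#' @slot trait trait name
#' @slot traitType "quantitative" or "case-control"
#' @slot sdY trait standard deviation (quantitative traits; NA when unknown)
#' @slot caseProp case proportion (case-control traits; NA otherwise)
#'
#' @export
setClass("GwasSumstats",
    representation(snps = "data.frame", trait = "character",
                   traitType = "character", sdY = "numeric",
                   caseProp = "numeric"),
    prototype(trait = "trait", traitType = "quantitative",
              sdY = NA_real_, caseProp = NA_real_))

setValidity("GwasSumstats", function(object) {
    d <- object@snps
    msg <- character(0)
    missing <- setdiff(.SUMSTATS_COLS, names(d))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(d$snp))
        msg <- c(msg, "snp identifiers must be unique")
    if (nrow(d)) {
        if (!all(d$eaf > 0 & d$eaf < 1))
            msg <- c(msg, "eaf must lie strictly in (0,1)")
        if (!all(d$se > 0))
            msg <- c(msg, "se must be > 0")
        if (!all(d$pval > 0 & d$pval <= 1))
            msg <- c(msg, "pval must lie in (0,1]")
        if (!all(d$n > 0))
            msg <- c(msg, "n must be > 0")
        if (any(d$ea == d$oa))
            msg <- c(msg, "effect and other allele must differ")
        if (!all(d$ea %in% c("A", "C", "G", "T")) ||
            !all(d$oa %in% c("A", "C", "G", "T")))
            msg <- c(msg, "alleles must be single bases A/C/G/T")
    }
    if (!object@traitType %in% c("quantitative", "case-control"))
        msg <- c(msg, "traitType must be 'quantitative' or 'case-control'")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Pairwise LD matrix
#'
#' Symmetric matrix of pairwise r-squared values with unit diagonal; SNP
#' identifiers are carried as dimnames.
#'
#' @export
setClass("LDMatrix", contains = "matrix")

setValidity("LDMatrix", function(object) {
    m <- object@.Data
    msg <- character(0)
    if (nrow(m) != ncol(m))
        return("LD matrix must be square")
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
        msg <- c(msg, "row and column names must be identical SNP ids")
    if (nrow(m)) {
        if (any(m < -1e-8 | m > 1 + 1e-8))
            msg <- c(msg, "r-squared values must lie in [0,1]")
        if (max(abs(m - t(m))) > 1e-8)
            msg <- c(msg, "matrix must be symmetric")
        if (max(abs(diag(m) - 1)) > 1e-8)
            msg <- c(msg, "diagonal must equal 1")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Exposure-outcome records harmonized to a shared effect allele
#'
#' One row per SNP with exposure (beta_x, se_x, eaf_x, n_x, pval_x) and
#' outcome (beta_y, ...) effects expressed on the same effect allele, the
#' palindromic flag and the harmonization action taken; SNPs that could not
#' be reconciled are kept in the `dropped` slot with a reason.
#'
#' @export
setClass("HarmonizedPair",
    representation(data = "data.frame", dropped = "data.frame",
                   exposure = "character", outcome = "character",
                   outcomeType = "character"),
    prototype(outcomeType = "quantitative"))

setValidity("HarmonizedPair", function(object) {
    need <- c("snp", "ea", "oa", "beta_x", "se_x", "eaf_x", "n_x", "pval_x",
              "beta_y", "se_y", "eaf_y", "n_y", "pval_y",
              "palindromic", "action")
    missing <- setdiff(need, names(object@data))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(object@data$snp))
        return("one row per SNP required")
    TRUE
})

#' Selected cis instrument SNPs with strength diagnostics
#'
#' @slot data per-SNP exposure records plus source locus, orientation flag
#'   and (after \code{strengthDiagnostics}) per-SNP F and variance explained
#' @slot loci locus (gene) names contributing SNPs
#' @slot cascadeLevel named numeric, the P-threshold actually used per locus
#' @slot r2Max clumping threshold the set was built under
#' @slot direction effect orientation ("raising", "lowering" or "none")
#' @slot setR2 total variance explained (sum of per-SNP r2)
#' @slot minF smallest per-SNP F-statistic
#' @slot trait exposure trait name
#'
#' @export
setClass("InstrumentSet",
    representation(data = "data.frame", loci = "character",
                   cascadeLevel = "numeric", r2Max = "numeric",
                   direction = "character", setR2 = "numeric",
                   minF = "numeric", trait = "character"),
    prototype(direction = "none", r2Max = 0.1, setR2 = NA_real_,
              minF = NA_real_, trait = "trait"))

setValidity("InstrumentSet", function(object) {
    need <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
              "pval", "n", "locus", "flipped")
    missing <- setdiff(need, names(object@data))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (anyDuplicated(object@data$snp))
        return("duplicated SNPs in instrument set")
    TRUE
})

#' Result of one two-sample MR estimator
#'
#' @slot method estimator label (wald, ivw_fixed, ivw_random, egger_slope,
#'   egger_intercept, weighted_median, weighted_mode, mr_lasso)
#' @slot beta causal estimate (outcome units per unit exposure)
#' @slot se standard error
#' @slot ciLow,ciHigh 95 percent confidence bounds
#' @slot pval p-value
#' @slot nSnp number of SNPs used
#' @slot notes list of method-specific details (bootstrap reps, lambda, ...)
#'
#' @export
setClass("MRResult",
    representation(method = "character", beta = "numeric", se = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                   nSnp = "integer", notes = "list"),
    prototype(notes = list()))

setValidity("MRResult", function(object) {
    if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
        (object@ciLow > object@beta || object@beta > object@ciHigh))
        return("confidence interval must bracket the estimate")
    TRUE
})

#' Cochran's Q heterogeneity test
#' @export
setClass("HeterogeneityResult",
    representation(Q = "numeric", df = "integer", pval = "numeric"))

#' Steiger directionality test
#' @export
setClass("SteigerResult",
    representation(r2Exposure = "numeric", r2Outcome = "numeric",
                   directionCorrect = "logical", pval = "numeric"))

#' Colocalization posteriors for one exposure-outcome locus pair
#'
#' Posterior probabilities for the five single-causal-variant hypotheses
#' (H0 no association, H1/H2 one trait only, H3 two distinct variants,
#' H4 one shared variant), the conditional H4 ratio H4/(H3+H4) and the
#' shared-variant flag at the 0.60 threshold.
#'
#' @export
setClass("ColocResult",
    representation(pp = "numeric", conditionalH4 = "numeric",
                   nSnp = "integer", priors = "numeric", notes = "list"),
    prototype(notes = list()))

setValidity("ColocResult", function(object) {
    if (length(object@pp) != 5L ||
        !identical(names(object@pp),
                   c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4")))
        return("pp must be named pp_h0..pp_h4")
    if (abs(sum(object@pp) - 1) > 1e-12)
        return("posterior probabilities must sum to 1")
    if (any(object@pp < -1e-15 | object@pp > 1 + 1e-15))
        return("posterior probabilities must lie in [0,1]")
    TRUE
})

#' Two-step MR mediation decomposition
#' @export
setClass("MediationResult",
    representation(total = "numeric", seTotal = "numeric",
                   step1 = "numeric", seStep1 = "numeric",
                   step2 = "numeric", seStep2 = "numeric",
                   indirect = "numeric", seIndirect = "numeric",
                   pval = "numeric", proportion = "numeric",
                   seProportion = "numeric", reason = "character"),
    prototype(reason = ""))

#' Activation-allele carrier prevalence summary
#' @export
setClass("PrevalenceResult",
    representation(perSnp = "data.frame", perLocus = "data.frame",
                   overall = "numeric"))

#' Ground truth of a synthetic GWAS simulation
#' @export
setClass("SimTruth",
    representation(theta = "numeric", betaX = "numeric", alpha = "numeric",
                   causalSnps = "character", scenario = "character",
                   seed = "numeric", config = "list"),
    prototype(scenario = "none", seed = NA_real_, config = list()))

#' Full-study report
#'
#' @slot results tidy table, one row per target x biomarker x source x
#'   outcome x method
#' @slot coloc one row per colocalized pair and locus
#' @slot log structured stage log (one record per event)
#' @slot seed seed the study ran under
#' @export
setClass("StudyReport",
    representation(results = "data.frame", coloc = "data.frame",
                   log = "data.frame", seed = "numeric"))
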