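#' Target specification for cis-instrument construction
#'
#' Bundles the target name, one or two loci, the exposure biomarker, the
#' P-value threshold cascade and the LD clumping threshold.  The default
#' cascade tries genome-wide significance (5e-8) first and falls back to
#' the relaxed 5e-6 level when a locus yields no SNPs.
#'
#' @slot name target label (e.g. "GLP1R", "GIPR", "GIPR/GLP1R")
#' @slot loci list of one or two \code{GRanges} from
#'   \code{\link{targetLocus}}
#' @slot biomarker exposure trait name (e.g. "BMI", "HbA1c")
#' @slot cascade strictly increasing P thresholds
#' @slot r2Max LD r-squared clumping threshold in (0,1)
#' @export
setClass("TargetSpec",
    representation(name = "character", loci = "list",
                   biomarker = "character", cascade = "numeric",
                   r2Max = "numeric"),
    prototype(cascade = c(5e-8, 5e-6), r2Max = 0.1))

setValidity("TargetSpec", function(object) {
    msg <- character(0)
    if (!length(object@loci) %in% 1:2)
        msg <- c(msg, "one or two loci required")
    if (is.unsorted(object@cascade, strictly = TRUE))
        msg <- c(msg, "cascade must be strictly increasing")
    if (object@r2Max <= 0 || object@r2Max >= 1)
        msg <- c(msg, "r2Max must lie in (0,1)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @rdname TargetSpec-class
#' @param name,loci,biomarker,cascade,r2Max see slots
#' @export
targetSpec <- function(name, loci, biomarker,
                       cascade = c(5e-8, 5e-6), r2Max = 0.1) {
    if (is(loci, "GRanges")) loci <- list(loci)
    new("TargetSpec", name = name, loci = loci, biomarker = biomarker,
        cascade = cascade, r2Max = r2Max)
}

# deterministic clumping order: p ascending, |z| descending, id
.clumpOrder <- function(d) order(d$pval, -abs(d$beta / d$se), d$snp)

#' Greedy LD clumping
#'
#' Sorts SNPs by p-value (ties broken by |z| descending, then id), then
#' repeatedly keeps the best remaining SNP and discards all remaining SNPs
#' with r-squared >= \code{r2Max} against it.  SNPs absent from the LD
#' matrix are dropped (reason \code{"no_ld"}).
#'
#' @param x a \linkS4class{GwasSumstats}
#' @param ld an \linkS4class{LDMatrix} covering the SNPs
#' @param r2Max exclusion threshold (kept pairs satisfy r2 < r2Max)
#' @return a \linkS4class{GwasSumstats} of kept SNPs in selection order,
#'   with attribute \code{"dropped_no_ld"}
#' @export
clumpSnps <- function(x, ld, r2Max = 0.1) {
    stopifnot(is(x, "GwasSumstats"), is(ld, "LDMatrix"))
    d <- x@snps
    inLd <- d$snp %in% rownames(ld)
    noLd <- d$snp[!inLd]
    if (length(noLd))
        message(sprintf("clumpSnps: %d SNP(s) dropped (no_ld)",
                        length(noLd)))
    d <- d[inLd, , drop = FALSE]
    d <- d[.clumpOrder(d), , drop = FALSE]
    kept <- character(0)
    remaining <- d$snp
    while (length(remaining)) {
        best <- remaining[1L]
        kept <- c(kept, best)
        r2 <- ld[best, remaining]
        remaining <- remaining[r2 < r2Max & remaining != best]
    }
    out <- initialize(x, snps = {
        k <- d[match(kept, d$snp), , drop = FALSE]
        rownames(k) <- NULL
        k
    })
    attr(out, "dropped_no_ld") <- noLd
    out
}

#' Select cis instruments at one locus
#'
#' Slices the cis window, filters at the first cascade P threshold,
#' advances to the next threshold if the window is empty at the current
#' one (logged), clumps the survivors, and attaches strength diagnostics.
#' The cascade level actually used is recorded per locus.
#'
#' @param x exposure \linkS4class{GwasSumstats} covering the window
#' @param locus a \code{GRanges} from \code{\link{targetLocus}}
#' @param ld \linkS4class{LDMatrix} for the window
#' @param cascade strictly increasing P thresholds
#'   (default \code{c(5e-8, 5e-6)})
#' @param r2Max clumping threshold
#' @return an \linkS4class{InstrumentSet}
#' @export
selectCisInstruments <- function(x, locus, ld, cascade = c(5e-8, 5e-6),
                                 r2Max = 0.1) {
    stopifnot(is(x, "GwasSumstats"))
    if (is.unsorted(cascade, strictly = TRUE))
        .stopf("cascade thresholds must be strictly increasing")
    gene <- S4Vectors::mcols(locus)$gene
    win <- sliceLocus(x, locus)
    level <- NA_real_
    for (thr in cascade) {
        if (any(win@snps$pval < thr)) { level <- thr; break }
        message(sprintf("selectCisInstruments: no SNPs at P < %g for %s; advancing cascade",
                        thr, gene))
    }
    if (is.na(level))
        .stopf("instrumentation error: no SNPs pass any cascade level at locus %s",
               gene)
    filt <- initialize(win, snps = win@snps[win@snps$pval < level, ,
                                            drop = FALSE])
    clumped <- clumpSnps(filt, ld, r2Max)
    d <- clumped@snps
    d$locus <- gene
    d$flipped <- FALSE
    set <- new("InstrumentSet", data = d, loci = gene,
               cascadeLevel = setNames(level, gene), r2Max = r2Max,
               trait = x@trait)
    strengthDiagnostics(set)
}

#' Combine two single-locus instrument sets into a dual-target set
#'
#' Concatenates the SNP lists preserving per-locus provenance and
#' recomputes set-level diagnostics on the union.  The loci must be
#' disjoint; duplicated SNP ids are an error.
#'
#' @param a,b \linkS4class{InstrumentSet}s built from the same exposure
#' @return an \linkS4class{InstrumentSet} spanning both loci
#' @export
combineTargets <- function(a, b) {
    stopifnot(is(a, "InstrumentSet"), is(b, "InstrumentSet"))
    if (!identical(a@trait, b@trait))
        .stopf("instrument sets must share the exposure trait (%s vs %s)",
               a@trait, b@trait)
    if (length(intersect(a@data$snp, b@data$snp)))
        .stopf("loci must be disjoint: duplicated SNP id(s) %s",
               paste(intersect(a@data$snp, b@data$snp), collapse = ", "))
    if (length(intersect(a@loci, b@loci)))
        .stopf("loci must be disjoint: shared locus %s",
               paste(intersect(a@loci, b@loci), collapse = ", "))
    d <- rbind(a@data, b@data)
    rownames(d) <- NULL
    direction <- if (identical(a@direction, b@direction)) a@direction
                 else "none"
    set <- new("InstrumentSet", data = d, loci = c(a@loci, b@loci),
               cascadeLevel = c(a@cascadeLevel, b@cascadeLevel),
               r2Max = max(a@r2Max, b@r2Max), direction = direction,
               trait = a@trait)
    strengthDiagnostics(set)
}

#' Orient instrument effects to model agonism
#'
#' Re-expresses every SNP on the allele giving a positive exposure effect:
#' SNPs with negative beta have their allele labels swapped, the
#' effect-allele frequency complemented and the beta negated, with the
#' flip recorded per SNP.  The reporting direction ("lowering" for
#' estimates per 1 SD biomarker decrease, mimicking agonist therapy;
#' "raising" for per 1 SD increase) is stored on the set and applied to
#' the sign of downstream causal estimates at reporting time.  Applying
#' the operation twice equals applying it once.
#'
#' @param set an \linkS4class{InstrumentSet}
#' @param direction "lowering" or "raising"
#' @return the oriented \linkS4class{InstrumentSet}
#' @export
orientToAgonism <- function(set, direction = c("lowering", "raising")) {
    stopifnot(is(set, "InstrumentSet"))
    direction <- match.arg(direction)
    d <- set@data
    flip <- d$beta < 0
    if (any(d$beta == 0))
        .warnf("%d SNP(s) with beta exactly 0 left unflipped",
               sum(d$beta == 0))
    if (any(flip)) {
        tmp <- d$ea[flip]
        d$ea[flip] <- d$oa[flip]
        d$oa[flip] <- tmp
        d$eaf[flip] <- 1 - d$eaf[flip]
        d$beta[flip] <- -d$beta[flip]
        d$flipped[flip] <- !d$flipped[flip]
    }
    initialize(set, data = d, direction = direction)
}

#' Instrument strength diagnostics
#'
#' Per-SNP F-statistic \eqn{F_j = (\beta_j/\sigma_j)^2} and variance
#' explained \eqn{r^2_j = F_j / (F_j + n - 2)}; the set-level R-squared
#' sums the per-SNP values (SNPs treated as independent after clumping)
#' and any SNP with F < 10 is flagged as weak.
#'
#' @param set an \linkS4class{InstrumentSet}
#' @param n sample size; defaults to the per-SNP \code{n} column
#' @return the set with \code{F}, \code{r2} and \code{weak} columns and
#'   set-level \code{setR2} / \code{minF} filled in
#' @export
strengthDiagnostics <- function(set, n = NULL) {
    stopifnot(is(set, "InstrumentSet"))
    d <- set@data
    nn <- if (is.null(n)) d$n else rep_len(n, nrow(d))
    if (any(nn <= 2)) .stopf("sample size must exceed 2")
    d$F <- (d$beta / d$se)^2
    d$r2 <- d$F / (d$F + nn - 2)
    d$weak <- d$F < 10
    if (any(d$weak))
        message(sprintf("strengthDiagnostics: %d SNP(s) with F < 10",
                        sum(d$weak)))
    initialize(set, data = d,
               setR2 = sum(d$r2), minF = if (nrow(d)) min(d$F) else NA_real_)
}

#' Build an instrument set from a user-supplied SNP list
#'
#' Sensitivity instruments (missense SNPs, eQTL-based SNP lists) bypass
#' the P-threshold/LD cascade but still receive orientation and strength
#' diagnostics.
#'
#' @param x exposure \linkS4class{GwasSumstats}
#' @param snps character vector of SNP ids to extract
#' @param locusName label recorded as the source locus
#' @return an \linkS4class{InstrumentSet}
#' @export
instrumentFromSnps <- function(x, snps, locusName = "custom") {
    stopifnot(is(x, "GwasSumstats"))
    hit <- x@snps$snp %in% snps
    if (!any(hit))
        .stopf("none of the requested SNPs are present in the table")
    miss <- setdiff(snps, x@snps$snp)
    if (length(miss))
        message(sprintf("instrumentFromSnps: %d SNP(s) not found", length(miss)))
    d <- x@snps[hit, , drop = FALSE]
    rownames(d) <- NULL
    d$locus <- locusName
    d$flipped <- FALSE
    strengthDiagnostics(new("InstrumentSet", data = d, loci = locusName,
                            cascadeLevel = setNames(NA_real_, locusName),
                            r2Max = 1 - 1e-9, trait = x@trait))
}

#' Build instruments for a full target specification
#'
#' Runs \code{\link{selectCisInstruments}} per locus (clumping within
#' each locus) and concatenates multi-locus targets with
#' \code{\link{combineTargets}}.
#'
#' @param x exposure \linkS4class{GwasSumstats}
#' @param spec a \linkS4class{TargetSpec}
#' @param ld an \linkS4class{LDMatrix} or a list of one per locus
#' @param direction orientation passed to \code{\link{orientToAgonism}}
#' @return an \linkS4class{InstrumentSet}
#' @export
buildInstruments <- function(x, spec, ld,
                             direction = c("lowering", "raising")) {
    stopifnot(is(spec, "TargetSpec"))
    direction <- match.arg(direction)
    if (is(ld, "LDMatrix")) ld <- rep(list(ld), length(spec@loci))
    sets <- mapply(function(locus, ldm)
        selectCisInstruments(x, locus, ldm, spec@cascade, spec@r2Max),
        spec@loci, ld, SIMPLIFY = FALSE)
    set <- Reduce(combineTargets, sets)
    orientToAgonism(set, direction)
}

#' Serialize an instrument set to TSV
#' @param x an \linkS4class{InstrumentSet}
#' @param path output file
#' @export
writeInstruments <- function(x, path) {
    stopifnot(is(x, "InstrumentSet"))
    write.table(x@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
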