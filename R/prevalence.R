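# Activation-allele carrier prevalence under Hardy-Weinberg equilibrium.

#' Per-SNP carrier probability
#'
#' Probability that an individual carries at least one copy of the effect
#' allele under Hardy-Weinberg equilibrium:
#' \eqn{P_{carrier} = 1 - (1-f)^2}.
#'
#' @param f effect-allele frequency (vectorized), each in [0,1]
#' @return carrier probabilities
#' @export
snpCarrierProb <- function(f) {
    if (any(is.na(f)) || any(f < 0 | f > 1))
        .stopf("allele frequency must lie in [0,1]")
    1 - (1 - f)^2
}

#' Locus-level carrier probability
#'
#' Probability of carrying at least one activation allele across a set of
#' independent (clumped) instrument SNPs:
#' \eqn{P_{locus} = 1 - \prod_i (1-f_i)^2}.
#'
#' @param fs effect-allele frequencies of the instrument SNPs
#' @return a probability
#' @export
locusCarrierProb <- function(fs) {
    if (!length(fs)) .stopf("empty frequency list")
    if (any(is.na(fs)) || any(fs < 0 | fs > 1))
        .stopf("allele frequencies must lie in [0,1]")
    1 - prod((1 - fs)^2)
}

#' Ancestry-level carrier prevalence across instrument sets
#'
#' Computes per-SNP carrier probabilities, combines them into per-locus
#' estimates and averages the locus estimates into an overall
#' ancestry-specific prevalence, together with the average effect-allele
#' frequency per set.  When an LD matrix is supplied, a warning is
#' emitted if any within-set pairwise r-squared exceeds \code{r2Max}
#' (the independence assumption behind the product formula).
#'
#' @param sets named list; each element a numeric vector of
#'   effect-allele frequencies or an \linkS4class{InstrumentSet}
#' @param ld optional \linkS4class{LDMatrix} for the independence check
#' @param r2Max threshold for the residual-LD warning (default 0.1)
#' @return a \linkS4class{PrevalenceResult}
#' @export
ancestrySummary <- function(sets, ld = NULL, r2Max = 0.1) {
    if (!length(sets)) .stopf("at least one instrument set required")
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    perSnp <- do.call(rbind, lapply(names(sets), function(nm) {
        s <- sets[[nm]]
        if (is(s, "InstrumentSet")) {
            fs <- s@data$eaf
            ids <- s@data$snp
        } else {
            fs <- as.numeric(s)
            ids <- if (!is.null(names(s))) names(s)
                   else paste0(nm, "_snp", seq_along(fs))
        }
        if (!is.null(ld)) {
            present <- ids[ids %in% rownames(ld)]
            if (length(present) > 1L) {
                sub <- ld[present, present, drop = FALSE]
                mx <- max(sub[upper.tri(sub)])
                if (mx >= r2Max)
                    .warnf("set %s: max pairwise r2 = %.3f exceeds %.2f; independence assumption strained",
                           nm, mx, r2Max)
            }
        }
        data.frame(set = nm, snp = ids, eaf = fs,
                   p_carrier = snpCarrierProb(fs),
                   stringsAsFactors = FALSE)
    }))
    perLocus <- do.call(rbind, lapply(names(sets), function(nm) {
        fs <- perSnp$eaf[perSnp$set == nm]
        data.frame(set = nm, n_snp = length(fs), mean_eaf = mean(fs),
                   p_locus = locusCarrierProb(fs), stringsAsFactors = FALSE)
    }))
    new("PrevalenceResult", perSnp = perSnp, perLocus = perLocus,
        overall = mean(perLocus$p_locus))
}
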