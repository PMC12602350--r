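# Single-causal-variant Bayesian colocalization via approximate Bayes
# factors, computed in log space for numerical stability.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (p1),
#' trait 2 only (p2) and both traits (p12).  Defaults are the method's
#' conventional values.
#'
#' @param p1,p2,p12 per-SNP prior probabilities
#' @return named numeric vector
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
    pr <- c(p1 = p1, p2 = p2, p12 = p12)
    if (any(pr <= 0 | pr >= 1))
        .stopf("priors must lie strictly in (0,1)")
    if (p12 > min(p1, p2))
        .stopf("p12 must not exceed min(p1, p2)")
    pr
}

#' Estimate a quantitative trait's SD from summary statistics
#'
#' For a unit-variance trait \eqn{1/\sigma_j^2 \approx 2 f_j (1-f_j)
#' n_j / sd_Y^2}, so the reciprocal of the slope of the through-origin
#' regression of \eqn{1/\sigma^2} on \eqn{2f(1-f)n} estimates
#' \eqn{sd_Y^2}.
#'
#' @param x a \linkS4class{GwasSumstats} with frequencies and sample sizes
#' @return estimated sdY
#' @export
estimateSdY <- function(x) {
    d <- if (is(x, "GwasSumstats")) x@snps else as.data.frame(x)
    ok <- !is.na(d$eaf) & !is.na(d$n)
    if (sum(ok) < 2L) .stopf("cannot estimate sdY: need eaf and n")
    oneover <- 1 / d$se[ok]^2
    nvx <- 2 * d$eaf[ok] * (1 - d$eaf[ok]) * d$n[ok]
    slope <- coef(lm(oneover ~ 0 + nvx))[[1]]
    if (slope <= 0) .stopf("cannot estimate sdY: non-positive slope")
    sqrt(1 / slope)
}

#' Per-SNP log approximate Bayes factors
#'
#' For each SNP with \eqn{z = \hat\beta/\sigma} and \eqn{V = \sigma^2},
#' the Wakefield approximate Bayes factor against the null uses a normal
#' prior with SD \eqn{W^{1/2}} on the true effect: with shrinkage
#' \eqn{r = W/(W+V)}, \eqn{\log ABF = \frac12(\log(1-r) + r z^2)}.  The
#' prior effect SD defaults to \eqn{0.15\, sd_Y} for quantitative traits
#' (sdY taken from the object, or estimated from frequencies and sample
#' sizes when unknown and flagged in the attributes) and 0.2 on the
#' log-odds scale for case-control traits.
#'
#' @param x a \linkS4class{GwasSumstats}
#' @param wScale prior effect-SD multiplier; default 0.15 (quantitative,
#'   times sdY) or 0.2 (case-control)
#' @param sdY override for the trait SD
#' @return named numeric vector of log-ABFs (attribute
#'   \code{"sdY_estimated"} marks an estimated sdY)
#' @export
labfPerSnp <- function(x, wScale = NULL, sdY = NULL) {
    stopifnot(is(x, "GwasSumstats"))
    d <- x@snps
    if (!all(d$se > 0)) .stopf("labfPerSnp requires se > 0")
    estimated <- FALSE
    if (x@traitType == "quantitative") {
        if (is.null(sdY)) sdY <- x@sdY
        if (is.na(sdY)) {
            sdY <- estimateSdY(x)
            estimated <- TRUE
            message(sprintf("labfPerSnp: sdY estimated as %.4g", sdY))
        }
        wSd <- (if (is.null(wScale)) 0.15 else wScale) * sdY
    } else {
        wSd <- if (is.null(wScale)) 0.2 else wScale
    }
    W <- wSd^2
    V <- d$se^2
    r <- W / (W + V)
    labf <- 0.5 * (log1p(-r) + r * (d$beta / d$se)^2)
    names(labf) <- d$snp
    attr(labf, "sdY_estimated") <- estimated
    labf
}

#' Colocalization posteriors from per-SNP log-ABFs
#'
#' Combines two traits' per-SNP log approximate Bayes factors (identical
#' SNP ordering) into posterior probabilities of the five
#' single-causal-variant hypotheses, in log space:
#' \eqn{l_1 = \log\sum_j ABF_{1j}}, \eqn{l_2} likewise,
#' \eqn{l_{12} = \log\sum_j ABF_{1j}ABF_{2j}}; then H0 = 1,
#' H1 = p1 e^{l_1}, H2 = p2 e^{l_2},
#' H3 = p1 p2 (e^{l_1 + l_2} - e^{l_{12}}), H4 = p12 e^{l_{12}},
#' normalized to sum to one.  A single-SNP locus has an empty
#' off-diagonal sum, hence pp_h3 = 0.
#'
#' @param labfX,labfY numeric log-ABF vectors in the same SNP order
#' @param priors from \code{\link{colocPriors}}
#' @return a \linkS4class{ColocResult}
#' @export
colocPosteriors <- function(labfX, labfY, priors = colocPriors()) {
    if (length(labfX) != length(labfY))
        .stopf("log-ABF vectors must have equal length")
    if (!length(labfX)) .stopf("empty locus")
    if (!is.null(names(labfX)) && !is.null(names(labfY)) &&
        !identical(names(labfX), names(labfY)))
        .stopf("SNP ordering differs between traits; harmonize the locus first")
    l1 <- .logsumexp(labfX)
    l2 <- .logsumexp(labfY)
    l12 <- .logsumexp(labfX + labfY)
    lh <- c(h0 = 0,
            h1 = log(priors[["p1"]]) + l1,
            h2 = log(priors[["p2"]]) + l2,
            h3 = if (length(labfX) == 1L) -Inf
                 else log(priors[["p1"]]) + log(priors[["p2"]]) +
                      .logdiffexp(l1 + l2, l12),
            h4 = log(priors[["p12"]]) + l12)
    denom <- .logsumexp(lh)
    pp <- exp(lh - denom)
    pp <- pp / sum(pp)
    names(pp) <- paste0("pp_", names(lh))
    ch4 <- if (pp[["pp_h3"]] + pp[["pp_h4"]] > 0)
        pp[["pp_h4"]] / (pp[["pp_h3"]] + pp[["pp_h4"]])
    else NA_real_
    new("ColocResult", pp = pp, conditionalH4 = ch4,
        nSnp = length(labfX), priors = priors)
}

#' Conditional H4 ratio
#'
#' \eqn{PP.H4 / (PP.H3 + PP.H4)} — the posterior probability of a shared
#' variant conditional on both traits being associated at the locus,
#' useful when the outcome signal is weak (high H1).  Missing (with a
#' warning) when the denominator is 0.
#'
#' @param result a \linkS4class{ColocResult}
#' @return a probability, or NA
#' @export
conditionalH4 <- function(result) {
    stopifnot(is(result, "ColocResult"))
    denom <- result@pp[["pp_h3"]] + result@pp[["pp_h4"]]
    if (denom == 0) {
        .warnf("conditional H4 undefined: pp_h3 + pp_h4 = 0")
        return(NA_real_)
    }
    result@pp[["pp_h4"]] / denom
}

#' Colocalize two traits at a locus
#'
#' Aligns the two summary tables on their shared SNPs (by id, position
#' order) and runs the approximate-Bayes-factor colocalization.
#'
#' @param x,y \linkS4class{GwasSumstats} for the two traits
#' @param priors from \code{\link{colocPriors}}
#' @param wScaleX,wScaleY optional prior effect-SD multipliers per trait
#' @return a \linkS4class{ColocResult}
#' @export
runColoc <- function(x, y, priors = colocPriors(), wScaleX = NULL,
                     wScaleY = NULL) {
    stopifnot(is(x, "GwasSumstats"), is(y, "GwasSumstats"))
    shared <- intersect(x@snps$snp, y@snps$snp)
    if (!length(shared)) .stopf("no shared SNPs at the locus")
    xs <- x@snps[match(shared, x@snps$snp), ]
    shared <- shared[order(xs$pos, shared)]
    subTab <- function(t) initialize(t, snps = {
        d <- t@snps[match(shared, t@snps$snp), , drop = FALSE]
        rownames(d) <- NULL
        d
    })
    labfX <- labfPerSnp(subTab(x), wScale = wScaleX)
    labfY <- labfPerSnp(subTab(y), wScale = wScaleY)
    res <- colocPosteriors(labfX, labfY, priors)
    res@notes <- list(sdY_estimated_x = attr(labfX, "sdY_estimated"),
                      sdY_estimated_y = attr(labfY, "sdY_estimated"))
    res
}
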