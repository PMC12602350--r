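#' Two-step MR mediation by the product of coefficients
#'
#' Decomposes a total genetically proxied effect of an exposure on an
#' outcome into the component transmitted through a mediator:
#' indirect = \eqn{\beta_1 \beta_2} (exposure-to-mediator times
#' mediator-to-outcome), with the Sobel-type standard error
#' \eqn{\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}} under two-sample
#' independence, and proportion mediated = indirect / total with a
#' first-order delta-method SE treating the total as independent.
#'
#' The proportion is reported as missing (with the reason) when the
#' indirect and total effects disagree in sign or when the total is too
#' imprecise (\eqn{|total| < zTotalMin \cdot se_{total}}), since the
#' ratio is then unstable; a zero step-1 or step-2 coefficient yields
#' proportion 0.
#'
#' @param total,step1,step2 \linkS4class{MRResult}s (or lists with
#'   \code{beta} and \code{se}) for exposure-outcome, exposure-mediator
#'   and mediator-outcome
#' @param zTotalMin suppression threshold on \eqn{|total|/se_{total}}
#'   (default 10; deliberately conservative)
#' @param scales optional character vector of the three effect scales
#'   (e.g. "log_odds"); a mismatch is a configuration error
#' @return a \linkS4class{MediationResult}
#' @export
mediate <- function(total, step1, step2, zTotalMin = 10, scales = NULL) {
    pick <- function(x) {
        if (is(x, "MRResult")) list(beta = x@beta, se = x@se)
        else list(beta = x$beta, se = x$se)
    }
    if (!is.null(scales) && length(unique(scales)) > 1L)
        .stopf("configuration error: mediation inputs on mismatched scales (%s)",
               paste(scales, collapse = ", "))
    tt <- pick(total); s1 <- pick(step1); s2 <- pick(step2)
    indirect <- s1$beta * s2$beta
    seInd <- sqrt(s1$beta^2 * s2$se^2 + s2$beta^2 * s1$se^2)
    pval <- if (seInd > 0) .zToP(indirect / seInd)
            else if (indirect == 0) 1 else 0
    prop <- NA_real_; seProp <- NA_real_; reason <- ""
    if (tt$beta == 0) {
        reason <- "zero_total"
    } else if (indirect == 0) {
        prop <- 0; seProp <- seInd / abs(tt$beta)
    } else if (sign(indirect) != sign(tt$beta)) {
        reason <- "sign_conflict"
    } else if (abs(tt$beta) < zTotalMin * tt$se) {
        reason <- "weak_total"
    } else {
        prop <- indirect / tt$beta
        seProp <- sqrt(seInd^2 / tt$beta^2 +
                       indirect^2 * tt$se^2 / tt$beta^4)
    }
    new("MediationResult", total = tt$beta, seTotal = tt$se,
        step1 = s1$beta, seStep1 = s1$se, step2 = s2$beta,
        seStep2 = s2$se, indirect = indirect, seIndirect = seInd,
        pval = pval, proportion = prop, seProportion = seProp,
        reason = reason)
}

#' Serialize a mediation result to a one-row data.frame
#' @param x a \linkS4class{MediationResult}
#' @export
mediationTable <- function(x) {
    stopifnot(is(x, "MediationResult"))
    data.frame(total = x@total, se_total = x@seTotal, step1 = x@step1,
               se_step1 = x@seStep1, step2 = x@step2,
               se_step2 = x@seStep2, indirect = x@indirect,
               se_indirect = x@seIndirect, pval = x@pval,
               proportion_mediated = x@proportion,
               se_proportion = x@seProportion,
               suppressed_reason = x@reason, stringsAsFactors = FALSE)
}
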