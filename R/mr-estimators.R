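# Two-sample MR estimators and diagnostics.  All operate on a
# HarmonizedPair (exposure and outcome effects on a shared effect allele),
# optionally restricted to an InstrumentSet.

.hpData <- function(tab) {
    if (is(tab, "HarmonizedPair")) tab@data
    else as.data.frame(tab)
}

.mrResult <- function(method, beta, se, nSnp, notes = list(),
                      ciMult = 1.96, pval = NULL) {
    ciLow <- beta - ciMult * se
    ciHigh <- beta + ciMult * se
    if (is.null(pval)) pval <- .zToP(beta / se)
    new("MRResult", method = method, beta = beta, se = se, ciLow = ciLow,
        ciHigh = ciHigh, pval = pval, nSnp = as.integer(nSnp),
        notes = notes)
}

#' Restrict a harmonized pair to an instrument set
#'
#' @param pair a \linkS4class{HarmonizedPair}
#' @param set an \linkS4class{InstrumentSet}
#' @return the pair restricted to (and ordered as) the instrument SNPs
#' @export
restrictToInstruments <- function(pair, set) {
    stopifnot(is(pair, "HarmonizedPair"), is(set, "InstrumentSet"))
    keep <- set@data$snp[set@data$snp %in% pair@data$snp]
    d <- pair@data[match(keep, pair@data$snp), , drop = FALSE]
    rownames(d) <- NULL
    initialize(pair, data = d)
}

#' Wald ratio estimate from a single SNP
#'
#' \eqn{\hat\theta = \beta_Y / \beta_X} with first-order standard error
#' \eqn{\sigma_Y / |\beta_X|}; 95\% CI from the normal 1.96 multiplier.
#'
#' @param tab a \linkS4class{HarmonizedPair} (or data.frame) with exactly
#'   one SNP
#' @return an \linkS4class{MRResult} with method "wald"
#' @export
waldRatio <- function(tab) {
    d <- .hpData(tab)
    if (nrow(d) != 1L)
        .stopf("waldRatio requires exactly one SNP (got %d)", nrow(d))
    if (d$beta_x == 0)
        .stopf("undefined ratio: exposure beta is exactly 0")
    theta <- d$beta_y / d$beta_x
    se <- d$se_y / abs(d$beta_x)
    .mrResult("wald", theta, se, 1L, notes = list(snp = d$snp))
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights \eqn{1/\sigma_{Yj}^2}:
#' \eqn{\hat\theta = \sum \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2} /
#'   \sum \beta_{Xj}^2 \sigma_{Yj}^{-2}}.  The fixed-effect standard error
#' is \eqn{(\sum \beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}}; the multiplicative
#' random-effects model inflates it by \eqn{\max(1, \sqrt{Q/(n-1)})}.
#' The default picks fixed effects below 4 SNPs and random effects from 4.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 2 SNPs
#' @param effectsModel "auto", "fixed" or "random_multiplicative"
#' @return an \linkS4class{MRResult}
#' @export
mrIVW <- function(tab, effectsModel = c("auto", "fixed",
                                        "random_multiplicative")) {
    effectsModel <- match.arg(effectsModel)
    d <- .hpData(tab)
    if (nrow(d) < 2L)
        .stopf("mrIVW requires >= 2 SNPs; use waldRatio for single-SNP instruments")
    if (effectsModel == "auto")
        effectsModel <- if (nrow(d) < 4L) "fixed" else "random_multiplicative"
    w <- 1 / d$se_y^2
    denom <- sum(d$beta_x^2 * w)
    theta <- sum(d$beta_x * d$beta_y * w) / denom
    se <- 1 / sqrt(denom)
    wq <- (d$beta_x / d$se_y)^2
    Q <- sum(wq * (d$beta_y / d$beta_x - theta)^2)
    if (effectsModel == "random_multiplicative")
        se <- se * max(1, sqrt(Q / (nrow(d) - 1)))
    .mrResult(if (effectsModel == "fixed") "ivw_fixed" else "ivw_random",
              theta, se, nrow(d),
              notes = list(effects_model = effectsModel, Q = Q))
}

#' MR-Egger regression
#'
#' Weighted least squares \eqn{\beta_{Yj} = \alpha + \theta\,\beta_{Xj}}
#' with weights \eqn{1/\sigma_{Yj}^2} after orienting every SNP so
#' \eqn{\beta_{Xj} \ge 0} (flipping exposure and outcome effects jointly).
#' The intercept estimates directional pleiotropy.  Standard errors are
#' inflated by \eqn{\max(1, \sqrt{Q_{res}/(n-2)})} and confidence
#' intervals use t-quantiles with n - 2 degrees of freedom.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 3 SNPs
#' @return list with \code{slope} and \code{intercept}
#'   \linkS4class{MRResult}s
#' @export
mrEgger <- function(tab) {
    d <- .hpData(tab)
    n <- nrow(d)
    if (n < 3L)
        .stopf("MR-Egger unavailable: requires >= 3 SNPs (got %d)", n)
    sgn <- ifelse(d$beta_x < 0, -1, 1)
    bx <- d$beta_x * sgn
    by <- d$beta_y * sgn
    w <- 1 / d$se_y^2
    X <- cbind(1, bx)
    XtWX <- crossprod(X, w * X)
    XtWy <- crossprod(X, w * by)
    est <- solve(XtWX, XtWy)
    resid <- by - X %*% est
    Qres <- sum(w * resid^2)
    phi <- max(1, Qres / (n - 2))
    covb <- phi * solve(XtWX)
    seI <- sqrt(covb[1, 1]); seS <- sqrt(covb[2, 2])
    tMult <- qt(0.975, df = n - 2)
    pS <- 2 * pt(-abs(est[2] / seS), df = n - 2)
    pI <- 2 * pt(-abs(est[1] / seI), df = n - 2)
    list(slope = .mrResult("egger_slope", est[2], seS, n,
                           notes = list(residual_Q = Qres),
                           ciMult = tMult, pval = pS),
         intercept = .mrResult("egger_intercept", est[1], seI, n,
                               notes = list(residual_Q = Qres),
                               ciMult = tMult, pval = pI))
}

# per-SNP ratio estimates and normalized ratio weights (bx/sy)^2
.ratioWeights <- function(d) {
    list(theta = d$beta_y / d$beta_x,
         w = {
             w <- (d$beta_x / d$se_y)^2
             w / sum(w)
         })
}

.weightedMedianEstimate <- function(theta, w) {
    ord <- order(theta)
    theta <- theta[ord]; w <- w[ord]
    p <- cumsum(w) - w / 2
    if (0.5 <= p[1]) return(theta[1])
    if (0.5 >= p[length(p)]) return(theta[length(theta)])
    stats::approx(p, theta, xout = 0.5, ties = "ordered")$y
}

.weightedModeEstimate <- function(theta, w, bandwidthFactor) {
    s <- mad(theta)                      # 1.4826 * MAD
    if (s == 0) s <- sd(theta)
    if (is.na(s) || s == 0) return(theta[1])   # degenerate cluster
    h <- bandwidthFactor * s * length(theta)^(-1 / 5)
    grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512L)
    dens <- colSums(w * outer(theta, grid, function(t, x)
        dnorm((x - t) / h)))
    grid[which.max(dens)]
}

# parametric bootstrap over the sampling distributions of the per-SNP
# effects; returns the SD of the re-estimates
.ratioBootstrapSE <- function(d, estimator, bootReps, seed) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    n <- nrow(d)
    ests <- vapply(seq_len(bootReps), function(i) {
        bx <- rnorm(n, d$beta_x, d$se_x)
        by <- rnorm(n, d$beta_y, d$se_y)
        bx[bx == 0] <- .Machine$double.eps
        w <- (bx / d$se_y)^2
        estimator(by / bx, w / sum(w))
    }, numeric(1))
    sd(ests)
}

#' Weighted median estimator
#'
#' Pleiotropy-robust estimator consistent when valid instruments carry at
#' least half the weight.  Per-SNP ratios are weighted by
#' \eqn{(\beta_{Xj}/\sigma_{Yj})^2} (normalized), sorted, and the
#' estimate interpolates the cumulative weight midpoints at 0.5.  The
#' standard error comes from a seeded parametric bootstrap of the summary
#' statistics.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 3 SNPs
#' @param bootReps bootstrap resamples (default 1000)
#' @param seed bootstrap seed (recorded in the notes)
#' @return an \linkS4class{MRResult}
#' @export
mrWeightedMedian <- function(tab, bootReps = 1000L, seed = 1L) {
    d <- .hpData(tab)
    if (nrow(d) < 3L)
        .stopf("weighted median unavailable: requires >= 3 SNPs")
    rw <- .ratioWeights(d)
    est <- .weightedMedianEstimate(rw$theta, rw$w)
    se <- .ratioBootstrapSE(d, .weightedMedianEstimate, bootReps, seed)
    .mrResult("weighted_median", est, se, nrow(d),
              notes = list(boot_reps = bootReps, seed = seed))
}

#' Weighted mode estimator
#'
#' Consistent when the largest group of instruments sharing one ratio
#' (the plurality) is valid.  A Gaussian kernel density over the per-SNP
#' ratios with weights \eqn{(\beta_{Xj}/\sigma_{Yj})^2} and bandwidth
#' \eqn{h = \phi\, s\, n^{-1/5}} (s the MAD-based robust scale, falling
#' back to the SD when the MAD is 0) is maximised; when all ratios are
#' identical their common value is returned.  SE by the same parametric
#' bootstrap as \code{\link{mrWeightedMedian}}.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 3 SNPs
#' @param bandwidthFactor multiplier \eqn{\phi} on the default bandwidth
#' @param bootReps,seed bootstrap settings
#' @return an \linkS4class{MRResult}
#' @export
mrWeightedMode <- function(tab, bandwidthFactor = 1, bootReps = 1000L,
                           seed = 1L) {
    d <- .hpData(tab)
    if (nrow(d) < 3L)
        .stopf("weighted mode unavailable: requires >= 3 SNPs")
    rw <- .ratioWeights(d)
    est <- .weightedModeEstimate(rw$theta, rw$w, bandwidthFactor)
    se <- .ratioBootstrapSE(d, function(theta, w)
        .weightedModeEstimate(theta, w, bandwidthFactor), bootReps, seed)
    .mrResult("weighted_mode", est, se, nrow(d),
              notes = list(bandwidth_factor = bandwidthFactor,
                           boot_reps = bootReps, seed = seed))
}

.softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' MR-LASSO estimator
#'
#' Models \eqn{\beta_{Yj} = \alpha_j + \theta\,\beta_{Xj}} with per-SNP
#' pleiotropy intercepts penalized by \eqn{\lambda \sum_j |\alpha_j|}
#' (weights \eqn{1/\sigma_{Yj}^2}).  Because each intercept enters one
#' observation, the coordinate updates are exact soft-thresholds.  The
#' solution path is traced over a decreasing log-spaced lambda grid and
#' the reported model is the largest valid set (SNPs with
#' \eqn{\hat\alpha_j = 0}) whose post-selection Cochran's Q does not
#' exceed the chi-square 0.05 critical value at its degrees of freedom;
#' the final estimate is fixed-effect IVW on that set.  When no grid
#' point satisfies the heterogeneity rule, the smallest-lambda valid set
#' with >= 2 SNPs is used and flagged in the notes.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 3 SNPs
#' @param nLambda grid size (default 50)
#' @param lambdaMinRatio smallest lambda as a fraction of
#'   \eqn{\lambda_{max}} (default 0.001)
#' @return an \linkS4class{MRResult} with method "mr_lasso"
#' @export
mrLasso <- function(tab, nLambda = 50L, lambdaMinRatio = 0.001) {
    d <- .hpData(tab)
    n <- nrow(d)
    if (n < 3L)
        .stopf("MR-LASSO unavailable: requires >= 3 SNPs")
    w <- 1 / d$se_y^2
    bx <- d$beta_x; by <- d$beta_y
    ivwTheta <- sum(bx * by * w) / sum(bx^2 * w)
    lambdaMax <- max(w * abs(by - ivwTheta * bx))
    if (lambdaMax == 0) lambdaMax <- .Machine$double.eps
    grid <- exp(seq(log(lambdaMax), log(lambdaMax * lambdaMinRatio),
                    length.out = nLambda))
    fitOne <- function(lambda) {
        theta <- ivwTheta; alpha <- numeric(n)
        for (it in seq_len(1000L)) {
            alphaNew <- .softThreshold(by - theta * bx, lambda / w)
            thetaNew <- sum(w * bx * (by - alphaNew)) / sum(w * bx^2)
            if (max(abs(alphaNew - alpha)) < 1e-12 &&
                abs(thetaNew - theta) < 1e-12) {
                theta <- thetaNew; alpha <- alphaNew; break
            }
            theta <- thetaNew; alpha <- alphaNew
        }
        alpha
    }
    best <- NULL; fallback <- NULL
    for (lambda in grid) {
        valid <- which(fitOne(lambda) == 0)
        if (length(valid) < 2L) next
        sub <- d[valid, , drop = FALSE]
        wv <- 1 / sub$se_y^2
        thetaV <- sum(sub$beta_x * sub$beta_y * wv) / sum(sub$beta_x^2 * wv)
        Qv <- sum((sub$beta_x / sub$se_y)^2 *
                  (sub$beta_y / sub$beta_x - thetaV)^2)
        cand <- list(lambda = lambda, valid = valid, Q = Qv)
        fallback <- cand
        if (Qv <= qchisq(0.95, df = length(valid) - 1L)) { best <- cand; break }
    }
    ruleMet <- !is.null(best)
    if (!ruleMet) best <- fallback
    if (is.null(best))
        .stopf("MR-LASSO unavailable: no lambda yields >= 2 valid SNPs")
    sub <- d[best$valid, , drop = FALSE]
    wv <- 1 / sub$se_y^2
    denom <- sum(sub$beta_x^2 * wv)
    theta <- sum(sub$beta_x * sub$beta_y * wv) / denom
    .mrResult("mr_lasso", theta, 1 / sqrt(denom), length(best$valid),
              notes = list(lambda = best$lambda,
                           n_excluded = n - length(best$valid),
                           excluded = d$snp[-best$valid],
                           heterogeneity_rule_met = ruleMet))
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\hat\theta_j - \hat\theta_{IVW})^2} with per-SNP
#' ratios \eqn{\hat\theta_j = \beta_{Yj}/\beta_{Xj}} and weights
#' \eqn{w_j = (\beta_{Xj}/\sigma_{Yj})^2}; the p-value is the upper tail
#' of chi-square with n - 1 degrees of freedom.
#'
#' @param tab a \linkS4class{HarmonizedPair} with >= 2 SNPs
#' @return a \linkS4class{HeterogeneityResult}
#' @export
cochranQ <- function(tab) {
    d <- .hpData(tab)
    if (nrow(d) < 2L) .stopf("cochranQ requires >= 2 SNPs")
    w <- (d$beta_x / d$se_y)^2
    theta <- sum(d$beta_x * d$beta_y / d$se_y^2) / sum(d$beta_x^2 / d$se_y^2)
    Q <- sum(w * (d$beta_y / d$beta_x - theta)^2)
    df <- nrow(d) - 1L
    new("HeterogeneityResult", Q = Q, df = df,
        pval = pchisq(Q, df, lower.tail = FALSE))
}

# per-trait variance explained from p-values and sample sizes:
# t^2 from the two-sided t quantile at p with df = n - 2,
# r2 = t^2 / (t^2 + n - 2), summed over instrument SNPs
.r2FromP <- function(p, n) {
    t2 <- qt(p / 2, df = n - 2, lower.tail = FALSE)^2
    sum(t2 / (t2 + n - 2))
}

#' MR Steiger directionality test
#'
#' Compares the instrument variance explained in the exposure against the
#' outcome; causation in the assumed direction should explain more
#' variance in the exposure.  Quantitative traits only: for case-control
#' outcomes the liability-scale conversion is out of scope and the result
#' is flagged not-computed (all fields NA).
#'
#' @param tab a \linkS4class{HarmonizedPair}
#' @return a \linkS4class{SteigerResult}
#' @export
steigerTest <- function(tab) {
    d <- .hpData(tab)
    if (is(tab, "HarmonizedPair") && tab@outcomeType == "case-control") {
        .warnf("Steiger not computed for case-control outcomes")
        return(new("SteigerResult", r2Exposure = NA_real_,
                   r2Outcome = NA_real_, directionCorrect = NA,
                   pval = NA_real_))
    }
    if (any(is.na(d$n_x)) || any(is.na(d$n_y)))
        .stopf("cannot compute Steiger test: sample sizes missing")
    r2x <- .r2FromP(d$pval_x, d$n_x)
    r2y <- .r2FromP(d$pval_y, d$n_y)
    nx <- mean(d$n_x); ny <- mean(d$n_y)
    zx <- atanh(min(sqrt(r2x), 1 - 1e-12))
    zy <- atanh(min(sqrt(r2y), 1 - 1e-12))
    z <- (zx - zy) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
    new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y,
        directionCorrect = r2x > r2y, pval = .zToP(z))
}

#' Run the estimator suite appropriate for an instrument size
#'
#' The primary estimator mirrors standard drug-target MR practice: Wald
#' ratio for single-SNP instruments, IVW for 2+ SNPs.  From 3 SNPs the
#' complementary pleiotropy-robust methods (MR-Egger, weighted median,
#' weighted mode, MR-LASSO) are added, plus Cochran's Q (2+ SNPs) and the
#' Steiger directionality test.
#'
#' @param tab a \linkS4class{HarmonizedPair}
#' @param seed seed for the bootstrap-based methods
#' @return named list of \linkS4class{MRResult}s plus \code{q}
#'   (\linkS4class{HeterogeneityResult} or NULL) and \code{steiger}
#' @export
mrSuite <- function(tab, seed = 1L) {
    d <- .hpData(tab)
    n <- nrow(d)
    if (!n) .stopf("no SNPs to analyse")
    out <- list()
    out$primary <- if (n == 1L) waldRatio(tab) else mrIVW(tab)
    if (n >= 3L) {
        egger <- tryCatch(mrEgger(tab), error = function(e) NULL)
        out$egger_slope <- egger$slope
        out$egger_intercept <- egger$intercept
        out$weighted_median <- mrWeightedMedian(tab, seed = seed)
        out$weighted_mode <- mrWeightedMode(tab, seed = seed)
        out$mr_lasso <- tryCatch(mrLasso(tab), error = function(e) NULL)
    }
    out$q <- if (n >= 2L) cochranQ(tab) else NULL
    out$steiger <- tryCatch(suppressWarnings(steigerTest(tab)),
                            error = function(e) NULL)
    out
}
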