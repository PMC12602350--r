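# Seeded generators for two-sample GWAS summary statistics with known
# ground truth.  All quantities are on the standardized (unit-variance)
# trait scale; per-SNP sampling SEs follow sigma_j = 1/sqrt(2 n f_j (1-f_j))
# for quantitative traits and 1/sqrt(2 n s (1-s) f_j (1-f_j)) on the
# log-odds scale for case-control traits (an approximation adequate for
# method testing).

# allele pairs excluding palindromes so harmonization is unambiguous
.ALLELE_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                       c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulation configuration
#'
#' Defaults emulate the scale of the biomarker GWAS the pipeline is built
#' for: cis windows with tens of SNPs, exposure cohorts of hundreds of
#' thousands, and per-allele causal effects around 0.02 SD, which put
#' instrument F-statistics in the tens-to-hundreds range typical of
#' published cis instruments.
#'
#' @param nSnp SNPs per locus
#' @param eafRange uniform bounds of the effect-allele frequency draw
#' @param ldModel "block" (block-constant correlation rho, positive
#'   definite by construction) or "ar1" (rho^|i-j|)
#' @param ldRho within-block genotype correlation
#' @param ldBlockSize SNPs per LD block ("block" model)
#' @param nX,nY exposure and outcome GWAS sample sizes (non-overlapping
#'   cohorts)
#' @param theta true causal effect of exposure on outcome
#' @param nCausal causal SNPs per locus
#' @param causalBeta base magnitude of per-allele causal exposure effects
#'   (SD units); magnitudes are drawn uniformly in [0.5, 1.5] times this,
#'   with random sign
#' @param invalidFraction fraction of causal SNPs given a direct
#'   (pleiotropic) outcome effect
#' @param pleiotropy "balanced" (mean-zero alpha) or "directional"
#' @param alphaMean,alphaSd pleiotropic effect distribution
#' @param outcomeType "quantitative" or "case-control"
#' @param caseProp case proportion for case-control outcomes
#' @param noiseScale multiplier on sampling noise; 0 is the noise-free
#'   diagnostic mode (estimates equal their expectations, SEs unchanged)
#' @param chrom,posStart,posEnd genomic coordinates assigned to the
#'   simulated SNPs (defaults inside the GLP1R cis window)
#' @param seed RNG seed recorded in the emitted truth
#' @return a list of class "SimConfig"
#' @export
simConfig <- function(nSnp = 30L, eafRange = c(0.05, 0.95),
                      ldModel = c("block", "ar1"), ldRho = 0.5,
                      ldBlockSize = 5L, nX = 3e5, nY = 5e5, theta = 0.3,
                      nCausal = 5L, causalBeta = 0.02,
                      invalidFraction = 0,
                      pleiotropy = c("balanced", "directional"),
                      alphaMean = 0.02, alphaSd = 0.01,
                      outcomeType = c("quantitative", "case-control"),
                      caseProp = 0.1, noiseScale = 1, chrom = "6",
                      posStart = 39016574L, posEnd = 39055519L,
                      seed = NULL) {
    stopifnot(nSnp >= 1, nX > 0, nY > 0, nCausal >= 1, nCausal <= nSnp,
              invalidFraction >= 0, invalidFraction <= 1,
              ldRho >= 0, ldRho < 1, caseProp > 0, caseProp < 1,
              noiseScale >= 0)
    structure(list(nSnp = as.integer(nSnp), eafRange = eafRange,
                   ldModel = match.arg(ldModel), ldRho = ldRho,
                   ldBlockSize = as.integer(ldBlockSize), nX = nX,
                   nY = nY, theta = theta, nCausal = as.integer(nCausal),
                   causalBeta = causalBeta,
                   invalidFraction = invalidFraction,
                   pleiotropy = match.arg(pleiotropy),
                   alphaMean = alphaMean, alphaSd = alphaSd,
                   outcomeType = match.arg(outcomeType),
                   caseProp = caseProp, noiseScale = noiseScale,
                   chrom = chrom, posStart = posStart, posEnd = posEnd,
                   seed = seed),
              class = "SimConfig")
}

# genotype correlation matrix under the configured LD model
.ldCorrelation <- function(config) {
    n <- config$nSnp
    if (config$ldModel == "ar1") {
        R <- config$ldRho^abs(outer(seq_len(n), seq_len(n), `-`))
    } else {
        block <- rep(seq_len(ceiling(n / config$ldBlockSize)),
                     each = config$ldBlockSize)[seq_len(n)]
        R <- outer(block, block, `==`) * config$ldRho
        diag(R) <- 1
    }
    R
}

# shared scaffold: ids, positions, alleles, frequencies, LD
.simScaffold <- function(config) {
    n <- config$nSnp
    ids <- sprintf("rs%s%05d", config$chrom, seq_len(n))
    pos <- as.integer(round(seq(config$posStart, config$posEnd,
                                length.out = n)))
    alleles <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), n,
                                        replace = TRUE), , drop = FALSE]
    eaf <- runif(n, config$eafRange[1], config$eafRange[2])
    R <- .ldCorrelation(config)
    dimnames(R) <- list(ids, ids)
    list(ids = ids, pos = pos, ea = alleles[, 1], oa = alleles[, 2],
         eaf = eaf, R = R)
}

# per-SNP sampling SE on the standardized scale
.samplingSe <- function(eaf, n, type = "quantitative", s = 0.1) {
    base <- 2 * n * eaf * (1 - eaf)
    if (type == "case-control") base <- base * s * (1 - s)
    1 / sqrt(base)
}

# draw one GWAS table around true marginal effects
.simTable <- function(scaffold, margBeta, n, config, trait, type, chol = NULL) {
    se <- .samplingSe(scaffold$eaf, n, type, config$caseProp)
    if (config$noiseScale > 0) {
        L <- if (is.null(chol)) chol(scaffold$R) else chol
        z <- drop(rnorm(length(margBeta)) %*% L)
        beta <- margBeta + config$noiseScale * se * z
    } else beta <- margBeta
    d <- data.frame(snp = scaffold$ids, chrom = config$chrom,
                    pos = scaffold$pos, ea = scaffold$ea,
                    oa = scaffold$oa, eaf = scaffold$eaf, beta = beta,
                    se = se, pval = pmax(.zToP(beta / se),
                                         .Machine$double.xmin),
                    n = n, stringsAsFactors = FALSE)
    gwasSumstats(d, trait = trait,
                 traitType = type,
                 sdY = if (type == "quantitative") 1 else NA_real_,
                 caseProp = if (type == "case-control") config$caseProp
                            else NA_real_)
}

#' Simulate a two-sample exposure/outcome GWAS pair
#'
#' Draws effect-allele frequencies and an LD correlation matrix R, places
#' causal exposure effects, forms marginal effects \eqn{R \beta_{causal}},
#' and samples exposure and outcome estimates from independent
#' multivariate normals (two non-overlapping cohorts) around the true
#' marginal effects.  Outcome truth is \eqn{\theta \beta_{marg} + \alpha}
#' with pleiotropic \eqn{\alpha} on an \code{invalidFraction} of causal
#' SNPs.  Noise-free mode (\code{noiseScale = 0}) returns estimates equal
#' to their expectations, so IVW on the instruments recovers
#' \eqn{\theta} exactly.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{exposure} and \code{outcome}
#'   \linkS4class{GwasSumstats}, \code{ld} (\linkS4class{LDMatrix} of
#'   r-squared), and \code{truth} (\linkS4class{SimTruth})
#' @export
simulateTwoSample <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    if (!is.null(config$seed)) set.seed(config$seed)
    sc <- .simScaffold(config)
    n <- config$nSnp
    causal <- sort(sample.int(n, config$nCausal))
    betaCausal <- numeric(n)
    betaCausal[causal] <- sample(c(-1, 1), config$nCausal, TRUE) *
        runif(config$nCausal, 0.5, 1.5) * config$causalBeta
    margX <- unname(drop(sc$R %*% betaCausal))
    nInvalid <- round(config$invalidFraction * config$nCausal)
    alpha <- numeric(n)
    if (nInvalid > 0) {
        inv <- causal[seq_len(nInvalid)]
        mu <- if (config$pleiotropy == "directional") config$alphaMean else 0
        alpha[inv] <- rnorm(nInvalid, mu, config$alphaSd)
    }
    margY <- config$theta * margX + alpha
    L <- chol(sc$R)
    exposure <- .simTable(sc, margX, config$nX, config,
                          trait = "exposure", type = "quantitative",
                          chol = L)
    outcome <- .simTable(sc, margY, config$nY, config,
                         trait = "outcome", type = config$outcomeType,
                         chol = L)
    truth <- new("SimTruth", theta = config$theta, betaX = margX,
                 alpha = alpha, causalSnps = sc$ids[causal],
                 scenario = "two_sample",
                 seed = if (is.null(config$seed)) NA_real_
                        else as.numeric(config$seed),
                 config = unclass(config)[setdiff(names(config), "seed")])
    list(exposure = exposure, outcome = outcome,
         ld = ldMatrix(sc$R^2), truth = truth)
}

#' Simulate a colocalization scenario
#'
#' Generates two quantitative-trait summary tables over one locus with a
#' configuration of causal variants matching the requested hypothesis:
#' H0 none, H1/H2 a causal variant in one trait only, H3 two distinct
#' causal variants (drawn from different LD blocks, r-squared between
#' them below \code{maxCausalR2}), H4 one shared causal variant.
#'
#' @param config a \code{\link{simConfig}}; \code{nX}/\code{nY} are the
#'   two traits' sample sizes
#' @param scenario "H0", "H1", "H2", "H3" or "H4"
#' @param effectSize per-allele causal effect (SD units) for both traits
#' @param maxCausalR2 maximum r-squared between the two H3 causal SNPs
#' @return list with \code{trait1}, \code{trait2}, \code{ld},
#'   \code{truth}
#' @export
simulateColocScenario <- function(config = simConfig(nSnp = 50L),
                                  scenario = c("H0", "H1", "H2", "H3", "H4"),
                                  effectSize = 0.05, maxCausalR2 = 0.04) {
    stopifnot(inherits(config, "SimConfig"))
    scenario <- match.arg(scenario)
    if (!is.null(config$seed)) set.seed(config$seed)
    sc <- .simScaffold(config)
    n <- config$nSnp
    pick1 <- sample.int(n, 1L)
    causal1 <- integer(0); causal2 <- integer(0)
    if (scenario %in% c("H1", "H3", "H4")) causal1 <- pick1
    if (scenario == "H2") causal2 <- pick1
    if (scenario == "H4") causal2 <- pick1
    if (scenario == "H3") {
        ok <- which(sc$R[pick1, ]^2 < maxCausalR2)
        if (!length(ok)) .stopf("no SNP in low enough LD for H3")
        causal2 <- sample(ok, 1L)
    }
    marg <- function(causal) {
        b <- numeric(n)
        b[causal] <- effectSize
        unname(drop(sc$R %*% b))
    }
    L <- chol(sc$R)
    trait1 <- .simTable(sc, marg(causal1), config$nX, config,
                        trait = "trait1", type = "quantitative", chol = L)
    trait2 <- .simTable(sc, marg(causal2), config$nY, config,
                        trait = "trait2", type = "quantitative", chol = L)
    truth <- new("SimTruth", theta = NA_real_, betaX = marg(causal1),
                 alpha = marg(causal2),
                 causalSnps = unique(sc$ids[c(causal1, causal2)]),
                 scenario = scenario,
                 seed = if (is.null(config$seed)) NA_real_
                        else as.numeric(config$seed),
                 config = unclass(config)[setdiff(names(config), "seed")])
    list(trait1 = trait1, trait2 = trait2, ld = ldMatrix(sc$R^2),
         truth = truth)
}

#' Simulate a two-step mediation design
#'
#' Emits three linked two-sample pairs: exposure-to-mediator over the
#' exposure's cis instruments (marginal mediator effects
#' \eqn{\beta_1 \beta_X}), mediator-to-outcome over an independent
#' genome-wide mediator instrument set, and exposure-to-outcome with
#' total effect \eqn{direct + \beta_1\beta_2}.
#'
#' @param config a \code{\link{simConfig}} (governs the exposure locus;
#'   the mediator instrument set reuses its size settings on another
#'   chromosome)
#' @param beta1 exposure-to-mediator effect
#' @param beta2 mediator-to-outcome effect
#' @param direct direct exposure-to-outcome effect (0 = full mediation)
#' @return list of pairs \code{xm}, \code{my}, \code{xy} (each with
#'   \code{exposure}/\code{outcome} tables), \code{ld}, \code{truth}
#' @export
simulateMediation <- function(config = simConfig(), beta1 = 0.5,
                              beta2 = 0.3, direct = 0) {
    stopifnot(inherits(config, "SimConfig"))
    if (!is.null(config$seed)) set.seed(config$seed)
    total <- direct + beta1 * beta2

    scA <- .simScaffold(config)
    n <- config$nSnp
    causal <- sort(sample.int(n, config$nCausal))
    bC <- numeric(n)
    bC[causal] <- sample(c(-1, 1), config$nCausal, TRUE) *
        runif(config$nCausal, 0.5, 1.5) * config$causalBeta
    margX <- unname(drop(scA$R %*% bC))
    LA <- chol(scA$R)
    xTab <- .simTable(scA, margX, config$nX, config, "exposure",
                      "quantitative", LA)
    mTabA <- .simTable(scA, beta1 * margX, config$nY, config, "mediator",
                       "quantitative", LA)
    yTabA <- .simTable(scA, total * margX, config$nY, config, "outcome",
                       "quantitative", LA)

    cfgB <- config
    cfgB$chrom <- "11"; cfgB$posStart <- 1e6; cfgB$posEnd <- 9e7
    cfgB$ldRho <- 0     # genome-wide independent mediator SNPs
    scB <- .simScaffold(cfgB)
    causalB <- sort(sample.int(n, config$nCausal))
    bM <- numeric(n)
    bM[causalB] <- sample(c(-1, 1), config$nCausal, TRUE) *
        runif(config$nCausal, 0.5, 1.5) * config$causalBeta
    margM <- unname(drop(scB$R %*% bM))
    LB <- chol(scB$R)
    mTabB <- .simTable(scB, margM, config$nX, cfgB, "mediator",
                       "quantitative", LB)
    yTabB <- .simTable(scB, beta2 * margM, config$nY, cfgB, "outcome",
                       "quantitative", LB)

    truth <- new("SimTruth", theta = total, betaX = margX, alpha = margM,
                 causalSnps = c(scA$ids[causal], scB$ids[causalB]),
                 scenario = sprintf("mediation_b1=%g_b2=%g_direct=%g",
                                    beta1, beta2, direct),
                 seed = if (is.null(config$seed)) NA_real_
                        else as.numeric(config$seed),
                 config = unclass(config)[setdiff(names(config), "seed")])
    list(xm = list(exposure = xTab, outcome = mTabA),
         my = list(exposure = mTabB, outcome = yTabB),
         xy = list(exposure = xTab, outcome = yTabA),
         ld = ldMatrix(scA$R^2), ldMediator = ldMatrix(scB$R^2),
         truth = truth)
}

#' Serialize / restore simulation ground truth
#'
#' JSON round-trips at full double precision.
#'
#' @param truth a \linkS4class{SimTruth}
#' @param path file path
#' @export
writeSimTruth <- function(truth, path) {
    stopifnot(is(truth, "SimTruth"))
    jsonlite::write_json(
        list(theta = truth@theta, betaX = truth@betaX,
             alpha = truth@alpha, causalSnps = truth@causalSnps,
             scenario = truth@scenario, seed = truth@seed,
             config = truth@config),
        path, auto_unbox = TRUE, digits = I(17), null = "null",
        na = "null")
    invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("SimTruth", theta = as.numeric(x$theta),
        betaX = as.numeric(x$betaX), alpha = as.numeric(x$alpha),
        causalSnps = as.character(x$causalSnps),
        scenario = x$scenario, seed = as.numeric(x$seed),
        config = as.list(x$config))
}
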