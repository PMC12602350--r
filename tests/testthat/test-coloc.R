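# independent linear-space enumeration used as the oracle
linearColoc <- function(labfX, labfY, priors = colocPriors()) {
    bfx <- exp(labfX); bfy <- exp(labfY)
    s1 <- sum(bfx); s2 <- sum(bfy); s12 <- sum(bfx * bfy)
    h <- c(1,
           priors[["p1"]] * s1,
           priors[["p2"]] * s2,
           priors[["p1"]] * priors[["p2"]] * (s1 * s2 - s12),
           priors[["p12"]] * s12)
    h / sum(h)
}

test_that("priors validate the p12 constraint", {
    expect_equal(colocPriors(), c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5))
    expect_error(colocPriors(p12 = 1e-3), "p12")
    expect_error(colocPriors(p1 = 0), "strictly")
})

test_that("per-SNP log-ABFs follow the Wakefield shrinkage form", {
    x <- makeSumstats(n = 3, beta = c(0, 0.05, 0.2),
                      se = c(0.02, 0.02, 0.02))
    labf <- labfPerSnp(x)
    W <- 0.15^2
    r <- W / (W + 0.02^2)
    z <- c(0, 0.05, 0.2) / 0.02
    expect_equal(as.numeric(labf), 0.5 * (log(1 - r) + r * z^2))
    expect_lt(labf[[1]], 0)           # z = 0 forces a negative log-ABF
    # vanishing prior effect variance: no evidence either way
    expect_equal(as.numeric(labfPerSnp(x, wScale = 1e-8)), rep(0, 3),
                 tolerance = 1e-8)
    # case-control scale uses W = 0.2^2
    xc <- makeSumstats(n = 1, beta = 0.1, se = 0.02, type = "case-control")
    Wc <- 0.2^2; rc <- Wc / (Wc + 4e-4)
    expect_equal(as.numeric(labfPerSnp(xc)),
                 0.5 * (log(1 - rc) + rc * 25))
})

test_that("log-space posteriors equal linear enumeration to 1e-10", {
    set.seed(42)
    for (i in 1:25) {
        n <- sample(1:20, 1)
        labfX <- 0.5 * (log(0.3) + 0.7 * rnorm(n, 0, 3)^2)
        labfY <- 0.5 * (log(0.3) + 0.7 * rnorm(n, 0, 3)^2)
        res <- colocPosteriors(labfX, labfY)
        expect_lt(max(abs(posteriors(res) - linearColoc(labfX, labfY))),
                  1e-10)
        expect_lt(abs(sum(posteriors(res)) - 1), 1e-12)
    }
})

test_that("single-SNP loci have an empty H3 and conditional H4 of 1", {
    res <- colocPosteriors(c(rs1 = 20), c(rs1 = 18))
    expect_equal(posteriors(res)[["pp_h3"]], 0)
    expect_equal(conditionalH4(res), 1)
    expect_equal(res@conditionalH4, 1)
})

test_that("null data concentrate the posterior on H0", {
    labf0 <- rep(0.5 * log(0.5), 100)   # z = 0 everywhere
    res <- colocPosteriors(labf0, labf0)
    expect_gt(posteriors(res)[["pp_h0"]], 0.9)
})

test_that("posteriors are invariant to joint SNP reordering", {
    set.seed(9)
    labfX <- rnorm(15, 2, 4); labfY <- rnorm(15, 2, 4)
    perm <- sample(15)
    expect_equal(posteriors(colocPosteriors(labfX, labfY)),
                 posteriors(colocPosteriors(labfX[perm], labfY[perm])))
})

test_that("unit changes with matching sdY leave posteriors unchanged", {
    sim <- simulateColocScenario(simConfig(nSnp = 20, nX = 5e4,
                                           nY = 5e4, seed = 3), "H4")
    base <- posteriors(runColoc(sim$trait1, sim$trait2))
    scale <- 3.2
    rescale <- function(t) {
        d <- snpData(t)
        d$beta <- d$beta * scale
        d$se <- d$se * scale
        gwasSumstats(d, trait = traitName(t), sdY = scale)
    }
    scaled <- posteriors(runColoc(rescale(sim$trait1),
                                  rescale(sim$trait2)))
    expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("conditional H4 handles degenerate denominators", {
    mk <- function(pp) new("ColocResult",
                           pp = setNames(pp, c("pp_h0", "pp_h1", "pp_h2",
                                               "pp_h3", "pp_h4")),
                           conditionalH4 = NA_real_, nSnp = 5L,
                           priors = colocPriors())
    expect_equal(conditionalH4(mk(c(0.3, 0.2, 0.1, 0.1, 0.3))), 0.75)
    expect_equal(conditionalH4(mk(c(0.4, 0.2, 0.1, 0, 0.3))), 1.0)
    expect_warning(
        expect_true(is.na(conditionalH4(mk(c(0.5, 0.3, 0.2, 0, 0))))),
        "undefined")
})

test_that("sdY is recovered from frequencies and sample sizes", {
    sim <- simulateTwoSample(simConfig(seed = 12, nSnp = 20))
    expect_equal(estimateSdY(sim$exposure), 1, tolerance = 1e-6)
})
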