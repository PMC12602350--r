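test_that("Wald ratio divides outcome by exposure effect", {
    p <- makePair(bx = 0.10, sx = 0.01, by = 0.05, sy = 0.01)
    r <- waldRatio(p)
    expect_equal(estimate(r), 0.5)
    expect_equal(stdError(r), 0.1)
    expect_equal(r@ciLow, 0.5 - 1.96 * 0.1)
    expect_equal(estimate(waldRatio(makePair(0.1, 0.01, 0, 0.01))), 0)
    expect_equal(estimate(waldRatio(makePair(-0.1, 0.01, 0.05, 0.01))),
                 -0.5)
    expect_error(waldRatio(makePair(0, 0.01, 0.05, 0.01)), "undefined")
    expect_error(waldRatio(makePair(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
                 "exactly one")
})

test_that("IVW equals the weighted average of ratios and WLS origin fit", {
    p <- makePair(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                  by = c(0.05, 0.2), sy = c(0.01, 0.01))
    r <- mrIVW(p, "fixed")
    # ratio weights (100, 400): (100*0.5 + 400*1.0) / 500
    expect_equal(estimate(r), 0.9)
    # cross-check against weighted least squares through the origin
    d <- snpData(p)
    wls <- lm(beta_y ~ 0 + beta_x, data = d, weights = 1 / d$se_y^2)
    expect_equal(estimate(r), unname(coef(wls)))
    expect_equal(stdError(r), 1 / sqrt(sum(d$beta_x^2 / d$se_y^2)))

    # consensus: identical ratios
    p2 <- makePair(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                   by = c(0.05, 0.1), sy = c(0.01, 0.01))
    expect_equal(estimate(mrIVW(p2, "fixed")), 0.5)

    expect_error(mrIVW(makePair(0.1, 0.01, 0.05, 0.01)), "waldRatio")
})

test_that("IVW is invariant to reordering and joint sign flips", {
    set.seed(4)
    n <- 8
    p <- makePair(bx = runif(n, 0.05, 0.2), sx = runif(n, 0.005, 0.02),
                  by = rnorm(n, 0.1, 0.05), sy = runif(n, 0.005, 0.02))
    base <- estimate(mrIVW(p))
    perm <- sample(n)
    pPerm <- initialize(p, data = p@data[perm, ])
    expect_equal(estimate(mrIVW(pPerm)), base)
    dFlip <- p@data
    dFlip$beta_x[3] <- -dFlip$beta_x[3]
    dFlip$beta_y[3] <- -dFlip$beta_y[3]
    expect_equal(estimate(mrIVW(initialize(p, data = dFlip))), base)
})

test_that("random-effects IVW inflates but never deflates the SE", {
    p <- makePair(bx = c(0.1, 0.1, 0.1, 0.1), sx = rep(0.01, 4),
                  by = c(0.01, 0.09, 0.02, 0.08), sy = rep(0.01, 4))
    expect_gte(stdError(mrIVW(p, "random_multiplicative")),
               stdError(mrIVW(p, "fixed")))
    # homogeneous data: multiplier capped at 1
    p2 <- makePair(bx = rep(0.1, 4), sx = rep(0.01, 4),
                   by = rep(0.05, 4), sy = rep(0.01, 4))
    expect_equal(stdError(mrIVW(p2, "random_multiplicative")),
                 stdError(mrIVW(p2, "fixed")))
})

test_that("Egger recovers an exact line and its intercept", {
    bx <- c(0.1, 0.2, 0.3)
    p <- makePair(bx = bx, sx = rep(0.01, 3), by = 0.1 + 0.5 * bx,
                  sy = rep(0.01, 3))
    e <- mrEgger(p)
    expect_equal(estimate(e$slope), 0.5)
    expect_equal(estimate(e$intercept), 0.1)
    # all-null outcome
    p0 <- makePair(bx = bx, sx = rep(0.01, 3), by = rep(0, 3),
                   sy = rep(0.01, 3))
    e0 <- mrEgger(p0)
    expect_equal(estimate(e0$slope), 0)
    expect_equal(estimate(e0$intercept), 0)
    expect_error(mrEgger(makePair(c(1, 1), c(1, 1), c(1, 1), c(1, 1))),
                 ">= 3")
})

test_that("Egger intercept is centred on zero under balanced pleiotropy", {
    set.seed(11)
    bx <- runif(10, 0.05, 0.15)
    reps <- 400
    ints <- vapply(seq_len(reps), function(i) {
        alpha <- rnorm(10, 0, 0.02)
        by <- 0.3 * bx + alpha + rnorm(10, 0, 0.01)
        estimate(mrEgger(makePair(bx, rep(0.005, 10), by,
                                  rep(0.01, 10)))$intercept)
    }, numeric(1))
    expect_lt(abs(mean(ints)), 4 * sd(ints) / sqrt(reps))
})

test_that("weighted median interpolates cumulative weight midpoints", {
    # equal weights, ratios (1,2,3): midpoints (1/6, 1/2, 5/6)
    p <- makePair(bx = rep(0.1, 3), sx = rep(0.01, 3),
                  by = c(0.1, 0.2, 0.3), sy = rep(0.01, 3))
    r <- mrWeightedMedian(p, bootReps = 50, seed = 7)
    expect_equal(estimate(r), 2)
    # robust to <50% invalid weight in the noise-free limit
    bx <- rep(0.1, 10)
    by <- 0.3 * bx
    by[1:4] <- by[1:4] + 0.5
    p2 <- makePair(bx, rep(0.01, 10), by, rep(0.01, 10))
    expect_equal(estimate(mrWeightedMedian(p2, bootReps = 50, seed = 7)),
                 0.3)
    # seeded bootstrap is reproducible
    expect_identical(stdError(mrWeightedMedian(p2, seed = 3)),
                     stdError(mrWeightedMedian(p2, seed = 3)))
})

test_that("weighted mode finds the plurality cluster", {
    # degenerate: all ratios identical
    p <- makePair(bx = rep(0.1, 4), sx = rep(0.01, 4),
                  by = rep(0.07, 4), sy = rep(0.01, 4))
    expect_equal(estimate(mrWeightedMode(p, bootReps = 50, seed = 5)),
                 0.7)
    # 7 valid near 0.3, 3 outliers near 2.0
    set.seed(8)
    bx <- rep(0.1, 10)
    ratios <- c(0.3 + rnorm(7, 0, 0.01), 2 + rnorm(3, 0, 0.01))
    p2 <- makePair(bx, rep(0.01, 10), ratios * bx, rep(0.01, 10))
    expect_lt(abs(estimate(mrWeightedMode(p2, bootReps = 50, seed = 5)) -
                  0.3), 0.05)
    # bandwidth sensitivity is smooth, not catastrophic
    wide <- mrWeightedMode(p2, bandwidthFactor = 2, bootReps = 50,
                           seed = 5)
    expect_lt(abs(estimate(wide) - 0.3), 0.2)
})

test_that("MR-LASSO keeps valid SNPs and excludes gross outliers", {
    bx <- seq(0.05, 0.25, length.out = 10)
    byValid <- 0.3 * bx
    pValid <- makePair(bx, rep(0.01, 10), byValid, rep(0.01, 10))
    rValid <- mrLasso(pValid)
    expect_equal(estimate(rValid), estimate(mrIVW(pValid, "fixed")))
    expect_equal(nSnp(rValid), 10L)
    expect_true(rValid@notes$heterogeneity_rule_met)

    by <- byValid
    by[4] <- by[4] + 0.5     # gross pleiotropic outlier
    pOut <- makePair(bx, rep(0.01, 10), by, rep(0.01, 10))
    rOut <- mrLasso(pOut)
    expect_equal(rOut@notes$excluded, "rs4")
    clean <- makePair(bx[-4], rep(0.01, 9), by[-4], rep(0.01, 9))
    expect_equal(estimate(rOut), estimate(mrIVW(clean, "fixed")))

    expect_error(mrLasso(makePair(c(1, 2), c(1, 1), c(1, 2), c(1, 1))),
                 ">= 3")
})

test_that("Cochran's Q matches hand computation and edge cases", {
    # ratios (0.5, 1.0), weights (100, 400), IVW 0.9:
    # Q = 100*0.16 + 400*0.01 = 20
    p <- makePair(bx = c(0.1, 0.2), sx = c(0.01, 0.01),
                  by = c(0.05, 0.2), sy = c(0.01, 0.01))
    q <- cochranQ(p)
    expect_equal(q@Q, 20)
    expect_equal(q@df, 1L)
    expect_equal(q@pval, pchisq(20, 1, lower.tail = FALSE))
    # identical ratios: no heterogeneity
    q0 <- cochranQ(makePair(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                            c(0.01, 0.01)))
    expect_equal(q0@Q, 0)
    expect_equal(q0@pval, 1)
})

test_that("Steiger compares variance explained across traits", {
    p <- makePair(bx = 0.1, sx = 0.01, by = 0.01, sy = 0.01,
                  px = 1e-10, py = 0.5)
    s <- steigerTest(p)
    expect_true(s@directionCorrect)
    expect_lt(s@pval, 0.05)
    # equal evidence on both sides: boundary
    p2 <- makePair(bx = 0.1, sx = 0.01, by = 0.1, sy = 0.01,
                   px = 1e-4, py = 1e-4)
    s2 <- steigerTest(p2)
    expect_false(s2@directionCorrect)
    expect_equal(s2@pval, 1)
    # binary outcomes flagged not-computed
    p3 <- makePair(0.1, 0.01, 0.05, 0.01, type = "case-control")
    expect_warning(s3 <- steigerTest(p3), "not computed")
    expect_true(is.na(s3@pval))
})

test_that("all estimators agree exactly on noise-free valid data", {
    sim <- simulateTwoSample(simConfig(seed = 7, theta = 0.5,
                                       noiseScale = 0, nCausal = 8,
                                       causalBeta = 0.04))
    set <- suppressMessages(selectCisInstruments(sim$exposure,
                                                 glp1rLocus(), sim$ld))
    pair <- harmonizeSumstats(gwasSumstats(snpData(set)), sim$outcome)
    expect_gte(nSnp(pair), 3L)
    suite <- suppressWarnings(mrSuite(pair, seed = 2))
    for (m in c("primary", "egger_slope", "weighted_median",
                "weighted_mode", "mr_lasso"))
        expect_equal(estimate(suite[[m]]), 0.5, tolerance = 1e-10)
    expect_equal(estimate(suite$egger_intercept), 0, tolerance = 1e-10)
    expect_equal(suite$q@Q, 0, tolerance = 1e-8)
})

test_that("the suite picks Wald for one SNP and IVW for several", {
    p1 <- makePair(0.1, 0.01, 0.05, 0.01)
    expect_equal(mrSuite(p1)$primary@method, "wald")
    p2 <- makePair(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.1),
                   c(0.01, 0.01))
    s2 <- mrSuite(p2)
    expect_equal(s2$primary@method, "ivw_fixed")
    expect_null(s2$weighted_median)
    p4 <- makePair(rep(0.1, 4), rep(0.01, 4), rep(0.05, 4),
                   rep(0.01, 4))
    s4 <- suppressWarnings(mrSuite(p4, seed = 3))
    expect_equal(s4$primary@method, "ivw_random")
    expect_s4_class(s4$weighted_median, "MRResult")
})
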