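ldFromMatrix <- function(r2, ids) {
    dimnames(r2) <- list(ids, ids)
    ldMatrix(r2)
}

test_that("greedy clumping keeps independent best SNPs", {
    x <- makeSumstats(n = 3, beta = c(0.12, 0.11, 0.10),
                      pval = c(1e-9, 1e-8, 1e-7))
    r2 <- diag(3)
    r2[1, 2] <- r2[2, 1] <- 0.5
    r2[1, 3] <- r2[3, 1] <- 0.05
    r2[2, 3] <- r2[3, 2] <- 0.05
    ld <- ldFromMatrix(r2, paste0("rs", 1:3))
    kept <- clumpSnps(x, ld, 0.1)
    expect_equal(snpData(kept)$snp, c("rs1", "rs3"))

    # no LD at all: everything kept
    expect_equal(nSnp(clumpSnps(x, ldFromMatrix(diag(3), paste0("rs", 1:3)),
                                0.1)), 3L)

    # equal p: the larger-|z| SNP wins the tie
    x2 <- makeSumstats(n = 2, beta = c(0.10, 0.12), se = c(0.02, 0.02),
                       pval = c(1e-8, 1e-8))
    r2b <- matrix(c(1, 0.9, 0.9, 1), 2)
    kept2 <- clumpSnps(x2, ldFromMatrix(r2b, c("rs1", "rs2")), 0.1)
    expect_equal(snpData(kept2)$snp, "rs2")

    # SNPs absent from the LD matrix are dropped with a message
    expect_message(k3 <- clumpSnps(x, ldFromMatrix(diag(2),
                                                   c("rs1", "rs2")), 0.1),
                   "no_ld")
    expect_equal(attr(k3, "dropped_no_ld"), "rs3")
})

test_that("clumping matches brute-force search on small instances", {
    # oracle: among all pairwise-admissible subsets, take the one that
    # prefers earlier SNPs in (p, |z| desc, id) order -- lexicographic
    # maximum of the inclusion vector
    bruteClump <- function(d, r2, r2max) {
        ord <- order(d$pval, -abs(d$beta / d$se), d$snp)
        n <- nrow(d)
        best <- NULL; bestScore <- -1
        for (mask in 0:(2^n - 1)) {
            inc <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
            idx <- ord[inc]
            if (length(idx) > 1) {
                sub <- r2[idx, idx]
                if (any(sub[upper.tri(sub)] >= r2max)) next
            }
            score <- sum(2^(n - seq_len(n))[inc])
            if (score > bestScore) { bestScore <- score; best <- idx }
        }
        d$snp[sort(best)]
    }
    set.seed(99)
    for (i in 1:20) {
        n <- sample(3:8, 1)
        z <- matrix(rnorm(n * n), n)
        r2 <- cov2cor(crossprod(z) + diag(n))^2
        dimnames(r2) <- list(paste0("rs", 1:n), paste0("rs", 1:n))
        x <- makeSumstats(n = n, beta = runif(n, 0.05, 0.2),
                          se = runif(n, 0.01, 0.05))
        kept <- clumpSnps(x, ldMatrix(r2), 0.1)
        expect_setequal(snpData(kept)$snp, bruteClump(snpData(x), r2, 0.1))
        # invariant: no kept pair at or above the threshold
        ks <- snpData(kept)$snp
        if (length(ks) > 1) {
            sub <- r2[ks, ks]
            expect_true(all(sub[upper.tri(sub)] < 0.1))
        }
    }
})

test_that("cascade falls back to the relaxed threshold and records it", {
    locus <- glp1rLocus()
    mk <- function(pvals) makeSumstats(n = length(pvals),
                                       pos = 39020000L + seq_along(pvals),
                                       pval = pvals)
    ld <- ldFromMatrix(diag(2), c("rs1", "rs2"))
    s1 <- selectCisInstruments(mk(c(1e-9, 1e-9)), locus, ld)
    expect_equal(nSnp(s1), 2L)
    expect_equal(unname(s1@cascadeLevel), 5e-8)

    expect_message(
        s2 <- selectCisInstruments(mk(c(8e-7, 0.5)), locus, ld),
        "advancing cascade")
    expect_equal(nSnp(s2), 1L)
    expect_equal(unname(s2@cascadeLevel), 5e-6)

    expect_error(suppressMessages(
        selectCisInstruments(mk(c(1e-4, 1e-3)), locus, ld)),
        "instrumentation error.*GLP1R")
})

test_that("selection is deterministic given table, LD and thresholds", {
    sim <- simulateTwoSample(simConfig(seed = 31, nCausal = 8,
                                       causalBeta = 0.04))
    a <- suppressMessages(selectCisInstruments(sim$exposure, glp1rLocus(),
                                               sim$ld))
    b <- suppressMessages(selectCisInstruments(sim$exposure, glp1rLocus(),
                                               sim$ld))
    expect_identical(snpData(a), snpData(b))
})

test_that("dual-target combination is order-insensitive and guarded", {
    a <- suppressMessages(strengthDiagnostics(new("InstrumentSet",
        data = cbind(snpData(makeSumstats(n = 1, chrom = "6")),
                     locus = "GLP1R", flipped = FALSE),
        loci = "GLP1R", cascadeLevel = c(GLP1R = 5e-8), r2Max = 0.1,
        trait = "BMI")))
    bTab <- makeSumstats(n = 3, chrom = "19",
                         snp = paste0("rs19_", 1:3),
                         pos = 46171500L + 1:3)
    b <- suppressMessages(strengthDiagnostics(new("InstrumentSet",
        data = cbind(snpData(bTab), locus = "GIPR", flipped = FALSE),
        loci = "GIPR", cascadeLevel = c(GIPR = 5e-8), r2Max = 0.1,
        trait = "BMI")))
    ab <- combineTargets(a, b)
    ba <- combineTargets(b, a)
    expect_equal(nSnp(ab), 4L)
    expect_setequal(snpData(ab)$snp, snpData(ba)$snp)
    expect_setequal(ab@loci, c("GLP1R", "GIPR"))
    expect_equal(ab@setR2, ba@setR2)
    expect_error(combineTargets(a, a), "disjoint")
    cOther <- initialize(b, trait = "HbA1c")
    expect_error(combineTargets(a, cOther), "share the exposure")
})

test_that("agonism orientation flips negative effects and is idempotent", {
    set <- new("InstrumentSet",
               data = cbind(snpData(makeSumstats(n = 2,
                                                 beta = c(-0.08, 0.05),
                                                 eaf = c(0.3, 0.4))),
                            locus = "GLP1R", flipped = FALSE),
               loci = "GLP1R", cascadeLevel = c(GLP1R = 5e-8),
               r2Max = 0.1, trait = "BMI")
    o1 <- orientToAgonism(set, "lowering")
    d <- snpData(o1)
    expect_equal(d$beta, c(0.08, 0.05))
    expect_equal(d$eaf, c(0.7, 0.4))
    expect_equal(d$flipped, c(TRUE, FALSE))
    expect_equal(d$ea[1], "G")     # allele labels swapped on the flip
    o2 <- orientToAgonism(o1, "lowering")
    expect_identical(snpData(o2), snpData(o1))
    # beta exactly zero warns and stays
    setz <- initialize(set, data = within(set@data, beta <- c(0, 0.05)))
    expect_warning(oz <- orientToAgonism(setz, "lowering"), "unflipped")
    expect_equal(snpData(oz)$beta[1], 0)
})

test_that("strength diagnostics implement F and variance explained", {
    set <- new("InstrumentSet",
               data = cbind(snpData(makeSumstats(n = 1, beta = 0.1,
                                                 se = 0.02,
                                                 nSample = 1000)),
                            locus = "L", flipped = FALSE),
               loci = "L", cascadeLevel = c(L = 5e-8), r2Max = 0.1,
               trait = "BMI")
    out <- strengthDiagnostics(set)
    expect_equal(snpData(out)$F, 25)
    expect_equal(snpData(out)$r2, 25 / 1023)
    expect_equal(out@setR2, 25 / 1023)
    expect_false(snpData(out)$weak)

    weak <- initialize(set, data = within(set@data, {
        beta <- 0.02; se <- 0.01
    }))
    expect_message(ow <- strengthDiagnostics(weak), "F < 10")
    expect_equal(snpData(ow)$F, 4)
    expect_true(snpData(ow)$weak)
})
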