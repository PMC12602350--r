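test_that("reading validates rows, normalizes alleles and counts drops", {
    df <- data.frame(SNP = paste0("rs", 1:5), CHR = "6",
                     POS = 39100000 + 1:5,
                     EA = c("a", "A", "g", "A", "A"),
                     OA = c("g", "G", "a", "G", "G"),
                     EAF = c(0.3, 0.4, 0.5, 0.2, 1.2),
                     BETA = 0.1, SE = c(0.02, 0.02, 0.02, 0, 0.02),
                     P = 2 * pnorm(-5), N = 1e5)
    path <- writeSumstatsFile(df)
    expect_message(x <- readSumstats(path), "dropped 2")
    expect_equal(attr(x, "dropped"), 2L)
    expect_equal(nSnp(x), 3L)
    expect_equal(snpData(x)$ea, c("A", "A", "G"))

    # missing mandatory column is a configuration error
    df2 <- df[, setdiff(names(df), "SE")]
    expect_error(readSumstats(writeSumstatsFile(df2)), "configuration")

    # everything invalid is an input error
    df$SE <- 0
    expect_error(suppressMessages(readSumstats(writeSumstatsFile(df))),
                 "no valid rows")
})

test_that("p-values inconsistent with beta/se warn but do not fail", {
    df <- data.frame(SNP = "rs1", CHR = "6", POS = 39100000, EA = "A",
                     OA = "G", EAF = 0.3, BETA = 0.1, SE = 0.02,
                     P = 0.5, N = 1e5)   # true p would be ~6e-7
    expect_warning(readSumstats(writeSumstatsFile(df)), "inconsistent")
})

test_that("summary statistics round-trip through the TSV dialect", {
    x <- makeSumstats(n = 4, beta = c(0.1, -0.2, 0.05, 0.3))
    path <- tempfile(fileext = ".tsv")
    writeSumstats(x, path)
    y <- readSumstats(path, trait = "trait")
    expect_equal(snpData(y)$beta, snpData(x)$beta)
    expect_equal(snpData(y)$snp, snpData(x)$snp)
})

test_that("cis window slicing is closed, build-faithful, order-invariant", {
    # GLP1R 6:39,016,574-39,055,519 with 500 kb flanks:
    # retained interval [38,516,574, 39,555,519]
    pos <- c(38516573L, 38516574L, 39555519L, 39555520L)
    x <- makeSumstats(n = 4, pos = pos)
    out <- sliceLocus(x, glp1rLocus())
    expect_equal(snpData(out)$pos, c(38516574L, 39555519L))

    # window 0 keeps only the gene body
    x2 <- makeSumstats(n = 3, pos = c(39016573L, 39016574L, 39055519L))
    out2 <- sliceLocus(x2, glp1rLocus(windowKb = 0))
    expect_equal(snpData(out2)$pos, c(39016574L, 39055519L))

    # wrong chromosome excluded; empty result allowed
    x3 <- makeSumstats(n = 2, chrom = "7", pos = c(39016580L, 39016590L))
    expect_message(out3 <- sliceLocus(x3, glp1rLocus()), "no SNPs")
    expect_equal(nSnp(out3), 0L)

    # input row order does not matter
    x4 <- makeSumstats(n = 6, pos = 39016574L + seq(0, 50000, by = 10000))
    shuffled <- initialize(x4, snps = snpData(x4)[c(4, 1, 6, 3, 2, 5), ])
    expect_equal(snpData(sliceLocus(shuffled, glp1rLocus())),
                 snpData(sliceLocus(x4, glp1rLocus())))
})

test_that("harmonization aligns labels, strands and palindromes", {
    ex <- makeSumstats(n = 7, ea = c("A", "A", "A", "A", "A", "A", "A"),
                       oa = c("G", "G", "G", "G", "G", "T", "T"),
                       eaf = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.5, 0.2),
                       beta = 0.1)
    ou <- makeSumstats(n = 7,
                       ea = c("A", "G", "T", "C", "A", "A", "T"),
                       oa = c("G", "A", "C", "T", "C", "T", "A"),
                       eaf = c(0.3, 0.7, 0.3, 0.7, 0.3, 0.5, 0.8),
                       beta = 0.3)
    h <- harmonizeSumstats(ex, ou)
    d <- snpData(h)
    # rs1 identical -> kept; rs2 swapped -> flipped; rs3 strand -> kept;
    # rs4 strand+swap -> flipped
    expect_equal(d$action[d$snp %in% c("rs1", "rs3")], c("kept", "kept"))
    expect_equal(d$beta_y[d$snp == "rs2"], -0.3)
    expect_equal(d$eaf_y[d$snp == "rs2"], 0.3)
    expect_equal(d$beta_y[d$snp == "rs4"], -0.3)
    # rs5: A/G vs A/C irreconcilable
    expect_true("rs5" %in% h@dropped$snp)
    expect_equal(h@dropped$reason[h@dropped$snp == "rs5"],
                 "allele_mismatch")
    # rs6: palindromic at eaf 0.5 -> ambiguous under the default policy
    expect_equal(h@dropped$reason[h@dropped$snp == "rs6"],
                 "palindromic_ambiguous")
    # rs7: palindromic, informative but discordant frequencies (0.2 vs
    # 0.2 after label swap... exposure 0.2, outcome swap -> 0.2) aligns
    expect_true("rs7" %in% d$snp)
    # effect alleles identical across traits after harmonization
    expect_true(all(d$ea == "A" | d$snp == "rs7"))
})

test_that("palindromic frequency alignment flips discordant strands", {
    ex <- makeSumstats(n = 1, ea = "A", oa = "T", eaf = 0.2, beta = 0.1)
    ouFlip <- makeSumstats(n = 1, ea = "A", oa = "T", eaf = 0.8,
                           beta = 0.3)
    h <- harmonizeSumstats(ex, ouFlip)
    expect_equal(snpData(h)$action, "flipped")
    expect_equal(snpData(h)$beta_y, -0.3)
    # drop policy removes it regardless
    h2 <- harmonizeSumstats(ex, ouFlip, palindromePolicy = "drop")
    expect_equal(h2@dropped$reason, "palindromic")
})

test_that("harmonization is idempotent and Wald-reciprocal", {
    sim <- simulateTwoSample(simConfig(seed = 21, nSnp = 12))
    h1 <- harmonizeSumstats(sim$exposure, sim$outcome)
    d <- snpData(h1)
    # re-harmonizing the harmonized tables changes nothing
    mk <- function(pre, trait) gwasSumstats(
        data.frame(snp = d$snp, chrom = d$chrom, pos = d$pos, ea = d$ea,
                   oa = d$oa, eaf = d[[paste0("eaf_", pre)]],
                   beta = d[[paste0("beta_", pre)]],
                   se = d[[paste0("se_", pre)]],
                   pval = d[[paste0("pval_", pre)]],
                   n = d[[paste0("n_", pre)]]), trait = trait)
    h2 <- harmonizeSumstats(mk("x", "exposure"), mk("y", "outcome"))
    expect_equal(snpData(h2)$beta_y, d$beta_y)
    expect_equal(snpData(h2)$ea, d$ea)
    expect_true(all(snpData(h2)$action == "kept"))
    # swapping the roles gives reciprocal Wald ratios on shared SNPs
    hRev <- harmonizeSumstats(sim$outcome, sim$exposure)
    dr <- snpData(hRev)
    common <- intersect(d$snp, dr$snp)
    fwd <- (d$beta_y / d$beta_x)[match(common, d$snp)]
    rev <- (dr$beta_y / dr$beta_x)[match(common, dr$snp)]
    expect_equal(fwd, 1 / rev)
})

test_that("LD matrices validate and round-trip", {
    m <- matrix(c(1, 0.25, 0.25, 1), 2,
                dimnames = list(c("rs1", "rs2"), c("rs1", "rs2")))
    ld <- ldMatrix(m)
    path <- tempfile(fileext = ".tsv")
    writeLDMatrix(ld, path)
    expect_equal(unclass(readLDMatrix(path))[,], m)
    expect_error(ldMatrix(matrix(c(1, 2, 2, 1), 2,
                                 dimnames = list(c("a", "b"), c("a", "b")))),
                 "\\[0,1\\]")
    expect_error(ldMatrix(matrix(c(0.5, 0, 0, 1), 2,
                                 dimnames = list(c("a", "b"), c("a", "b")))),
                 "diagonal")
})
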