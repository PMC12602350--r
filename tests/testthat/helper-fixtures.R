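# hand-built containers used across the unit tests

makeSumstats <- function(n = 3, trait = "trait", type = "quantitative",
                         snp = paste0("rs", seq_len(n)), chrom = "6",
                         pos = seq(39100000L, by = 1000L, length.out = n),
                         ea = rep("A", n), oa = rep("G", n),
                         eaf = rep(0.3, n), beta = rep(0.1, n),
                         se = rep(0.02, n), pval = NULL, nSample = 1e5,
                         sdY = 1) {
    if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
    gwasSumstats(data.frame(snp = snp, chrom = chrom, pos = pos, ea = ea,
                            oa = oa, eaf = eaf, beta = beta, se = se,
                            pval = pval, n = nSample,
                            stringsAsFactors = FALSE),
                 trait = trait, traitType = type, sdY = sdY)
}

makePair <- function(bx, sx, by, sy, nx = 1e5, ny = 1e5,
                     type = "quantitative",
                     px = 2 * pnorm(-abs(bx / sx)),
                     py = 2 * pnorm(-abs(by / sy))) {
    n <- length(bx)
    d <- data.frame(snp = paste0("rs", seq_len(n)), chrom = "6",
                    pos = seq_len(n), ea = "A", oa = "G",
                    beta_x = bx, se_x = sx, eaf_x = 0.3, n_x = nx,
                    pval_x = px, beta_y = by, se_y = sy, eaf_y = 0.3,
                    n_y = ny, pval_y = py, palindromic = FALSE,
                    action = "kept", stringsAsFactors = FALSE)
    new("HarmonizedPair", data = d,
        dropped = data.frame(snp = character(0), reason = character(0)),
        exposure = "X", outcome = "Y", outcomeType = type)
}

mrr <- function(beta, se) new("MRResult", method = "ivw_fixed",
                              beta = beta, se = se,
                              ciLow = beta - 1.96 * se,
                              ciHigh = beta + 1.96 * se,
                              pval = 2 * pnorm(-abs(beta / se)),
                              nSnp = 5L)

writeSumstatsFile <- function(df, path = tempfile(fileext = ".tsv")) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}
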