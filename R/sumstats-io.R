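#' Construct a GwasSumstats object from a data.frame
#'
#' Columns must be (or be renamed to) \code{snp, chrom, pos, ea, oa, eaf,
#' beta, se, pval, n}.  Alleles are upper-cased; \code{eaf} may be NA
#' (unknown frequency) but, when present, must lie strictly in (0,1).
#'
#' @param snps data.frame of per-SNP records
#' @param trait trait name
#' @param traitType "quantitative" or "case-control"
#' @param sdY trait SD (quantitative; NA when unknown)
#' @param caseProp case proportion for case-control traits
#' @return a \linkS4class{GwasSumstats}
#' @export
gwasSumstats <- function(snps, trait = "trait",
                         traitType = c("quantitative", "case-control"),
                         sdY = NA_real_, caseProp = NA_real_) {
    traitType <- match.arg(traitType)
    snps <- as.data.frame(snps, stringsAsFactors = FALSE)
    snps$snp <- as.character(snps$snp)
    snps$chrom <- as.character(snps$chrom)
    snps$pos <- as.integer(snps$pos)
    snps$ea <- toupper(as.character(snps$ea))
    snps$oa <- toupper(as.character(snps$oa))
    for (col in c("eaf", "beta", "se", "pval"))
        snps[[col]] <- as.numeric(snps[[col]])
    snps$n <- as.numeric(snps$n)
    rownames(snps) <- NULL
    new("GwasSumstats", snps = snps[, .SUMSTATS_COLS, drop = FALSE],
        trait = trait, traitType = traitType, sdY = sdY,
        caseProp = caseProp)
}

.DEFAULT_COLUMN_MAP <- c(snp = "SNP", chrom = "CHR", pos = "POS",
                         ea = "EA", oa = "OA", eaf = "EAF", beta = "BETA",
                         se = "SE", pval = "P", n = "N")

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a header-ed delimited file, renames columns through
#' \code{columnMap}, validates each row and drops (with a message) rows
#' violating the type/range invariants: missing values, \code{se <= 0},
#' \code{eaf} outside (0,1), \code{pval} outside (0,1], non-SNP or equal
#' alleles, non-positive \code{n}, duplicated identifiers.  A consistency
#' check between the reported p-value and the normal approximation
#' 2*pnorm(-|beta/se|) warns (never fails) when -log10 p deviates by more
#' than \code{pzTol} in relative terms, since published tables round.
#'
#' @param path file path (tab-separated by default)
#' @param columnMap named character vector mapping internal names
#'   (\code{snp, chrom, pos, ea, oa, eaf, beta, se, pval, n}) to file
#'   column names; defaults to \code{SNP, CHR, POS, EA, OA, EAF, BETA,
#'   SE, P, N}.  The \code{eaf} column may be absent (frequencies unknown).
#' @param trait,traitType,sdY,caseProp trait metadata, see
#'   \code{\link{gwasSumstats}}
#' @param sep field separator
#' @param pzTol relative tolerance of the p-vs-z warning on the -log10 scale
#' @return a validated \linkS4class{GwasSumstats}; the number of dropped
#'   rows is attached as attribute \code{"dropped"}
#' @export
readSumstats <- function(path, columnMap = NULL, trait = "trait",
                         traitType = c("quantitative", "case-control"),
                         sdY = NA_real_, caseProp = NA_real_, sep = "\t",
                         pzTol = 1e-3) {
    traitType <- match.arg(traitType)
    map <- .DEFAULT_COLUMN_MAP
    if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
    raw <- read.delim(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
    mandatory <- setdiff(names(map), "eaf")
    missing <- map[mandatory][!map[mandatory] %in% names(raw)]
    if (length(missing))
        .stopf("configuration error: mandatory column(s) not found: %s",
               paste(missing, collapse = ", "))
    d <- data.frame(snp = as.character(raw[[map["snp"]]]),
                    chrom = as.character(raw[[map["chrom"]]]),
                    pos = suppressWarnings(as.integer(raw[[map["pos"]]])),
                    ea = toupper(as.character(raw[[map["ea"]]])),
                    oa = toupper(as.character(raw[[map["oa"]]])),
                    eaf = if (map["eaf"] %in% names(raw))
                        suppressWarnings(as.numeric(raw[[map["eaf"]]]))
                    else NA_real_,
                    beta = suppressWarnings(as.numeric(raw[[map["beta"]]])),
                    se = suppressWarnings(as.numeric(raw[[map["se"]]])),
                    pval = suppressWarnings(as.numeric(raw[[map["pval"]]])),
                    n = suppressWarnings(as.numeric(raw[[map["n"]]])),
                    stringsAsFactors = FALSE)
    ok <- !is.na(d$snp) & !is.na(d$pos) & !is.na(d$beta) & !is.na(d$se) &
        !is.na(d$pval) & !is.na(d$n) &
        d$se > 0 & d$pval > 0 & d$pval <= 1 & d$n > 0 &
        d$ea %in% c("A", "C", "G", "T") & d$oa %in% c("A", "C", "G", "T") &
        d$ea != d$oa &
        (is.na(d$eaf) | (d$eaf > 0 & d$eaf < 1))
    ok[ok][duplicated(d$snp[ok])] <- FALSE
    nDropped <- sum(!ok)
    if (nDropped)
        message(sprintf("readSumstats: dropped %d invalid row(s)", nDropped))
    d <- d[ok, , drop = FALSE]
    if (!nrow(d))
        .stopf("input error: no valid rows remain in '%s'", path)
    lp <- -log10(d$pval)
    lpz <- -log10(pmax(.zToP(d$beta / d$se), .Machine$double.xmin))
    rel <- abs(lp - lpz) / pmax(lpz, 1)
    if (any(rel > pzTol))
        .warnf("%d row(s) have p-values inconsistent with beta/se beyond relative tolerance %g",
               sum(rel > pzTol), pzTol)
    out <- gwasSumstats(d, trait = trait, traitType = traitType, sdY = sdY,
                        caseProp = caseProp)
    attr(out, "dropped") <- nDropped
    out
}

#' Write summary statistics in the package's TSV dialect
#'
#' @param x a \linkS4class{GwasSumstats}
#' @param path output file
#' @export
writeSumstats <- function(x, path) {
    stopifnot(is(x, "GwasSumstats"))
    d <- x@snps
    names(d) <- .DEFAULT_COLUMN_MAP[names(d)]
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Construct / read / write LD matrices
#'
#' An \linkS4class{LDMatrix} is a symmetric matrix of pairwise r-squared
#' values with unit diagonal and SNP ids as dimnames.  On disk it is a
#' square TSV with an id header row and a leading id column.
#'
#' @param m numeric matrix of r-squared values
#' @param ids SNP identifiers (defaults to existing dimnames)
#' @return an \linkS4class{LDMatrix}
#' @export
ldMatrix <- function(m, ids = rownames(m)) {
    m <- as.matrix(m)
    if (is.null(ids)) .stopf("LD matrix needs SNP ids")
    dimnames(m) <- list(ids, ids)
    new("LDMatrix", m)
}

#' @rdname ldMatrix
#' @param path file path
#' @export
readLDMatrix <- function(path) {
    m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
    colnames(m) <- rownames(m)
    ldMatrix(m)
}

#' @rdname ldMatrix
#' @param x an LDMatrix
#' @export
writeLDMatrix <- function(x, path) {
    stopifnot(is(x, "LDMatrix"))
    d <- data.frame(SNP = rownames(x), as.data.frame(x@.Data),
                    check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Define a drug-target locus
#'
#' Returns a length-1 \code{GRanges} on GRCh37 carrying the gene symbol and
#' the flanking cis window (kb) as metadata; coordinates are 1-based
#' inclusive.
#'
#' @param gene gene symbol
#' @param chrom chromosome
#' @param start,end gene body coordinates (1-based, GRCh37)
#' @param windowKb flank added on each side when slicing (default 500)
#' @return a \code{GRanges}
#' @export
targetLocus <- function(gene, chrom, start, end, windowKb = 500) {
    if (start > end) .stopf("locus start must be <= end")
    if (windowKb < 0) .stopf("windowKb must be >= 0")
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(chrom),
        ranges = IRanges::IRanges(start = start, end = end))
    S4Vectors::mcols(gr)$gene <- gene
    S4Vectors::mcols(gr)$window_kb <- windowKb
    gr
}

#' @rdname targetLocus
#' @details \code{glp1rLocus()} is GLP1R at 6:39,016,574-39,055,519
#'   (GRCh37); \code{giprLocus()} is GIPR at 19:46,171,479-46,185,705.
#' @export
glp1rLocus <- function(windowKb = 500)
    targetLocus("GLP1R", "6", 39016574L, 39055519L, windowKb)

#' @rdname targetLocus
#' @export
giprLocus <- function(windowKb = 500)
    targetLocus("GIPR", "19", 46171479L, 46185705L, windowKb)

#' Slice a cis window around a target locus
#'
#' Retains SNPs on the locus chromosome with position in
#' \code{[start - windowKb*1000, end + windowKb*1000]}, closed on both
#' ends.  The result is sorted by position (then id), so it is invariant
#' to input row order.  An empty result is allowed and returned empty.
#'
#' @param x a \linkS4class{GwasSumstats}
#' @param locus a \code{GRanges} from \code{\link{targetLocus}}
#' @return a \linkS4class{GwasSumstats} restricted to the window
#' @export
sliceLocus <- function(x, locus) {
    stopifnot(is(x, "GwasSumstats"), is(locus, "GRanges"),
              length(locus) == 1L)
    wkb <- S4Vectors::mcols(locus)$window_kb
    if (is.null(wkb)) wkb <- 0
    win <- IRanges::IRanges(
        start = max(1L, GenomicRanges::start(locus) - wkb * 1000),
        end = GenomicRanges::end(locus) + wkb * 1000)
    d <- x@snps
    d <- d[d$chrom == as.character(GenomicRanges::seqnames(locus)), ,
           drop = FALSE]
    hit <- IRanges::overlapsAny(IRanges::IRanges(d$pos, d$pos), win)
    d <- d[hit, , drop = FALSE]
    d <- d[order(d$pos, d$snp), , drop = FALSE]
    rownames(d) <- NULL
    if (!nrow(d))
        message(sprintf("sliceLocus: no SNPs in the %s window",
                        S4Vectors::mcols(locus)$gene))
    initialize(x, snps = d)
}

#' Harmonize two-sample summary statistics to a shared effect allele
#'
#' Aligns outcome records to the exposure's effect allele.  Swapped
#' alleles flip the outcome beta and complement its frequency; alleles
#' reported on the opposite strand are complemented first.  Palindromic
#' SNPs (A/T, C/G), for which strand cannot be resolved from allele
#' labels, are handled by \code{palindromePolicy}:
#' \describe{
#'   \item{freq}{(default) align by allele frequency when both traits have
#'     \code{min(f, 1-f) < freqThreshold}; drop as ambiguous otherwise or
#'     when the outcome frequency is missing}
#'   \item{drop}{always drop palindromic SNPs}
#'   \item{keep}{trust the reported labels}
#' }
#' Irreconcilable allele sets are dropped with reason
#' \code{"allele_mismatch"}.  The operation is idempotent.
#'
#' @param exposure,outcome \linkS4class{GwasSumstats} objects
#' @param palindromePolicy one of "freq", "drop", "keep"
#' @param freqThreshold ambiguity threshold on \code{min(f, 1-f)}
#'   (default 0.42)
#' @return a \linkS4class{HarmonizedPair}
#' @export
harmonizeSumstats <- function(exposure, outcome,
                              palindromePolicy = c("freq", "drop", "keep"),
                              freqThreshold = 0.42) {
    stopifnot(is(exposure, "GwasSumstats"), is(outcome, "GwasSumstats"))
    palindromePolicy <- match.arg(palindromePolicy)
    ex <- exposure@snps
    ou <- outcome@snps
    shared <- intersect(ex$snp, ou$snp)
    if (!length(shared))
        .stopf("no shared SNPs between exposure and outcome")
    ex <- ex[match(shared, ex$snp), ]
    ou <- ou[match(shared, ou$snp), ]

    n <- length(shared)
    action <- character(n)
    reason <- character(n)
    pal <- .isPalindromic(ex$ea, ex$oa)

    bY <- ou$beta; fY <- ou$eaf; eaY <- ou$ea; oaY <- ou$oa
    for (i in seq_len(n)) {
        eaX <- ex$ea[i]; oaX <- ex$oa[i]
        if (pal[i]) {
            if (palindromePolicy == "drop") {
                action[i] <- "dropped"; reason[i] <- "palindromic"; next
            }
            sameLabels <- eaY[i] == eaX && oaY[i] == oaX
            swapLabels <- eaY[i] == oaX && oaY[i] == eaX
            if (!sameLabels && !swapLabels) {
                action[i] <- "dropped"; reason[i] <- "allele_mismatch"; next
            }
            if (swapLabels) {  # express on the exposure's effect allele
                bY[i] <- -bY[i]
                fY[i] <- 1 - fY[i]
                eaY[i] <- eaX; oaY[i] <- oaX
            }
            if (palindromePolicy == "keep") {
                action[i] <- if (swapLabels) "flipped" else "kept"; next
            }
            if (is.na(fY[i])) {
                action[i] <- "dropped"; reason[i] <- "palindromic_no_eaf"
                next
            }
            ambiguous <- min(ex$eaf[i], 1 - ex$eaf[i]) >= freqThreshold ||
                min(fY[i], 1 - fY[i]) >= freqThreshold
            if (is.na(ex$eaf[i]) || ambiguous) {
                action[i] <- "dropped"; reason[i] <- "palindromic_ambiguous"
                next
            }
            if ((ex$eaf[i] - 0.5) * (fY[i] - 0.5) < 0) {
                # frequencies disagree: alleles were read off the other
                # strand, which for a palindrome is the swap
                bY[i] <- -bY[i]
                fY[i] <- 1 - fY[i]
                action[i] <- "flipped"
            } else {
                action[i] <- if (swapLabels) "flipped" else "kept"
            }
            next
        }
        ceaY <- unname(.complement(eaY[i])); coaY <- unname(.complement(oaY[i]))
        if (eaY[i] == eaX && oaY[i] == oaX) {
            action[i] <- "kept"
        } else if (eaY[i] == oaX && oaY[i] == eaX) {
            bY[i] <- -bY[i]; fY[i] <- 1 - fY[i]
            eaY[i] <- eaX; oaY[i] <- oaX
            action[i] <- "flipped"
        } else if (ceaY == eaX && coaY == oaX) {
            eaY[i] <- eaX; oaY[i] <- oaX       # strand complement only
            action[i] <- "kept"
        } else if (ceaY == oaX && coaY == eaX) {
            bY[i] <- -bY[i]; fY[i] <- 1 - fY[i]
            eaY[i] <- eaX; oaY[i] <- oaX
            action[i] <- "flipped"
        } else {
            action[i] <- "dropped"; reason[i] <- "allele_mismatch"
        }
    }

    keep <- action != "dropped"
    data <- data.frame(snp = shared, chrom = ex$chrom, pos = ex$pos,
                       ea = ex$ea, oa = ex$oa,
                       beta_x = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
                       n_x = ex$n, pval_x = ex$pval,
                       beta_y = bY, se_y = ou$se, eaf_y = fY,
                       n_y = ou$n, pval_y = ou$pval,
                       palindromic = pal, action = action,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(data) <- NULL
    dropped <- data.frame(snp = shared[!keep], reason = reason[!keep],
                          stringsAsFactors = FALSE)
    new("HarmonizedPair", data = data, dropped = dropped,
        exposure = exposure@trait, outcome = outcome@trait,
        outcomeType = outcome@traitType)
}

#' Write a harmonized pair to TSV
#' @param x a \linkS4class{HarmonizedPair}
#' @param path output file
#' @export
writeHarmonized <- function(x, path) {
    stopifnot(is(x, "HarmonizedPair"))
    write.table(x@data, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
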