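# Self-contained synthetic study corpus: two targets, two biomarkers
# with primary + replication sources, three outcomes, LD per locus, and
# a ready-to-run YAML study configuration.

#' Materialize a synthetic study fixture corpus
#'
#' Writes a complete small study to \code{dir}: exposure summary
#' statistics for BMI and HbA1c analogs (primary and replication
#' cohorts) spanning the GLP1R and GIPR cis windows, three outcome GWAS
#' (a quantitative binge-drinking score, a case-control heavy-drinking
#' classification, a quantitative liver-fat measure), per-locus LD
#' matrices, and \code{study.yaml} consumable by \code{\link{runStudy}}.
#' Outcome effects are generated from fixed per-biomarker causal effects
#' so every pipeline stage has signal to find.  Fully deterministic
#' given the seed.
#'
#' @param dir output directory (created if needed)
#' @param seed RNG seed
#' @return the path of the written YAML config, invisibly
#' @export
writeFixtureCorpus <- function(dir, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    lociDef <- list(
        GLP1R = list(gene = "GLP1R", chrom = "6", start = 39016574L,
                     end = 39055519L, window_kb = 500L),
        GIPR = list(gene = "GIPR", chrom = "19", start = 46171479L,
                    end = 46185705L, window_kb = 500L))
    # causal effect of each biomarker on each outcome (per 1 SD increase)
    thetaMap <- list(
        binge = c(BMI = 0.5, HbA1c = 0.1),
        heavy_drinking = c(BMI = 0.2, HbA1c = 0.6),
        liver_fat = c(BMI = 0.1, HbA1c = 0.4))
    outcomesDef <- list(
        binge = list(type = "quantitative", n = 4e5),
        heavy_drinking = list(type = "case-control", n = 3e5,
                              case_prop = 0.1),
        liver_fat = list(type = "quantitative", n = 3e5))
    biomarkers <- c("BMI", "HbA1c")
    sources <- c(primary = 3e5, replication = 2e5)

    scaffolds <- list(); cfgs <- list(); margs <- list()
    for (nm in names(lociDef)) {
        l <- lociDef[[nm]]
        cfg <- simConfig(nSnp = 30L, eafRange = c(0.1, 0.9), ldRho = 0.5,
                         ldBlockSize = 5L, chrom = l$chrom,
                         posStart = l$start - 100000L,
                         posEnd = l$end + 100000L)
        sc <- .simScaffold(cfg)
        sc$ids <- sprintf("rs%s%05d", l$chrom, seq_len(cfg$nSnp))
        dimnames(sc$R) <- list(sc$ids, sc$ids)
        scaffolds[[nm]] <- sc
        cfgs[[nm]] <- cfg
        for (bm in biomarkers) {
            causal <- sort(sample.int(cfg$nSnp, 4L))
            b <- numeric(cfg$nSnp)
            b[causal] <- sample(c(-1, 1), 4L, TRUE) * runif(4L, 1, 2) * 0.025
            margs[[paste(nm, bm)]] <- unname(drop(sc$R %*% b))
        }
        writeLDMatrix(ldMatrix(sc$R^2), file.path(dir,
                                                  sprintf("ld_%s.tsv", nm)))
    }

    combineLoci <- function(tables, trait, type, caseProp = NA_real_) {
        d <- do.call(rbind, lapply(tables, slot, "snps"))
        rownames(d) <- NULL
        gwasSumstats(d, trait = trait, traitType = type,
                     sdY = if (type == "quantitative") 1 else NA_real_,
                     caseProp = caseProp)
    }

    paths <- list()
    for (bm in biomarkers) {
        for (src in names(sources)) {
            tabs <- lapply(names(lociDef), function(nm)
                .simTable(scaffolds[[nm]], margs[[paste(nm, bm)]],
                          sources[[src]], cfgs[[nm]], bm, "quantitative"))
            p <- sprintf("%s_%s.tsv", tolower(bm), src)
            writeSumstats(combineLoci(tabs, bm, "quantitative"),
                          file.path(dir, p))
            paths[[paste(bm, src)]] <- p
        }
    }
    for (oc in names(outcomesDef)) {
        od <- outcomesDef[[oc]]
        tabs <- lapply(names(lociDef), function(nm) {
            marg <- Reduce(`+`, lapply(biomarkers, function(bm)
                thetaMap[[oc]][[bm]] * margs[[paste(nm, bm)]]))
            cfg <- cfgs[[nm]]
            cfg$caseProp <- if (is.null(od$case_prop)) 0.1 else od$case_prop
            .simTable(scaffolds[[nm]], marg, od$n, cfg, oc, od$type)
        })
        writeSumstats(combineLoci(tabs, oc, od$type,
                                  if (is.null(od$case_prop)) NA_real_
                                  else od$case_prop),
                      file.path(dir, sprintf("outcome_%s.tsv", oc)))
    }

    cfgOut <- list(
        seed = as.integer(seed),
        alpha = 0.05,
        n_tests = 20L,
        coloc_gate = 0.05,
        direction = "lowering",
        cascade = c(5e-8, 5e-6),
        r2_max = 0.1,
        loci = lapply(lociDef, function(l)
            l[c("gene", "chrom", "start", "end", "window_kb")]),
        ld = setNames(as.list(sprintf("ld_%s.tsv", names(lociDef))),
                      names(lociDef)),
        targets = list(
            list(name = "GLP1R", loci = list("GLP1R")),
            list(name = "GIPR/GLP1R", loci = list("GLP1R", "GIPR"))),
        biomarkers = lapply(biomarkers, function(bm) list(
            name = bm, type = "quantitative",
            sources = list(primary = paths[[paste(bm, "primary")]],
                           replication = paths[[paste(bm, "replication")]]))),
        outcomes = lapply(names(outcomesDef), function(oc) {
            od <- outcomesDef[[oc]]
            out <- list(label = oc,
                        path = sprintf("outcome_%s.tsv", oc),
                        type = od$type)
            if (!is.null(od$case_prop)) out$case_prop <- od$case_prop
            out
        }))
    yamlPath <- file.path(dir, "study.yaml")
    yaml::write_yaml(cfgOut, yamlPath)
    invisible(yamlPath)
}
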