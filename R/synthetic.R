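## Synthetic corpus with planted ground truth. Emulates the data shapes the
## pipeline consumes: multi-stage chromHMM segmentations with planted
## enhancer-origin classes, replicate H3K27ac and p52 peak files, a patient
## expression cohort with an elevated NF-kB signature subgroup, external-style
## differential tables, and HiChIP loops over planted EE/EP/PP feature pairs.
## Every file is plain text in the format the corresponding reader expects,
## and a fixed seed yields a byte-identical directory.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the standard study conditions: a 2 x 5 Mb toy genome, 200
#' genes, 500 one-kb loci with origin classes in equal proportions, three
#' samples per developmental stage, a 60-sample expression cohort with half
#' the samples carrying a 1.5-fold signature elevation, and 300 loops.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param nChroms,chromLength Number and length (bp) of toy chromosomes.
#' @param nGenes,nLoci Number of genes and of planted enhancer loci.
#' @param classProportions Named proportions over the five origin classes.
#' @param nSamplesPerGroup Samples per stage (B, PC, MM).
#' @param cohortSize,fractionNFkBPlus Expression cohort size and fraction of
#'   truly NF-kB+ samples.
#' @param signatureEffect Multiplicative shift of signature-gene expression in
#'   NF-kB+ samples (on the variance-stabilized scale).
#' @param exprNoiseSd Log-scale sd of multiplicative expression noise.
#' @param peakSignalNoiseSd Log-scale sd of replicate peak-signal noise.
#' @param nLoops Total number of loops.
#' @param loopTypeProportions Proportions of EE/EP/PP among assigned loops.
#' @param boundaryJitter Half-width (bp) of uniform jitter applied to active
#'   segmentation boundaries (0 = exact).
#' @param p52Fraction Fraction of p52-dependent enhancers co-occupied by p52.
#' @param depFraction Fraction of enhancer features depleted on p52 knockdown.
#' @param nClustersPerChrom Super-enhancer clusters planted per chromosome.
#' @return A validated config list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(seed = 1L, nChroms = 2L, chromLength = 5e6,
                            nGenes = 200L, nLoci = 500L,
                            classProportions = c(de_novo = 0.2,
                                                 reactivated = 0.2,
                                                 preserved = 0.2,
                                                 lost = 0.2, unknown = 0.2),
                            nSamplesPerGroup = c(B = 3L, PC = 3L, MM = 3L),
                            cohortSize = 60L, fractionNFkBPlus = 0.5,
                            signatureEffect = 1.5, exprNoiseSd = 0.15,
                            peakSignalNoiseSd = 0.1, nLoops = 300L,
                            loopTypeProportions = c(EE = 0.25, EP = 0.5,
                                                    PP = 0.25),
                            boundaryJitter = 0L, p52Fraction = 0.6,
                            depFraction = 0.4, nClustersPerChrom = 5L) {
    cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
                chromLength = chromLength, nGenes = as.integer(nGenes),
                nLoci = as.integer(nLoci),
                classProportions = classProportions,
                nSamplesPerGroup = nSamplesPerGroup,
                cohortSize = as.integer(cohortSize),
                fractionNFkBPlus = fractionNFkBPlus,
                signatureEffect = signatureEffect,
                exprNoiseSd = exprNoiseSd,
                peakSignalNoiseSd = peakSignalNoiseSd,
                nLoops = as.integer(nLoops),
                loopTypeProportions = loopTypeProportions,
                boundaryJitter = as.integer(boundaryJitter),
                p52Fraction = p52Fraction, depFraction = depFraction,
                nClustersPerChrom = as.integer(nClustersPerChrom))
    stopifnot(abs(sum(classProportions) - 1) < 1e-9,
              abs(sum(loopTypeProportions) - 1) < 1e-9,
              all(names(classProportions) ==
                  c("de_novo", "reactivated", "preserved", "lost", "unknown")),
              cfg$nSamplesPerGroup[["MM"]] >= 1L)
    locusPeriod <- 19000
    lociPerChrom <- ceiling(cfg$nLoci / cfg$nChroms)
    needed <- 30000 + lociPerChrom * locusPeriod + 20000 +
        cfg$nClustersPerChrom * 25000
    if (needed > cfg$chromLength)
        stop("chromLength too small for the requested loci/cluster layout (",
             needed, " bp needed)")
    class(cfg) <- "syntheticConfig"
    cfg
}

## deterministic genome layout (no RNG): loci, SE clusters and genes
syntheticLayout <- function(cfg) {
    period <- 19000; offset <- 30000; locusWidth <- 1000
    lociPerChrom <- ceiling(cfg$nLoci / cfg$nChroms)
    genesPerChrom <- ceiling(cfg$nGenes / cfg$nChroms)
    loci <- list(); clusters <- list(); constituents <- list(); genes <- list()
    nLociLeft <- cfg$nLoci; nGenesLeft <- cfg$nGenes
    for (ci in seq_len(cfg$nChroms)) {
        chrom <- paste0("chr", ci)
        nl <- min(lociPerChrom, nLociLeft); nLociLeft <- nLociLeft - nl
        starts0 <- offset + (seq_len(nl) - 1L) * period
        loci[[ci]] <- data.frame(
            unit_id = sprintf("locus_%s_%03d", chrom, seq_len(nl)),
            chrom = chrom, start0 = starts0, end0 = starts0 + locusWidth,
            stringsAsFactors = FALSE)
        clStart <- offset + lociPerChrom * period + 20000 +
            (seq_len(cfg$nClustersPerChrom) - 1L) * 25000
        clusters[[ci]] <- data.frame(
            unit_id = sprintf("cluster_%s_%d", chrom,
                              seq_len(cfg$nClustersPerChrom)),
            chrom = chrom, start0 = clStart, end0 = clStart + 9500,
            stringsAsFactors = FALSE)
        cons <- expand.grid(k = 0:3, cl = seq_len(cfg$nClustersPerChrom))
        constituents[[ci]] <- data.frame(
            unit_id = sprintf("cluster_%s_%d", chrom, cons$cl),
            chrom = chrom, start0 = clStart[cons$cl] + cons$k * 3000,
            end0 = clStart[cons$cl] + cons$k * 3000 + 500,
            stringsAsFactors = FALSE)
        ng <- min(genesPerChrom, nGenesLeft); nGenesLeft <- nGenesLeft - ng
        lidx <- floor((seq_len(ng) - 1L) * nl / ng)
        tss0 <- offset + lidx * period + 12000
        genes[[ci]] <- data.frame(
            gene_id = sprintf("GENE%s_%03d", ci, seq_len(ng)),
            chrom = chrom, tss0 = tss0,
            strand = rep_len(c("+", "-"), ng), stringsAsFactors = FALSE)
    }
    list(loci = do.call(rbind, loci), clusters = do.call(rbind, clusters),
         constituents = do.call(rbind, constituents),
         genes = do.call(rbind, genes))
}

writeTsv <- function(df, path, colNames = TRUE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = colNames)
    invisible(path)
}

## activity pattern (b, pc, mm) realizing a class; free slots drawn randomly
classToPattern <- function(cls) {
    switch(cls,
           de_novo = c(FALSE, FALSE, TRUE),
           reactivated = c(TRUE, FALSE, TRUE),
           preserved = c(stats::runif(1) < 0.5, TRUE, TRUE),
           lost = {
               variants <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE),
                                c(FALSE, TRUE, FALSE))
               variants[[sample.int(3L, 1L)]]
           },
           unknown = c(FALSE, FALSE, FALSE))
}

#' Generate the synthetic corpus
#'
#' Writes all pipeline inputs plus ground-truth tables to \code{outdir} and
#' returns the manifest and in-memory truth. See \code{syntheticConfig} for
#' the planted conditions. With a fixed seed the output directory is
#' byte-identical across runs.
#'
#' @param cfg A \code{syntheticConfig}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{manifest} (named file
#'   paths) and \code{truth} (list of ground-truth data.frames).
#' @export
generateSyntheticData <- function(cfg = syntheticConfig(), outdir) {
    stopifnot(inherits(cfg, "syntheticConfig"))
    if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
        stop("cannot create output directory: ", outdir)
    set.seed(cfg$seed)
    lay <- syntheticLayout(cfg)
    units <- rbind(lay$loci, lay$clusters)
    nUnits <- nrow(units)

    ## --- planted origin classes and stage activity -------------------------
    classes <- sample(names(cfg$classProportions), nUnits, replace = TRUE,
                      prob = cfg$classProportions)
    pat <- t(vapply(classes, classToPattern, logical(3L)))
    truthUnits <- data.frame(units, b_active = pat[, 1L],
                             pc_active = pat[, 2L], mm_active = pat[, 3L],
                             stabilo_class = classes, stringsAsFactors = FALSE)

    ## --- segmentations: per-sample BED4 realizing the any-sample rule ------
    groups <- rep(c("B", "PC", "MM"), cfg$nSamplesPerGroup[c("B", "PC", "MM")])
    sampleIds <- sprintf("%s%d", groups,
                         unlist(lapply(cfg$nSamplesPerGroup[c("B", "PC", "MM")],
                                       seq_len)))
    groupCol <- c(B = 1L, PC = 2L, MM = 3L)
    ## active sample subsets per unit x group (at least one when group active)
    activeMat <- matrix(FALSE, nrow = nUnits, ncol = length(sampleIds))
    for (u in seq_len(nUnits)) {
        for (g in c("B", "PC", "MM")) {
            idx <- which(groups == g)
            if (!pat[u, groupCol[[g]]]) next
            on <- stats::rbinom(length(idx), 1L, 0.6) == 1L
            if (!any(on)) on[sample.int(length(idx), 1L)] <- TRUE
            activeMat[u, idx[on]] <- TRUE
        }
    }
    segDir <- file.path(outdir, "segmentations")
    dir.create(segDir, showWarnings = FALSE)
    segPaths <- character(length(sampleIds))
    for (s in seq_along(sampleIds)) {
        st <- character(nUnits); a0 <- units$start0; e0 <- units$end0
        for (u in seq_len(nUnits)) {
            if (activeMat[u, s]) {
                st[u] <- paste0(sample(c("E9", "E10"), 1L), "_EnhA")
                if (cfg$boundaryJitter > 0L) {
                    j <- cfg$boundaryJitter
                    a0[u] <- max(0L, units$start0[u] +
                                 sample.int(2L * j + 1L, 1L) - j - 1L)
                    e0[u] <- units$end0[u] + sample.int(2L * j + 1L, 1L) - j - 1L
                }
            } else {
                st[u] <- "E1_Low"
            }
        }
        segPaths[s] <- file.path(segDir, paste0(sampleIds[s], ".bed"))
        writeTsv(data.frame(units$chrom, a0, e0, st), segPaths[s],
                 colNames = FALSE)
    }
    ## manifests carry paths relative to the corpus directory so a fixed
    ## seed yields byte-identical output wherever the corpus lives
    segManifest <- data.frame(sample = sampleIds, group = groups,
                              path = file.path("segmentations",
                                               basename(segPaths)),
                              stringsAsFactors = FALSE)
    segManifestPath <- file.path(outdir, "segmentation_manifest.tsv")
    writeTsv(segManifest, segManifestPath)

    ## --- gene models (GTF) -------------------------------------------------
    gtfPath <- file.path(outdir, "genes.gtf")
    writeGtf(lay$genes, gtfPath)

    ## --- enhancer features: mm-active loci + all cluster constituents ------
    isLocus <- grepl("^locus_", units$unit_id)
    lociFeat <- units[isLocus & pat[, 3L], , drop = FALSE]
    featDf <- rbind(
        data.frame(unit_id = lociFeat$unit_id, chrom = lociFeat$chrom,
                   start0 = lociFeat$start0 + 250L,
                   end0 = lociFeat$start0 + 750L, stringsAsFactors = FALSE),
        lay$constituents)
    featDf$peak_id <- sprintf("enh_%s_%d", featDf$chrom, featDf$start0)
    featDf <- featDf[order(featDf$chrom, featDf$start0), ]
    rownames(featDf) <- NULL
    featDf$is_cluster <- grepl("^cluster_", featDf$unit_id)
    featDf$mid0 <- featDf$start0 + 250L
    featDf$class <- truthUnits$stabilo_class[match(featDf$unit_id,
                                                   truthUnits$unit_id)]

    ## --- planted differential effects on enhancers -------------------------
    nFeat <- nrow(featDf)
    featDf$dependent <- stats::runif(nFeat) < cfg$depFraction
    featDf$enh_log2fc <- ifelse(featDf$dependent,
                                -abs(stats::rnorm(nFeat, 1.5, 0.4)),
                                stats::rnorm(nFeat, 0, 0.2))
    up <- !featDf$dependent & stats::runif(nFeat) < 0.15
    featDf$enh_log2fc[up] <- abs(stats::rnorm(sum(up), 1, 0.3))
    featDf$enh_sig <- featDf$dependent | up
    featDf$enh_fdr <- ifelse(featDf$enh_sig, stats::runif(nFeat, 0, 0.05),
                             stats::runif(nFeat, 0.2, 1))
    featDf$p52_bound <- ifelse(featDf$dependent,
                               stats::runif(nFeat) < cfg$p52Fraction,
                               stats::runif(nFeat) < 0.2)

    ## --- replicate peak files (H3K27ac WT/KD, p52) -------------------------
    ## replicate peak = full unit interval for loci, constituent for clusters
    repPeakDf <- featDf
    repPeakDf$pk_start0 <- ifelse(featDf$is_cluster, featDf$start0,
                                  featDf$start0 - 250L)
    repPeakDf$pk_end0 <- ifelse(featDf$is_cluster, featDf$end0,
                                featDf$end0 + 250L)
    ## super-enhancer constituents carry an order of magnitude more signal
    ## than typical enhancers, the hallmark the tangent cutoff detects
    base <- ifelse(featDf$is_cluster, stats::runif(nFeat, 300, 500),
                   stats::runif(nFeat, 5, 15))
    peakDir <- file.path(outdir, "peaks")
    dir.create(peakDir, showWarnings = FALSE)
    h3kPaths <- list()
    for (cond in c("wt", "kd")) {
        mult <- if (cond == "kd") 2^featDf$enh_log2fc else rep(1, nFeat)
        for (r in 1:3) {
            sig <- base * mult * exp(stats::rnorm(nFeat, 0,
                                                  cfg$peakSignalNoiseSd))
            p <- file.path(peakDir, sprintf("h3k27ac_%s_rep%d.bed", cond, r))
            writeTsv(data.frame(repPeakDf$chrom, repPeakDf$pk_start0,
                                repPeakDf$pk_end0,
                                sprintf("pk%04d", seq_len(nFeat)),
                                round(sig, 4)), p, colNames = FALSE)
            h3kPaths[[sprintf("h3k27ac_%s_rep%d", cond, r)]] <- p
        }
    }
    p52Paths <- list()
    p52Feat <- featDf[featDf$p52_bound, , drop = FALSE]
    for (r in 1:2) {
        sig <- stats::runif(nrow(p52Feat), 10, 40)
        p <- file.path(peakDir, sprintf("p52_rep%d.bed", r))
        writeTsv(data.frame(p52Feat$chrom, p52Feat$mid0 - 200L,
                            p52Feat$mid0 + 200L,
                            sprintf("p52_%04d", seq_len(nrow(p52Feat))),
                            round(sig, 4)), p, colNames = FALSE)
        p52Paths[[sprintf("p52_rep%d", r)]] <- p
    }

    ## --- expression cohort -------------------------------------------------
    geneIds <- lay$genes$gene_id
    allRows <- c(nfkbSignatureGenes, geneIds)
    nPlus <- round(cfg$cohortSize * cfg$fractionNFkBPlus)
    cohortGroups <- rep(c("NFkB_plus", "NFkB_minus"),
                        c(nPlus, cfg$cohortSize - nPlus))
    cohortIds <- sprintf("PT%03d", seq_len(cfg$cohortSize))
    baseline <- stats::runif(length(allRows), 5, 12)
    expr <- baseline * exp(matrix(stats::rnorm(length(allRows) *
                                               cfg$cohortSize, 0,
                                               cfg$exprNoiseSd),
                                  nrow = length(allRows)))
    sigRows <- seq_along(nfkbSignatureGenes)
    expr[sigRows, cohortGroups == "NFkB_plus"] <-
        expr[sigRows, cohortGroups == "NFkB_plus"] * cfg$signatureEffect
    dimnames(expr) <- list(allRows, cohortIds)
    exprPath <- file.path(outdir, "expression.tsv")
    writeTsv(data.frame(gene = allRows, expr, check.names = FALSE), exprPath)

    ## --- gene expression dynamics (KD vs WT) and target mapping ------------
    depFeat <- which(featDf$dependent)
    targetGene <- rep(NA_integer_, nFeat)
    for (fi in depFeat) {
        cand <- which(lay$genes$chrom == featDf$chrom[fi] &
                      abs(lay$genes$tss0 - featDf$mid0[fi]) > 10500 &
                      abs(lay$genes$tss0 - featDf$mid0[fi]) <= 1.9e6)
        if (length(cand))
            targetGene[fi] <- cand[sample.int(length(cand), 1L)]
    }
    nGenesAll <- nrow(lay$genes)
    geneL2fc <- stats::rnorm(nGenesAll, 0, 0.15)
    geneFdr <- stats::runif(nGenesAll, 0.2, 1)
    isTarget <- seq_len(nGenesAll) %in% targetGene[!is.na(targetGene)]
    for (g in which(isTarget)) {
        partners <- featDf$enh_log2fc[which(targetGene == g)]
        geneL2fc[g] <- 0.8 * mean(partners) + stats::rnorm(1L, 0, 0.25)
        geneFdr[g] <- stats::runif(1L, 0, 0.05)
    }
    enhDiffPath <- file.path(outdir, "enhancer_diff.tsv")
    writeTsv(data.frame(feature_id = featDf$peak_id,
                        log2fc = featDf$enh_log2fc,
                        pvalue = featDf$enh_fdr / 2, fdr = featDf$enh_fdr),
             enhDiffPath)
    exprDiffPath <- file.path(outdir, "expression_diff.tsv")
    writeTsv(data.frame(feature_id = geneIds, log2fc = geneL2fc,
                        pvalue = geneFdr / 2, fdr = geneFdr), exprDiffPath)

    ## --- patient enrichment tables and essential genes ---------------------
    epiEnriched <- featDf$dependent & stats::runif(nFeat) < 0.7
    epiL2fc <- ifelse(epiEnriched, abs(stats::rnorm(nFeat, 1, 0.3)),
                      stats::rnorm(nFeat, 0, 0.2))
    epiFdr <- ifelse(epiEnriched, stats::runif(nFeat, 0, 0.05),
                     stats::runif(nFeat, 0.2, 1))
    patientEpiPath <- file.path(outdir, "patient_epigenome.tsv")
    writeTsv(data.frame(feature_id = featDf$peak_id, log2fc = epiL2fc,
                        pvalue = epiFdr / 2, fdr = epiFdr), patientEpiPath)
    gexEnriched <- stats::runif(nGenesAll) < 0.3
    gexL2fc <- ifelse(gexEnriched, abs(stats::rnorm(nGenesAll, 1, 0.3)),
                      stats::rnorm(nGenesAll, 0, 0.2))
    gexFdr <- ifelse(gexEnriched, stats::runif(nGenesAll, 0, 0.05),
                     stats::runif(nGenesAll, 0.2, 1))
    patientGexPath <- file.path(outdir, "patient_expression.tsv")
    writeTsv(data.frame(feature_id = geneIds, log2fc = gexL2fc,
                        pvalue = gexFdr / 2, fdr = gexFdr), patientGexPath)
    essential <- sort(sample(geneIds, max(1L, round(nGenesAll * 0.1))))
    essentialPath <- file.path(outdir, "essential_genes.txt")
    writeLines(essential, essentialPath)

    ## --- loops --------------------------------------------------------------
    nUn <- round(cfg$nLoops * 0.05)
    nAssigned <- cfg$nLoops - nUn
    nEE <- round(nAssigned * cfg$loopTypeProportions[["EE"]])
    nPP <- round(nAssigned * cfg$loopTypeProportions[["PP"]])
    nEP <- nAssigned - nEE - nPP
    inWindow <- function(d) d > 10500 & d <= 1.9e6
    pickPartner <- function(mid, chrom, mids, chroms) {
        cand <- which(chroms == chrom & inWindow(abs(mids - mid)))
        if (length(cand) == 0L) NA_integer_
        else cand[sample.int(length(cand), 1L)]
    }
    loops <- list(); li <- 0L
    addLoop <- function(type, m1chrom, m1, m2, f1, f2, diff, sign) {
        li <<- li + 1L
        if (diff) {
            l2fc <- sign * abs(stats::rnorm(1L, 1.2, 0.3))
            fdr <- stats::runif(1L, 0, 0.05)
        } else {
            l2fc <- stats::rnorm(1L, 0, 0.1)
            fdr <- stats::runif(1L, 0.2, 0.9)
        }
        ca <- stats::rpois(1L, 50) + 5L
        cb <- max(1L, round(ca * 2^l2fc))
        loops[[li]] <<- data.frame(
            loop_id = sprintf("loop_%04d", li), type = type,
            chrom = m1chrom, mid1 = m1, mid2 = m2,
            feature1 = f1, feature2 = f2,
            contact_a = ca, contact_b = cb,
            log2fc = l2fc, fdr = fdr, stringsAsFactors = FALSE)
    }
    ## EP loops: half over dependent enhancers with their target gene
    depWithTarget <- which(featDf$dependent & !is.na(targetGene))
    for (k in seq_len(nEP)) {
        useDep <- length(depWithTarget) > 0L && stats::runif(1L) < 0.5
        if (useDep) {
            fi <- depWithTarget[sample.int(length(depWithTarget), 1L)]
            gi <- targetGene[fi]
            addLoop("EP", featDf$chrom[fi], featDf$mid0[fi],
                    lay$genes$tss0[gi], featDf$peak_id[fi],
                    lay$genes$gene_id[gi], diff = TRUE, sign = -1)
        } else {
            ## background EP loops connect unaffected enhancers to
            ## unaffected genes, so planted concordance lives only in the
            ## dependent enhancer / target-gene pairs
            nonDep <- which(!featDf$dependent)
            fi <- nonDep[sample.int(length(nonDep), 1L)]
            tssPool <- lay$genes$tss0
            tssPool[isTarget] <- NA
            gi <- pickPartner(featDf$mid0[fi], featDf$chrom[fi],
                              tssPool, lay$genes$chrom)
            if (is.na(gi)) next
            diff <- stats::runif(1L) < 0.69
            addLoop("EP", featDf$chrom[fi], featDf$mid0[fi],
                    lay$genes$tss0[gi], featDf$peak_id[fi],
                    lay$genes$gene_id[gi], diff = diff,
                    sign = if (stats::runif(1L) < 2 / 3) -1 else 1)
        }
    }
    for (k in seq_len(nEE)) {
        fi <- sample.int(nFeat, 1L)
        fj <- pickPartner(featDf$mid0[fi], featDf$chrom[fi], featDf$mid0,
                          featDf$chrom)
        if (is.na(fj)) next
        diff <- stats::runif(1L) < 0.69
        addLoop("EE", featDf$chrom[fi], featDf$mid0[fi], featDf$mid0[fj],
                featDf$peak_id[fi], featDf$peak_id[fj], diff = diff,
                sign = if (stats::runif(1L) < 2 / 3) -1 else 1)
    }
    for (k in seq_len(nPP)) {
        gi <- sample.int(nGenesAll, 1L)
        gj <- pickPartner(lay$genes$tss0[gi], lay$genes$chrom[gi],
                          lay$genes$tss0, lay$genes$chrom)
        if (is.na(gj)) next
        diff <- stats::runif(1L) < 0.69
        addLoop("PP", lay$genes$chrom[gi], lay$genes$tss0[gi],
                lay$genes$tss0[gj], lay$genes$gene_id[gi],
                lay$genes$gene_id[gj], diff = diff,
                sign = if (stats::runif(1L) < 2 / 3) -1 else 1)
    }
    ## unassigned loops anchored in feature-free positions (5 kb into a unit
    ## gap, > 2.5 kb from any TSS, locus or promoter)
    isLocusUnit <- which(grepl("^locus_", units$unit_id))
    for (k in seq_len(nUn)) {
        u <- isLocusUnit[sample.int(length(isLocusUnit), 1L)]
        m1 <- units$start0[u] + 5000
        v <- pickPartner(m1, units$chrom[u], units$start0[isLocusUnit] + 5000,
                         units$chrom[isLocusUnit])
        if (is.na(v)) next
        m2 <- units$start0[isLocusUnit[v]] + 5000
        addLoop("unassigned", units$chrom[u], m1, m2, NA_character_,
                NA_character_, diff = TRUE,
                sign = if (stats::runif(1L) < 2 / 3) -1 else 1)
    }
    loopDf <- do.call(rbind, loops)
    loopsPath <- file.path(outdir, "loops.bedpe")
    writeTsv(data.frame(loopDf$chrom, loopDf$mid1 - 1250L,
                        loopDf$mid1 + 1250L, loopDf$chrom,
                        loopDf$mid2 - 1250L, loopDf$mid2 + 1250L,
                        loopDf$loop_id, ".", ".", ".",
                        loopDf$contact_a, loopDf$contact_b,
                        loopDf$log2fc, loopDf$fdr), loopsPath,
             colNames = FALSE)

    ## --- ground truth -------------------------------------------------------
    truthDir <- file.path(outdir, "truth")
    dir.create(truthDir, showWarnings = FALSE)
    truthFeatures <- data.frame(
        peak_id = featDf$peak_id, unit_id = featDf$unit_id,
        stabilo_class = featDf$class, p52_bound = featDf$p52_bound,
        se_member = featDf$is_cluster, dependent = featDf$dependent,
        nfkb_enriched_epigenome = epiEnriched, stringsAsFactors = FALSE)
    truthCohort <- data.frame(sample = cohortIds, group = cohortGroups,
                              stringsAsFactors = FALSE)
    truthSE <- lay$clusters
    truthLoops <- loopDf[, c("loop_id", "type", "feature1", "feature2",
                             "log2fc", "fdr")]
    truthLoops$differential <- truthLoops$fdr <= 0.1
    ## expected master table: differential EP loops joined from the plantings
    epDiff <- loopDf[loopDf$type == "EP" & loopDf$fdr <= 0.1, , drop = FALSE]
    fIdx <- match(epDiff$feature1, featDf$peak_id)
    gIdx <- match(epDiff$feature2, lay$genes$gene_id)
    truthMaster <- data.frame(
        enhancer_id = epDiff$feature1, gene_id = epDiff$feature2,
        loop_id = epDiff$loop_id, loop_log2fc = epDiff$log2fc,
        loop_fdr = epDiff$fdr, enh_log2fc = featDf$enh_log2fc[fIdx],
        enh_fdr = featDf$enh_fdr[fIdx], gene_log2fc = geneL2fc[gIdx],
        gene_fdr = geneFdr[gIdx], p52_bound = featDf$p52_bound[fIdx],
        se_member = featDf$is_cluster[fIdx],
        stabilo_class = featDf$class[fIdx],
        nfkb_enriched_epigenome = epiEnriched[fIdx],
        nfkb_enriched_expression = gexEnriched[gIdx],
        essential = epDiff$feature2 %in% essential,
        stringsAsFactors = FALSE)
    truth <- list(units = truthUnits, features = truthFeatures,
                  cohort = truthCohort, se = truthSE, loops = truthLoops,
                  master = truthMaster)
    writeTsv(truthUnits, file.path(truthDir, "truth_units.tsv"))
    writeTsv(truthFeatures, file.path(truthDir, "truth_features.tsv"))
    writeTsv(truthCohort, file.path(truthDir, "truth_cohort.tsv"))
    writeTsv(truthSE, file.path(truthDir, "truth_se.tsv"))
    writeTsv(truthLoops, file.path(truthDir, "truth_loops.tsv"))
    writeTsv(truthMaster, file.path(truthDir, "truth_master.tsv"))

    manifest <- c(list(genes_gtf = gtfPath, expression = exprPath,
                       segmentation_manifest = segManifestPath,
                       loops = loopsPath, enhancer_diff = enhDiffPath,
                       expression_diff = exprDiffPath,
                       patient_epigenome = patientEpiPath,
                       patient_expression = patientGexPath,
                       essential_genes = essentialPath),
                  h3kPaths, p52Paths)
    manifestPath <- file.path(outdir, "manifest.tsv")
    relPaths <- sub(paste0("^", normalizePath(outdir), "/"), "",
                    normalizePath(unlist(manifest, use.names = FALSE)))
    writeTsv(data.frame(key = names(manifest), path = relPaths),
             manifestPath)
    invisible(list(dir = outdir, manifest = manifest,
                   manifest_path = manifestPath, truth = truth))
}

writeGtf <- function(genesDf, path) {
    rows <- character(0L)
    for (i in seq_len(nrow(genesDf))) {
        tss0 <- genesDf$tss0[i]; strand <- genesDf$strand[i]
        if (strand == "+") {
            gs <- tss0 + 1L; ge <- tss0 + 2000L
            ex <- list(c(gs, gs + 299L), c(ge - 499L, ge))
        } else {
            ge <- tss0 + 1L; gs <- ge - 1999L
            ex <- list(c(ge - 299L, ge), c(gs, gs + 499L))
        }
        attr <- sprintf('gene_id "%s";', genesDf$gene_id[i])
        rows <- c(rows,
                  paste(genesDf$chrom[i], "synthetic", "gene", gs, ge, ".",
                        strand, ".", attr, sep = "\t"),
                  vapply(ex, function(e)
                      paste(genesDf$chrom[i], "synthetic", "exon", e[1L],
                            e[2L], ".", strand, ".", attr, sep = "\t"), ""))
    }
    writeLines(rows, path)
    invisible(path)
}
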