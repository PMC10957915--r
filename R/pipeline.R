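## End-to-end orchestration: consensus peaks -> NF-kB index || STABILO ||
## super-enhancers -> loop integration and the master table, with a run log,
## parameter echo and input checksums. Deterministic for fixed inputs.

#' Default pipeline parameters
#'
#' All numeric constants of the integrative analysis with their standard
#' values: 12500 bp stitching, 2500 bp TSS exclusion, 500 bp consensus peaks
#' supported by >= 2 replicates, 50\% state overlap, -2000/+500 promoters,
#' FDR 0.1 thresholds, active states E9/E10.
#'
#' @return Named list of parameters.
#' @export
pipelineParams <- function() {
    list(stitchDistance = 12500L, tssExclusion = 2500L,
         consensusWidth = 500L, minSupport = 2L, minOverlapFraction = 0.5,
         fdrThreshold = 0.1, promoterUp = 2000L, promoterDown = 500L,
         nearestN = 5L, activeStates = c("E9", "E10"))
}

## manifest paths may be relative to the manifest's own directory
resolvePaths <- function(paths, base) {
    rel <- !startsWith(paths, "/")
    paths[rel] <- file.path(base, paths[rel])
    paths
}

readManifest <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    stats::setNames(as.list(resolvePaths(df$path, dirname(path))), df$key)
}

logLine <- function(con, ...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, con)
}

#' Run the integrative pipeline end to end
#'
#' Executes the stages in dependency order: consensus-peak construction and
#' gene-model loading; NF-kB indexing of the expression cohort;
#' enhancer-origin (STABILO) classification of the enhancer features;
#' per-sample super-enhancer calling with consensus construction; and loop
#' integration producing the enhancer-promoter master table and summaries.
#' Any stage error aborts with the stage name. Reruns on identical inputs
#' produce identical outputs (no randomness is involved).
#'
#' @param manifest Path to a manifest TSV (columns \code{key}, \code{path};
#'   as written by \code{generateSyntheticData}) or a named list of paths.
#' @param outdir Output directory.
#' @param params Pipeline parameters; see \code{pipelineParams}.
#' @return Invisibly, a list with the main in-memory results
#'   (\code{features}, \code{index}, \code{stabilo}, \code{consensus_se},
#'   \code{master}, \code{summaries}) and \code{outdir}.
#' @export
runPipeline <- function(manifest, outdir, params = pipelineParams()) {
    if (is.character(manifest) && length(manifest) == 1L)
        manifest <- readManifest(manifest)
    p <- utils::modifyList(pipelineParams(), params)
    if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
        stop("cannot create output directory: ", outdir)
    logCon <- file(file.path(outdir, "run.log"), open = "wt")
    on.exit(close(logCon))
    logLine(logCon, "parameters: ",
            paste(names(p), vapply(p, function(x) paste(x, collapse = ","),
                                   ""), sep = "=", collapse = "; "))
    inputs <- unlist(manifest[vapply(manifest, is.character, TRUE)])
    sums <- tools::md5sum(inputs[file.exists(inputs)])
    for (f in names(sums))
        logLine(logCon, "input ", f, " md5=", sums[[f]])

    stage <- function(name, expr) {
        logLine(logCon, "stage ", name, " start")
        res <- tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        logLine(logCon, "stage ", name, " done")
        res
    }
    need <- function(key) {
        if (is.null(manifest[[key]]))
            stop("manifest entry '", key, "' is required")
        manifest[[key]]
    }

    ## ------- intervals: gene models, consensus enhancer and p52 peaks ------
    iv <- stage("intervals", {
        gm <- readGeneModels(need("genes_gtf"))
        wtKeys <- grep("^h3k27ac_wt_", names(manifest), value = TRUE)
        if (length(wtKeys) == 0L)
            stop("no h3k27ac_wt_* replicate peak files in manifest")
        reps <- lapply(wtKeys, function(k)
            readPeakBED(manifest[[k]], sampleId = k))
        names(reps) <- wtKeys
        features <- consensusPeaks(reps, minSupport = p$minSupport,
                                   consensusWidth = p$consensusWidth)
        mcols(features)$feature_class <- annotateFeatureClass(
            features, gm$genes, gm$exons, p$promoterUp, p$promoterDown)
        p52Keys <- grep("^p52_", names(manifest), value = TRUE)
        p52 <- GRanges()
        if (length(p52Keys) > 0L) {
            p52reps <- lapply(p52Keys, function(k)
                readPeakBED(manifest[[k]], sampleId = k))
            p52 <- consensusPeaks(p52reps,
                                  minSupport = min(p$minSupport,
                                                   length(p52reps)),
                                  consensusWidth = p$consensusWidth)
        }
        writeBED(features, file.path(outdir, "enhancer_features.bed"),
                 extraCols = c("peak_id", "support", "feature_class"))
        writeBED(p52, file.path(outdir, "p52_consensus.bed"),
                 extraCols = c("peak_id", "support"))
        list(gm = gm, reps = reps, features = features, p52 = p52)
    })

    ## ------- NF-kB index ----------------------------------------------------
    index <- stage("nfkb_index", {
        expr <- readExpressionMatrix(need("expression"))
        res <- nfkbIndex(expr)
        writeIndexResult(res, file.path(outdir, "nfkb_index.tsv"))
        res
    })

    ## ------- STABILO --------------------------------------------------------
    stab <- stage("stabilo", {
        man <- readSampleManifest(need("segmentation_manifest"))
        segs <- GRangesList(lapply(man$path, readSegmentationBED))
        names(segs) <- man$sample
        segset <- SegmentationSet(segs, man$group)
        calls <- stabiloClassify(iv$features, segset,
                                 activeStates = p$activeStates,
                                 minFraction = p$minOverlapFraction)
        df <- data.frame(peak_id = calls$peak_id, b_active = calls$b_active,
                         pc_active = calls$pc_active,
                         mm_active = calls$mm_active,
                         stabilo_class = as.character(calls$stabilo_class),
                         dormant = calls$dormant)
        writeTsv(df, file.path(outdir, "stabilo_features.tsv"))
        calls
    })

    ## ------- super-enhancers ------------------------------------------------
    se <- stage("superenhancer", {
        perSample <- lapply(iv$reps, function(pk)
            callSuperEnhancers(pk, iv$gm$genes,
                               stitchDistance = p$stitchDistance,
                               tssExclusion = p$tssExclusion))
        for (s in names(perSample)) {
            regions <- perSample[[s]]
            writeBED(regions, file.path(outdir,
                                        paste0("se_regions_", s, ".bed")),
                     extraCols = c("signal", "rank", "is_super"))
        }
        superOnly <- lapply(perSample, function(r) r[r$is_super])
        cons <- consensusSE(superOnly, minFraction = p$minOverlapFraction)
        asg <- assignConstituents(cons, iv$features)
        writeBED(asg$ses, file.path(outdir, "consensus_se.bed"),
                 extraCols = c("se_id", "member_samples"))
        list(perSample = perSample, consensus = asg$ses,
             features = asg$peaks)
    })

    ## ------- loop integration ----------------------------------------------
    loopRes <- stage("loop_integration", {
        loopsAll <- readLoopsBEDPE(need("loops"))
        fdr <- loopData(loopsAll)$fdr
        loopsDiff <- loopsAll[fdr <= p$fdrThreshold]
        proms <- promoterWindows(iv$gm$genes, up = p$promoterUp,
                                 down = p$promoterDown)
        pairs <- classifyLoops(loopsDiff, iv$features, proms)
        writeTsv(pairs, file.path(outdir, "loop_pairs.tsv"))
        enhDiff <- readDiffTable(need("enhancer_diff"))
        exprDiff <- readDiffTable(need("expression_diff"))
        patEpi <- if (!is.null(manifest$patient_epigenome))
            readDiffTable(manifest$patient_epigenome) else NULL
        patGex <- if (!is.null(manifest$patient_expression))
            readDiffTable(manifest$patient_expression) else NULL
        essential <- if (!is.null(manifest$essential_genes))
            readLines(manifest$essential_genes) else character()
        master <- buildMasterTable(pairs, iv$features, enhDiff, exprDiff,
                                   p52Peaks = iv$p52,
                                   consensusSEs = se$consensus,
                                   stabiloCalls = stab,
                                   patientEpigenome = patEpi,
                                   patientExpression = patGex,
                                   essentialGenes = essential,
                                   enrichFdr = p$fdrThreshold)
        writeTsv(master, file.path(outdir, "master_table.tsv"))
        diffSum <- loopDiffSummary(loopsAll, loopsDiff)
        conc <- if (nrow(master) >= 3L)
            concordanceSummary(master, fdrThreshold = p$fdrThreshold)
        else NULL
        summaries <- data.frame(
            key = c("n_loops_total", "n_loops_differential",
                    "pct_loops_differential", "frac_loops_negative",
                    "n_master_rows", "concordance_pearson",
                    "concordance_spearman"),
            value = c(diffSum$n_total, diffSum$n_diff, diffSum$percent,
                      diffSum$frac_negative, nrow(master),
                      if (is.null(conc)) NA_real_ else conc$pearson,
                      if (is.null(conc)) NA_real_ else conc$spearman))
        writeTsv(summaries, file.path(outdir, "summary.tsv"))
        list(all = loopsAll, differential = loopsDiff, pairs = pairs,
             master = master, diffSummary = diffSum, concordance = conc)
    })

    logLine(logCon, "pipeline complete")
    invisible(list(features = se$features, index = index, stabilo = stab,
                   perSampleSE = se$perSample, consensus_se = se$consensus,
                   pairs = loopRes$pairs, master = loopRes$master,
                   summaries = list(loops = loopRes$diffSummary,
                                    concordance = loopRes$concordance),
                   outdir = outdir))
}

eqField <- function(a, b, tol = 1e-9) {
    if (is.numeric(a)) {
        same <- abs(a - b) <= tol
        same[is.na(a) & is.na(b)] <- TRUE
        same[xor(is.na(a), is.na(b))] <- FALSE
        same
    } else {
        same <- as.character(a) == as.character(b)
        same[is.na(a) & is.na(b)] <- TRUE
        same[xor(is.na(a), is.na(b))] <- FALSE
        same
    }
}

#' Validate pipeline outputs against generator ground truth
#'
#' Computes exact-match agreement rates per stage (enhancer-origin class,
#' NF-kB group, super-enhancer status, loop type, master-table rows) and
#' compares them with configurable thresholds. Identifier-space mismatches
#' raise a structural error rather than scoring low.
#'
#' @param pipelineOut The list returned by \code{runPipeline}, or the
#'   pipeline output directory.
#' @param truth The \code{truth} list returned by
#'   \code{generateSyntheticData}, or the generator's \code{truth/}
#'   directory.
#' @param thresholds Named list of minimum agreement rates.
#' @return A list with per-stage \code{rates}, per-stage \code{pass} flags
#'   and \code{all_pass}.
#' @export
validateAgainstTruth <- function(pipelineOut, truth,
                                 thresholds = list(stabilo = 0.95,
                                                   nfkb = 0.95, se = 0.95,
                                                   loops = 0.95,
                                                   master = 1.0)) {
    if (is.character(truth)) {
        rd <- function(f) utils::read.table(file.path(truth, f), sep = "\t",
                                            header = TRUE,
                                            stringsAsFactors = FALSE)
        truth <- list(units = rd("truth_units.tsv"),
                      features = rd("truth_features.tsv"),
                      cohort = rd("truth_cohort.tsv"),
                      se = rd("truth_se.tsv"),
                      loops = rd("truth_loops.tsv"),
                      master = rd("truth_master.tsv"))
    }
    if (is.character(pipelineOut))
        pipelineOut <- readPipelineOutputs(pipelineOut)

    ## STABILO class agreement over enhancer features
    stab <- pipelineOut$stabilo
    m <- match(truth$features$peak_id, stab$peak_id)
    if (anyNA(m))
        stop("structural error: enhancer feature ids differ from ground truth")
    stabiloRate <- mean(as.character(stab$stabilo_class[m]) ==
                        truth$features$stabilo_class)

    ## NF-kB group agreement
    idx <- pipelineOut$index
    m <- match(truth$cohort$sample, idx$sample)
    if (anyNA(m))
        stop("structural error: cohort sample ids differ from ground truth")
    nfkbRate <- mean(as.character(idx$group[m]) == truth$cohort$group)

    ## SE status agreement on the first sample's stitched regions
    regions <- pipelineOut$perSampleSE[[1L]]
    truthSE <- GRanges(truth$se$chrom,
                       IRanges(truth$se$start0 + 1L, truth$se$end0))
    inTruth <- overlapsAny(regions, truthSE, ignore.strand = TRUE)
    seRate <- mean(regions$is_super == inTruth)

    ## loop type agreement over differential loops
    pairs <- pipelineOut$pairs
    tl <- truth$loops[truth$loops$differential, , drop = FALSE]
    pTypes <- tapply(pairs$type, pairs$loop_id,
                     function(x) paste(sort(unique(x)), collapse = ","))
    m <- match(tl$loop_id, names(pTypes))
    if (anyNA(m))
        stop("structural error: differential loop ids differ from ground truth")
    loopRate <- mean(unname(pTypes[m]) == tl$type)

    ## master table field-by-field
    ord <- function(df) df[order(df$loop_id, df$enhancer_id, df$gene_id), ]
    pm <- ord(pipelineOut$master); tm <- ord(truth$master)
    if (nrow(pm) != nrow(tm) ||
        !all(sort(pm$loop_id) == sort(tm$loop_id)))
        stop("structural error: master-table loop ids differ from ground truth")
    fields <- names(tm)
    rowOk <- rep(TRUE, nrow(tm))
    for (f in fields)
        rowOk <- rowOk & eqField(pm[[f]], tm[[f]])
    masterRate <- if (nrow(tm) == 0L) 1 else mean(rowOk)

    rates <- list(stabilo = stabiloRate, nfkb = nfkbRate, se = seRate,
                  loops = loopRate, master = masterRate)
    pass <- mapply(function(r, t) r >= t, rates, thresholds[names(rates)])
    list(rates = rates, pass = as.list(pass), all_pass = all(unlist(pass)))
}

## reload the pipeline results needed by validateAgainstTruth from outdir
readPipelineOutputs <- function(outdir) {
    stabilo <- utils::read.table(file.path(outdir, "stabilo_features.tsv"),
                                 sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    index <- utils::read.table(file.path(outdir, "nfkb_index.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    seFiles <- list.files(outdir, "^se_regions_.*\\.bed$", full.names = TRUE)
    firstSE <- readPeakBED(seFiles[1L])
    ## columns: name=signal, signal=rank, then is_super in column 6
    raw <- utils::read.table(seFiles[1L], sep = "\t",
                             stringsAsFactors = FALSE)
    perSampleSE <- GRanges(raw[[1L]], IRanges(raw[[2L]] + 1L, raw[[3L]]),
                           signal = raw[[4L]], rank = raw[[5L]],
                           is_super = as.logical(raw[[6L]]))
    pairs <- utils::read.table(file.path(outdir, "loop_pairs.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    master <- utils::read.table(file.path(outdir, "master_table.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    list(stabilo = stabilo, index = index, perSampleSE = list(perSampleSE),
         pairs = pairs, master = master)
}
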