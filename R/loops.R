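## HiChIP loop integration: BEDPE I/O, anchor annotation against enhancer and
## promoter features, inclusive EE/EP/PP classification, the integrated
## enhancer-promoter master table, and the reporting summaries.

#' Read loops from a BEDPE file
#'
#' Expects the 10 standard BEDPE columns (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2) followed by four statistics
#' columns: contact counts in the two conditions, log2 fold change and FDR.
#' Coordinates are 0-based half-open in the file.
#'
#' @param path Path to the BEDPE file.
#' @return A \code{LoopSet} with statistics columns \code{loop_id},
#'   \code{contact_a}, \code{contact_b}, \code{log2fc}, \code{fdr}.
#' @export
readLoopsBEDPE <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 14L)
        stop("BEDPE file ", path, " must have 14 columns ",
             "(10 BEDPE + contact_a, contact_b, log2fc, fdr)")
    a1 <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
    a2 <- GRanges(df[[4L]], IRanges(df[[5L]] + 1L, df[[6L]]))
    LoopSet(a1, a2, loop_id = as.character(df[[7L]]),
            contact_a = as.numeric(df[[11L]]),
            contact_b = as.numeric(df[[12L]]),
            log2fc = as.numeric(df[[13L]]), fdr = as.numeric(df[[14L]]))
}

#' Write a LoopSet as BEDPE
#'
#' @param loops A \code{LoopSet} with \code{loop_id}, \code{contact_a},
#'   \code{contact_b}, \code{log2fc}, \code{fdr} statistics.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeLoopsBEDPE <- function(loops, path) {
    a1 <- anchorOne(loops); a2 <- anchorTwo(loops)
    st <- loopData(loops)
    df <- data.frame(chrom1 = as.character(seqnames(a1)),
                     start1 = start(a1) - 1L, end1 = end(a1),
                     chrom2 = as.character(seqnames(a2)),
                     start2 = start(a2) - 1L, end2 = end(a2),
                     name = st$loop_id, score = ".",
                     strand1 = ".", strand2 = ".",
                     contact_a = st$contact_a, contact_b = st$contact_b,
                     log2fc = st$log2fc, fdr = st$fdr,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Annotate loop anchors with overlapping features
#'
#' Every feature overlapping an anchor by at least 1 bp is reported, split
#' into enhancers and promoters.
#'
#' @param anchors A \code{GRanges} of loop anchors.
#' @param enhancers A \code{GRanges} of enhancer features with a
#'   \code{peak_id} (or \code{id}) metadata column.
#' @param promoters A \code{GRanges} of promoter windows with a
#'   \code{gene_id} metadata column.
#' @return A list of two \code{CharacterList}s parallel to \code{anchors}:
#'   \code{enhancers} and \code{promoters}, holding overlapping feature ids.
#' @export
annotateAnchor <- function(anchors, enhancers, promoters) {
    featIds <- function(gr) {
        ids <- mcols(gr)$peak_id
        if (is.null(ids)) ids <- mcols(gr)$gene_id
        if (is.null(ids)) ids <- mcols(gr)$id
        if (is.null(ids)) stop("features need a peak_id/gene_id/id column")
        as.character(ids)
    }
    hitIds <- function(features) {
        out <- vector("list", length(anchors))
        for (i in seq_along(out)) out[[i]] <- character()
        if (length(features)) {
            hits <- findOverlaps(anchors, features, ignore.strand = TRUE)
            ids <- featIds(features)
            if (length(hits)) {
                sp <- split(ids[subjectHits(hits)], queryHits(hits))
                for (k in names(sp)) out[[as.integer(k)]] <- unique(sp[[k]])
            }
        }
        CharacterList(out)
    }
    list(enhancers = hitIds(enhancers), promoters = hitIds(promoters))
}

pairKind <- function(k1, k2) {
    ifelse(k1 == "E" & k2 == "E", "EE",
           ifelse(k1 == "P" & k2 == "P", "PP", "EP"))
}

## inclusive cross-anchor expansion of one loop's annotations: every
## (f1, f2) combination, EP oriented enhancer-first, deduplicated
## order-insensitively; empty annotation on either side -> one unassigned row.
## Kinds default to the feature id's first letter (E/P).
crossPairs <- function(f1, f2, k1 = substr(f1, 1L, 1L),
                       k2 = substr(f2, 1L, 1L)) {
    if (length(f1) == 0L || length(f2) == 0L)
        return(data.frame(feature1 = NA_character_, feature2 = NA_character_,
                          type = "unassigned", stringsAsFactors = FALSE))
    grid <- expand.grid(i1 = seq_along(f1), i2 = seq_along(f2))
    a <- f1[grid$i1]; b <- f2[grid$i2]
    ka <- k1[grid$i1]; kb <- k2[grid$i2]
    type <- pairKind(ka, kb)
    swap <- ka == "P" & kb == "E"
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi, sep = "\r"))
    data.frame(feature1 = a[keep], feature2 = b[keep], type = type[keep],
               stringsAsFactors = FALSE)
}

#' Classify loops into EE / EP / PP feature pairs
#'
#' Expands each loop into every cross-anchor feature pair (the inclusive
#' strategy: ambiguous anchors overlapping several features preserve all
#' possible interactions). Pairs are typed by the feature kinds
#' (enhancer/promoter) and deduplicated order-insensitively within a loop; a
#' loop with no feature on one or both anchors yields a single
#' \code{unassigned} record. EP rows always carry the enhancer in
#' \code{feature1} and the gene in \code{feature2}.
#'
#' @param loops A \code{LoopSet}.
#' @param enhancers,promoters Feature \code{GRanges} as in
#'   \code{annotateAnchor}.
#' @return A data.frame with one row per (loop, feature pair): \code{loop_id},
#'   \code{feature1}, \code{feature2}, \code{type} (EE/EP/PP/unassigned) and
#'   the loop statistics columns.
#' @export
classifyLoops <- function(loops, enhancers, promoters) {
    ann1 <- annotateAnchor(anchorOne(loops), enhancers, promoters)
    ann2 <- annotateAnchor(anchorTwo(loops), enhancers, promoters)
    st <- as.data.frame(loopData(loops))
    rows <- vector("list", length(loops))
    for (i in seq_len(length(loops))) {
        f1 <- c(ann1$enhancers[[i]], ann1$promoters[[i]])
        k1 <- rep(c("E", "P"), c(length(ann1$enhancers[[i]]),
                                 length(ann1$promoters[[i]])))
        f2 <- c(ann2$enhancers[[i]], ann2$promoters[[i]])
        k2 <- rep(c("E", "P"), c(length(ann2$enhancers[[i]]),
                                 length(ann2$promoters[[i]])))
        rows[[i]] <- crossPairs(f1, f2, k1, k2)
    }
    nPer <- vapply(rows, nrow, 0L)
    out <- do.call(rbind, rows)
    out <- cbind(st[rep(seq_len(length(loops)), nPer), , drop = FALSE], out)
    rownames(out) <- NULL
    out
}

lookupDiff <- function(ids, diffTable, what) {
    m <- match(ids, diffTable$feature_id)
    if (anyNA(m)) {
        miss <- unique(ids[is.na(m)])
        message(length(miss), " ", what,
                " id(s) absent from the differential table; recorded as NA")
    }
    data.frame(log2fc = diffTable$log2fc[m], fdr = diffTable$fdr[m])
}

#' Build the integrated enhancer-promoter interaction master table
#'
#' Restricts classified loop pairs to EP interactions and joins, per record:
#' loop statistics, the enhancer's H3K27ac dynamics, the target gene's
#' expression dynamics, p52 binding of the enhancer (>= 1 bp overlap with any
#' p52 consensus peak), super-enhancer membership, enhancer-origin (STABILO)
#' class, patient NF-kB+ enrichment flags (positive log2fc at FDR < 0.1 in
#' the supplied cohort comparison tables) and gene essentiality. Records with
#' identifiers missing from a join are kept with NA flags, never dropped.
#'
#' @param epiPairs Output of \code{classifyLoops} (only \code{type == "EP"}
#'   rows are used).
#' @param enhancerFeatures A \code{GRanges} of enhancer consensus peaks with
#'   \code{peak_id}.
#' @param enhancerDiff,expressionDiff Data.frames with columns
#'   \code{feature_id}, \code{log2fc}, \code{fdr}: external differential
#'   statistics for enhancers (H3K27ac) and genes (expression).
#' @param p52Peaks A \code{GRanges} of p52 consensus peaks (may be empty).
#' @param consensusSEs A \code{GRanges} of consensus super-enhancers (may be
#'   empty).
#' @param stabiloCalls A \code{GRanges} as returned by
#'   \code{stabiloClassify}, with \code{peak_id} matching the enhancer
#'   features where available.
#' @param patientEpigenome,patientExpression Data.frames (same columns as the
#'   differential tables) contrasting NF-kB+ vs NF-kB- patients for enhancers
#'   and genes respectively; \code{patientEpigenome} may be a list of tables
#'   (e.g. H3K27ac and accessibility), in which case enrichment is an OR
#'   across assays.
#' @param essentialGenes Character vector of essential gene symbols.
#' @param enrichFdr FDR threshold for the enrichment flags (default 0.1).
#' @return A data.frame with one row per EP (loop, enhancer, gene) record.
#' @export
buildMasterTable <- function(epiPairs, enhancerFeatures, enhancerDiff,
                             expressionDiff, p52Peaks = GRanges(),
                             consensusSEs = GRanges(),
                             stabiloCalls = NULL,
                             patientEpigenome = NULL,
                             patientExpression = NULL,
                             essentialGenes = character(),
                             enrichFdr = 0.1) {
    ep <- epiPairs[epiPairs$type == "EP", , drop = FALSE]
    if (nrow(ep) == 0L)
        return(emptyMasterTable())
    enhId <- ep$feature1
    geneId <- ep$feature2
    eIdx <- match(enhId, enhancerFeatures$peak_id)
    if (anyNA(eIdx))
        stop("EP enhancer id(s) missing from enhancerFeatures: ",
             paste(utils::head(unique(enhId[is.na(eIdx)]), 3L), collapse = ", "))
    enhGr <- enhancerFeatures[eIdx]
    enhDyn <- lookupDiff(enhId, enhancerDiff, "enhancer")
    geneDyn <- lookupDiff(geneId, expressionDiff, "gene")
    p52Bound <- overlapsAny(enhGr, p52Peaks, ignore.strand = TRUE)
    seMember <- overlapsAny(midpointRanges(enhGr), consensusSEs,
                            ignore.strand = TRUE)
    stabiloCls <- rep(NA_character_, length(enhGr))
    if (!is.null(stabiloCalls) && length(stabiloCalls)) {
        if (!is.null(stabiloCalls$peak_id)) {
            sm <- match(enhId, stabiloCalls$peak_id)
        } else {
            sm <- GenomicRanges::findOverlaps(midpointRanges(enhGr),
                                              stabiloCalls, select = "first",
                                              ignore.strand = TRUE)
        }
        stabiloCls <- as.character(stabiloCalls$stabilo_class[sm])
    }
    enrichFlag <- function(ids, tables) {
        if (is.null(tables))
            return(rep(NA, length(ids)))
        if (is.data.frame(tables))
            tables <- list(tables)
        flags <- matrix(NA, nrow = length(ids), ncol = length(tables))
        for (k in seq_along(tables)) {
            tb <- tables[[k]]
            m <- match(ids, tb$feature_id)
            flags[, k] <- tb$log2fc[m] > 0 & tb$fdr[m] < enrichFdr
        }
        ## OR across assays, NA only when every assay is missing the id
        anyTrue <- rowSums(flags, na.rm = TRUE) > 0L
        allNA <- rowSums(!is.na(flags)) == 0L
        ifelse(allNA, NA, anyTrue)
    }
    out <- data.frame(
        enhancer_id = enhId,
        gene_id = geneId,
        loop_id = ep$loop_id,
        loop_log2fc = ep$log2fc,
        loop_fdr = ep$fdr,
        enh_log2fc = enhDyn$log2fc,
        enh_fdr = enhDyn$fdr,
        gene_log2fc = geneDyn$log2fc,
        gene_fdr = geneDyn$fdr,
        p52_bound = p52Bound,
        se_member = seMember,
        stabilo_class = stabiloCls,
        nfkb_enriched_epigenome = enrichFlag(enhId, patientEpigenome),
        nfkb_enriched_expression = enrichFlag(geneId, patientExpression),
        essential = geneId %in% essentialGenes,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

emptyMasterTable <- function() {
    data.frame(enhancer_id = character(), gene_id = character(),
               loop_id = character(), loop_log2fc = numeric(),
               loop_fdr = numeric(), enh_log2fc = numeric(),
               enh_fdr = numeric(), gene_log2fc = numeric(),
               gene_fdr = numeric(), p52_bound = logical(),
               se_member = logical(), stabilo_class = character(),
               nfkb_enriched_epigenome = logical(),
               nfkb_enriched_expression = logical(),
               essential = logical(), stringsAsFactors = FALSE)
}

#' Count and integer percentage (round half up)
#'
#' The reporting convention used throughout: percentages are
#' \code{floor(100 * k/n + 0.5)}, i.e. rounded half up to an integer.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return A list with \code{count}, \code{total} and \code{percent}.
#' @examples
#' countPercent(889, 2868)$percent   # 31
#' countPercent(30651, 44476)$percent  # 69
#' @export
countPercent <- function(k, n) {
    if (n <= 0)
        stop("denominator must be positive")
    list(count = k, total = n, percent = floor(100 * k / n + 0.5))
}

#' Concordance between enhancer and gene dynamics across EP records
#'
#' Reports Pearson and Spearman correlation between enhancer log2 fold change
#' and target-gene log2 fold change, and counts/percentages of records in
#' sign/significance categories (both significant at \code{fdrThreshold}).
#'
#' @param records Master-table data.frame (needs \code{enh_log2fc},
#'   \code{gene_log2fc}, \code{enh_fdr}, \code{gene_fdr}).
#' @param fdrThreshold Significance threshold for the categories.
#' @return A list: \code{n}, \code{pearson}, \code{spearman} (NA when a
#'   dynamic has zero variance) and \code{categories}, each a
#'   \code{countPercent} list for concordant_down, concordant_up and
#'   discordant records among the doubly-significant ones.
#' @export
concordanceSummary <- function(records, fdrThreshold = 0.1) {
    ok <- stats::complete.cases(records[, c("enh_log2fc", "gene_log2fc")])
    r <- records[ok, , drop = FALSE]
    if (nrow(r) < 3L)
        stop("need at least 3 records with both dynamics present")
    degenerate <- stats::sd(r$enh_log2fc) == 0 || stats::sd(r$gene_log2fc) == 0
    pearson <- if (degenerate) NA_real_ else
        stats::cor(r$enh_log2fc, r$gene_log2fc, method = "pearson")
    spearman <- if (degenerate) NA_real_ else
        stats::cor(r$enh_log2fc, r$gene_log2fc, method = "spearman")
    sig <- !is.na(r$enh_fdr) & !is.na(r$gene_fdr) &
        r$enh_fdr < fdrThreshold & r$gene_fdr < fdrThreshold
    s <- r[sig, , drop = FALSE]
    nSig <- nrow(s)
    cats <- list(
        concordant_down = sum(s$enh_log2fc < 0 & s$gene_log2fc < 0),
        concordant_up = sum(s$enh_log2fc > 0 & s$gene_log2fc > 0))
    cats$discordant <- nSig - cats$concordant_down - cats$concordant_up
    categories <- if (nSig > 0L)
        lapply(cats, countPercent, n = nSig)
    else
        lapply(cats, function(k) list(count = k, total = 0L,
                                      percent = NA_real_))
    list(n = nrow(r), n_significant = nSig, pearson = pearson,
         spearman = spearman, categories = categories)
}

#' Summary of differential loop calling
#'
#' @param loopsAll All significant loops: a \code{LoopSet} or a count.
#' @param loopsDifferential The differential subset: a \code{LoopSet} or a
#'   count.
#' @return A list with \code{n_total}, \code{n_diff}, \code{percent}
#'   (round-half-up integer) and \code{frac_negative} (fraction of
#'   differential loops with negative log2fc; NA when only counts are given).
#' @examples
#' loopDiffSummary(44476, 30651)$percent  # 69
#' @export
loopDiffSummary <- function(loopsAll, loopsDifferential) {
    nTotal <- if (is(loopsAll, "LoopSet")) length(loopsAll)
              else as.numeric(loopsAll)
    if (is(loopsDifferential, "LoopSet")) {
        nDiff <- length(loopsDifferential)
        fracNeg <- if (nDiff > 0)
            mean(loopData(loopsDifferential)$log2fc < 0) else NA_real_
    } else {
        nDiff <- as.numeric(loopsDifferential)
        fracNeg <- NA_real_
    }
    if (nTotal == 0)
        stop("no loops to summarise")
    if (nDiff > nTotal)
        stop("differential loops must be a subset of all loops")
    cp <- countPercent(nDiff, nTotal)
    list(n_total = nTotal, n_diff = nDiff, percent = cp$percent,
         frac_negative = fracNeg)
}

#' Read a differential-statistics table
#'
#' TSV with header columns \code{feature_id}, \code{log2fc}, \code{pvalue},
#' \code{fdr} (external DESeq2/DiffBind/DiffLoop-style output).
#'
#' @param path Path to the TSV.
#' @return A data.frame with those columns.
#' @export
readDiffTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "log2fc", "fdr")
    if (!all(need %in% names(df)))
        stop("differential table ", path, " must have columns ",
             paste(need, collapse = ", "))
    df
}
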