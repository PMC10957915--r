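## ROSE-style super-enhancer calling: TSS exclusion, peak stitching, and the
## signal-rank tangent cutoff separating super-enhancers from typical
## enhancers, plus consensus construction across samples.

#' Remove peaks near transcription start sites
#'
#' Drops peaks overlapping any window of \code{tssExclusion} bp on either side
#' of a TSS (default 2500 bp), so promoter-proximal signal does not seed
#' stitched enhancer regions.
#'
#' @param peaks A \code{GRanges} of peaks.
#' @param genes A \code{GRanges} with a \code{tss} metadata column (as from
#'   \code{readGeneModels}).
#' @param tssExclusion Half-width of the exclusion window in bp.
#' @return The subset of \code{peaks} clear of all TSS windows.
#' @export
excludeTSSPeaks <- function(peaks, genes, tssExclusion = 2500L) {
    if (length(genes) == 0L)
        return(peaks)
    ## 0-based window [tss0 - excl, tss0 + excl) -> 1-based
    win <- GRanges(seqnames(genes),
                   IRanges(pmax(genes$tss - tssExclusion, 1L),
                           genes$tss + tssExclusion - 1L))
    peaks[!overlapsAny(peaks, win, ignore.strand = TRUE)]
}

#' Stitch peaks into candidate enhancer regions
#'
#' Peaks whose edge-to-edge gap is at most \code{stitchDistance} bp (default
#' 12500) are merged transitively. Each stitched region spans its constituent
#' peaks and carries their summed signal.
#'
#' @param peaks A \code{GRanges} with a numeric \code{signal} metadata column.
#' @param stitchDistance Maximum gap between peaks to merge, in bp.
#' @return A \code{GRanges} of stitched regions with metadata columns
#'   \code{signal} (sum over constituents), \code{n_constituents} and
#'   \code{constituents} (an \code{IntegerList} of indices into \code{peaks}).
#' @examples
#' pk <- GRanges("chr1", IRanges(c(1, 12001), c(500, 12500)),
#'               signal = c(5, 7))
#' stitchPeaks(pk)  # one region, signal 12
#' @export
stitchPeaks <- function(peaks, stitchDistance = 12500L) {
    if (is.null(peaks$signal))
        stop("peaks must carry a numeric 'signal' metadata column")
    merged <- reduce(peaks, min.gapwidth = stitchDistance + 1L,
                     ignore.strand = TRUE, with.revmap = TRUE)
    revmap <- mcols(merged)$revmap
    sig <- vapply(revmap, function(i) sum(peaks$signal[i]), 0)
    out <- GRanges(seqnames(merged), IRanges(start(merged), end(merged)))
    mcols(out)$signal <- sig
    mcols(out)$n_constituents <- lengths(revmap)
    mcols(out)$constituents <- revmap
    sortIntervals(out)
}

## brute-force-verifiable tangent point: with signals sorted ascending
## y_1..y_n over x_i = i and chord slope s = (y_n - y_1)/(n - 1), the tangent
## index is the point furthest below the chord, i.e. it maximizes s*i - y_i
## (largest index on ties, so a perfectly linear curve yields no cutoff).
tangentIndex <- function(ySorted) {
    n <- length(ySorted)
    s <- (ySorted[n] - ySorted[1L]) / (n - 1L)
    d <- s * seq_len(n) - ySorted
    max(which(d == max(d)))
}

#' Flag super-enhancers by the signal-rank tangent cutoff
#'
#' Sorts region signals ascending against their ranks, draws the chord from
#' the lowest to the highest signal, and places the cutoff at the point
#' furthest above the chord (the tangent point; largest rank on ties).
#' Regions with signal strictly above the cutoff signal are super-enhancers.
#' The assignment is invariant under positive affine rescaling of the
#' signals. Ranks (1 = strongest) are assigned by descending signal, ties
#' broken by leftmost coordinate.
#'
#' @param regions A \code{GRanges} of stitched regions with a \code{signal}
#'   metadata column (at least 3 regions, not all signals identical).
#' @return \code{regions} with added metadata columns \code{rank} and
#'   \code{is_super}, plus a \code{cutoff} entry in \code{metadata()}.
#' @export
tangentCutoff <- function(regions) {
    n <- length(regions)
    if (n < 3L)
        stop("tangent cutoff needs at least 3 regions")
    y <- regions$signal
    if (length(unique(y)) == 1L) {
        warning("all region signals identical; no super-enhancers flagged")
        mcols(regions)$is_super <- rep(FALSE, n)
        cutoff <- y[1L]
    } else {
        ySorted <- sort(y)
        cutoff <- ySorted[tangentIndex(ySorted)]
        mcols(regions)$is_super <- y > cutoff
    }
    ord <- order(-y, as.character(seqnames(regions)), start(regions))
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    mcols(regions)$rank <- rk
    metadata(regions)$cutoff <- cutoff
    regions
}

#' Call super-enhancers for one sample
#'
#' TSS exclusion, stitching and the tangent cutoff in sequence.
#'
#' @inheritParams excludeTSSPeaks
#' @inheritParams stitchPeaks
#' @return Stitched regions with \code{signal}, \code{rank} and
#'   \code{is_super} metadata columns.
#' @export
callSuperEnhancers <- function(peaks, genes, stitchDistance = 12500L,
                               tssExclusion = 2500L) {
    kept <- excludeTSSPeaks(peaks, genes, tssExclusion)
    tangentCutoff(stitchPeaks(kept, stitchDistance))
}

#' Sample membership of consensus regions
#'
#' A sample is a member of a consensus region when at least \code{minFraction}
#' of one of that sample's original regions lies within the consensus
#' interval (fraction measured on the original sample region).
#'
#' @param consensus A \code{GRanges} of consensus intervals.
#' @param sampleRegions Named list of \code{GRanges}, one per sample.
#' @param minFraction Required fraction of the sample region (default 0.5).
#' @return A \code{CharacterList} parallel to \code{consensus}: member sample
#'   ids per consensus region.
#' @export
assignSEMembership <- function(consensus, sampleRegions, minFraction = 0.5) {
    members <- vector("list", length(consensus))
    for (i in seq_along(members)) members[[i]] <- character()
    for (sampleId in names(sampleRegions)) {
        regions <- sampleRegions[[sampleId]]
        hits <- findOverlaps(regions, consensus, ignore.strand = TRUE)
        if (length(hits) == 0L) next
        w <- width(pintersect(regions[queryHits(hits)],
                              consensus[subjectHits(hits)],
                              ignore.strand = TRUE))
        frac <- w / width(regions)[queryHits(hits)]
        memberOf <- unique(subjectHits(hits)[frac >= minFraction])
        for (j in memberOf)
            members[[j]] <- c(members[[j]], sampleId)
    }
    CharacterList(members)
}

#' Build consensus super-enhancers across samples
#'
#' Union-merges the per-sample super-enhancer intervals and re-assigns each
#' sample to the consensus regions that contain at least half of one of its
#' original super-enhancers.
#'
#' @param perSampleSEs Named list of \code{GRanges}: the \code{is_super}
#'   regions of each sample.
#' @param minFraction Membership threshold on the original sample SE length.
#' @return A \code{GRanges} of consensus super-enhancers with metadata columns
#'   \code{se_id} and \code{member_samples} (a \code{CharacterList}).
#' @export
consensusSE <- function(perSampleSEs, minFraction = 0.5) {
    if (length(perSampleSEs) < 1L)
        stop("at least one sample is required")
    if (is.null(names(perSampleSEs)))
        names(perSampleSEs) <- paste0("sample", seq_along(perSampleSEs))
    all <- unlist(GRangesList(lapply(perSampleSEs, function(g) {
        mcols(g) <- NULL
        g
    })), use.names = FALSE)
    cons <- sortIntervals(reduce(all, ignore.strand = TRUE))
    mcols(cons)$se_id <- sprintf("se_%s_%d", as.character(seqnames(cons)),
                                 start(cons) - 1L)
    mcols(cons)$member_samples <-
        assignSEMembership(cons, perSampleSEs, minFraction)
    cons
}

#' Assign consensus peaks as constituents of consensus super-enhancers
#'
#' A consensus peak is a constituent of every consensus super-enhancer whose
#' interval contains the peak midpoint; peaks inside no super-enhancer remain
#' typical enhancers.
#'
#' @param consensusSEs A \code{GRanges} of consensus super-enhancers.
#' @param peaks A \code{GRanges} of consensus enhancer peaks.
#' @return A list: \code{ses} (the input SEs with a \code{constituents}
#'   \code{IntegerList} of peak indices) and \code{peaks} (the input peaks
#'   with a logical \code{se_member} column).
#' @export
assignConstituents <- function(consensusSEs, peaks) {
    mids <- midpointRanges(peaks)
    hits <- findOverlaps(mids, consensusSEs, ignore.strand = TRUE)
    constituents <- vector("list", length(consensusSEs))
    for (i in seq_along(constituents)) constituents[[i]] <- integer()
    if (length(hits)) {
        sp <- split(queryHits(hits), subjectHits(hits))
        for (k in names(sp))
            constituents[[as.integer(k)]] <- as.integer(sp[[k]])
    }
    mcols(consensusSEs)$constituents <- IntegerList(constituents)
    mcols(peaks)$se_member <- overlapsAny(mids, consensusSEs,
                                          ignore.strand = TRUE)
    list(ses = consensusSEs, peaks = peaks)
}
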