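#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#'   queryHits subjectHits
#' @importFrom IRanges IRanges CharacterList IntegerList overlapsAny
#'   isDisjoint
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand findOverlaps reduce promoters resize pintersect start<- end<-
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom stats setNames
#' @importFrom utils head modifyList read.table write.table
NULL

#' SegmentationSet: chromatin-state segmentations grouped by developmental stage
#'
#' Container for per-sample chromHMM-style segmentations, each a \code{GRanges}
#' with a \code{state} metadata column, together with a stage label per sample.
#' Stages follow the B-cell to plasma-cell to myeloma axis used by the
#' enhancer-origin (STABILO) classification: \code{"B"}, \code{"PC"},
#' \code{"MM"}.
#'
#' @slot segmentations A \code{GRangesList}, one element per sample; every
#'   element carries a character \code{state} metadata column and its ranges
#'   must not overlap within the sample.
#' @slot groups A factor parallel to \code{segmentations} with levels drawn
#'   from \code{c("B", "PC", "MM")}.
#' @export
setClass("SegmentationSet",
         representation(segmentations = "GRangesList", groups = "factor"))

setValidity("SegmentationSet", function(object) {
    msg <- character()
    if (length(object@segmentations) != length(object@groups))
        msg <- c(msg, "one group label per sample segmentation is required")
    if (!all(levels(object@groups) %in% c("B", "PC", "MM")))
        msg <- c(msg, "groups must be drawn from {B, PC, MM}")
    for (i in seq_along(object@segmentations)) {
        seg <- object@segmentations[[i]]
        if (!"state" %in% names(mcols(seg))) {
            msg <- c(msg, "every segmentation needs a 'state' metadata column")
            break
        }
        if (!isDisjoint(seg)) {
            msg <- c(msg, sprintf(
                "segmentation %d has overlapping intervals within the sample", i))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SegmentationSet
#'
#' @param segmentations A \code{GRangesList} (or list of \code{GRanges}) of
#'   per-sample segmentations, each with a \code{state} metadata column.
#' @param groups Character or factor of stage labels (\code{"B"}, \code{"PC"},
#'   \code{"MM"}), one per sample. Names of \code{segmentations} are kept as
#'   sample identifiers.
#' @return A \code{SegmentationSet}.
#' @examples
#' seg <- GRanges("chr1", IRanges(1, 1000), state = "E9")
#' ss <- SegmentationSet(GRangesList(s1 = seg), groups = "MM")
#' sampleGroups(ss)
#' @export
SegmentationSet <- function(segmentations, groups) {
    if (is.list(segmentations) && !is(segmentations, "GRangesList"))
        segmentations <- GRangesList(segmentations)
    groups <- factor(as.character(groups), levels = c("B", "PC", "MM"))
    if (anyNA(groups))
        stop("sample groups must be one of 'B', 'PC', 'MM'")
    new("SegmentationSet", segmentations = segmentations, groups = groups)
}

#' @describeIn SegmentationSet The per-sample segmentations.
#' @param x A \code{SegmentationSet}.
#' @export
setGeneric("segmentations", function(x) standardGeneric("segmentations"))

#' @rdname SegmentationSet
#' @export
setMethod("segmentations", "SegmentationSet", function(x) x@segmentations)

#' @describeIn SegmentationSet The stage label (B/PC/MM) of each sample.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname SegmentationSet
#' @export
setMethod("sampleGroups", "SegmentationSet", function(x) x@groups)

setMethod("show", "SegmentationSet", function(object) {
    tab <- table(object@groups)
    cat("SegmentationSet with", length(object@segmentations), "samples (",
        paste(names(tab), tab, sep = ":", collapse = " "), ")\n")
})

#' LoopSet: chromatin loops with differential contact statistics
#'
#' Pairs of fixed-width loop anchors (2500 bp, the resolution at which
#' differential HiChIP anchors are annotated) with per-loop contact
#' statistics. Only intra-chromosomal loops with anchor-midpoint separation in
#' (10 kb, 2 Mb] are admitted, matching the distance window of the loop
#' caller.
#'
#' @slot anchor1,anchor2 \code{GRanges} of equal length, each range 2500 bp.
#' @slot loopData A \code{DataFrame} of per-loop statistics; columns
#'   \code{log2fc} and \code{fdr} are expected by downstream integration.
#' @export
setClass("LoopSet",
         representation(anchor1 = "GRanges", anchor2 = "GRanges",
                        loopData = "DataFrame"))

setValidity("LoopSet", function(object) {
    msg <- character()
    n <- length(object@anchor1)
    if (length(object@anchor2) != n || nrow(object@loopData) != n)
        msg <- c(msg, "anchor1, anchor2 and loopData must have equal length")
    if (n > 0L) {
        if (!all(width(object@anchor1) == 2500L) ||
            !all(width(object@anchor2) == 2500L))
            msg <- c(msg, "loop anchors must span exactly 2500 bp")
        same <- as.character(seqnames(object@anchor1)) ==
            as.character(seqnames(object@anchor2))
        if (!all(same)) {
            msg <- c(msg, "loops must be intra-chromosomal")
        } else {
            d <- loopSpan(object@anchor1, object@anchor2)
            if (any(d <= 10000L | d > 2000000L))
                msg <- c(msg,
                    "anchor separation must lie in (10 kb, 2 Mb]")
        }
    }
    if (length(msg)) msg else TRUE
})

loopSpan <- function(a1, a2) {
    mid1 <- floor((start(a1) - 1L + end(a1)) / 2)
    mid2 <- floor((start(a2) - 1L + end(a2)) / 2)
    abs(mid1 - mid2)
}

#' Construct a LoopSet
#'
#' @param anchor1,anchor2 \code{GRanges} of 2500 bp anchors, parallel to each
#'   other.
#' @param ... Per-loop statistics (vectors parallel to the anchors), e.g.
#'   \code{contact_a}, \code{contact_b}, \code{log2fc}, \code{fdr},
#'   \code{loop_id}.
#' @return A \code{LoopSet}.
#' @examples
#' a1 <- GRanges("chr1", IRanges(10001, width = 2500))
#' a2 <- GRanges("chr1", IRanges(60001, width = 2500))
#' ls <- LoopSet(a1, a2, log2fc = -1.2, fdr = 0.01, loop_id = "loop_1")
#' loopDistance(ls)
#' @export
LoopSet <- function(anchor1, anchor2, ...) {
    stats <- DataFrame(...)
    if (nrow(stats) == 0L && length(anchor1) > 0L)
        stats <- DataFrame(matrix(nrow = length(anchor1), ncol = 0L))
    new("LoopSet", anchor1 = anchor1, anchor2 = anchor2, loopData = stats)
}

#' @describeIn LoopSet First anchor of every loop.
#' @param x A \code{LoopSet}.
#' @export
setGeneric("anchorOne", function(x) standardGeneric("anchorOne"))

#' @rdname LoopSet
#' @export
setMethod("anchorOne", "LoopSet", function(x) x@anchor1)

#' @describeIn LoopSet Second anchor of every loop.
#' @export
setGeneric("anchorTwo", function(x) standardGeneric("anchorTwo"))

#' @rdname LoopSet
#' @export
setMethod("anchorTwo", "LoopSet", function(x) x@anchor2)

#' @describeIn LoopSet Per-loop statistics as a \code{DataFrame}.
#' @export
setGeneric("loopData", function(x) standardGeneric("loopData"))

#' @rdname LoopSet
#' @export
setMethod("loopData", "LoopSet", function(x) x@loopData)

#' @describeIn LoopSet Anchor midpoint separation in bp.
#' @export
setGeneric("loopDistance", function(x) standardGeneric("loopDistance"))

#' @rdname LoopSet
#' @export
setMethod("loopDistance", "LoopSet",
          function(x) loopSpan(x@anchor1, x@anchor2))

#' @rdname LoopSet
#' @export
setMethod("length", "LoopSet", function(x) length(x@anchor1))

#' @param i Index into the loops.
#' @param j,drop Ignored.
#' @rdname LoopSet
#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = TRUE) {
    new("LoopSet", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
        loopData = x@loopData[i, , drop = FALSE])
})

setMethod("show", "LoopSet", function(object) {
    cat("LoopSet with", length(object), "loops;",
        ncol(object@loopData), "statistics column(s)\n")
    if (length(object)) {
        d <- loopDistance(object)
        cat("  anchor separation:", min(d), "-", max(d), "bp\n")
    }
})
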