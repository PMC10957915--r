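## STABILO: enhancer-origin classification from chromatin-state activity
## across the B-cell -> plasma-cell -> myeloma axis. A locus counts as active
## in a sample when active-enhancer chromHMM states cover at least half of it;
## a stage is active when any of its samples is; the activity trajectory
## (B, PC, MM) then maps onto five origin classes.

#' Read a chromHMM segmentation (BED4)
#'
#' Column 4 is the state label; dense-BED dialect labels such as
#' \code{"E9_EnhActive"} are truncated to the part before the first
#' underscore.
#'
#' @param path Path to the BED4 file (0-based half-open coordinates).
#' @return A \code{GRanges} with a \code{state} metadata column, sorted by
#'   position.
#' @export
readSegmentationBED <- function(path) {
    gr <- readPeakBED(path)
    if (all(is.na(gr$name)) && length(gr) > 0L)
        stop("segmentation file ", path, " lacks the state column (BED4)")
    state <- sub("_.*$", "", gr$name)
    mcols(gr) <- DataFrame(state = state)
    gr
}

#' Read a sample manifest mapping sample files to stage groups
#'
#' Two or three tab-separated columns with header: \code{sample},
#' \code{group} (one of B, PC, MM) and optionally \code{path}.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame with columns \code{sample}, \code{group} and, when
#'   present, \code{path}.
#' @export
readSampleManifest <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(df)))
        stop("manifest must have 'sample' and 'group' columns: ", path)
    bad <- setdiff(unique(df$group), c("B", "PC", "MM"))
    if (length(bad))
        stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "))
    if (!is.null(df$path)) {
        rel <- !startsWith(df$path, "/")
        df$path[rel] <- file.path(dirname(path), df$path[rel])
    }
    df
}

#' Is a locus in an active-enhancer state in one sample?
#'
#' A locus is active when segments carrying an active-enhancer state cover at
#' least \code{minFraction} of it (union coverage; the threshold is
#' inclusive). Loci on chromosomes absent from the segmentation are inactive.
#'
#' @param loci A \code{GRanges} of target loci.
#' @param segmentation A \code{GRanges} with a \code{state} metadata column.
#' @param activeStates Character vector of state labels counted as active
#'   enhancer (e.g. \code{c("E9", "E10")}).
#' @param minFraction Required covered fraction of the locus (default 0.5).
#' @return Logical vector parallel to \code{loci}.
#' @export
locusActive <- function(loci, segmentation, activeStates, minFraction = 0.5) {
    if (length(activeStates) == 0L)
        stop("activeStates must be non-empty")
    active <- segmentation[segmentation$state %in% activeStates]
    overlapFraction(loci, active) >= minFraction
}

#' Summarise locus activity per developmental stage
#'
#' A stage (B, PC, MM) is active at a locus when at least one of its samples
#' is active there (any-sample rule).
#'
#' @param loci A \code{GRanges} of target loci.
#' @param segset A \code{SegmentationSet}.
#' @inheritParams locusActive
#' @return A \code{DataFrame} parallel to \code{loci} with logical columns
#'   \code{b_active}, \code{pc_active}, \code{mm_active}.
#' @export
groupActivity <- function(loci, segset, activeStates, minFraction = 0.5) {
    stopifnot(is(segset, "SegmentationSet"))
    groups <- sampleGroups(segset)
    if (sum(groups == "MM") < 1L)
        stop("the MM group must contain at least one sample")
    segs <- segmentations(segset)
    perSample <- vapply(seq_along(segs), function(i)
        locusActive(loci, segs[[i]], activeStates, minFraction),
        logical(length(loci)))
    perSample <- matrix(perSample, nrow = length(loci))
    groupAny <- function(g) {
        idx <- which(groups == g)
        if (length(idx) == 0L) rep(FALSE, length(loci))
        else rowSums(perSample[, idx, drop = FALSE]) > 0L
    }
    DataFrame(b_active = groupAny("B"), pc_active = groupAny("PC"),
              mm_active = groupAny("MM"))
}

#' Classify enhancer origin from a stage-activity trajectory
#'
#' Maps (B, PC, MM) activity onto the five origin classes:
#' \itemize{
#'   \item \code{preserved}: active in MM and in plasma cells (B free);
#'   \item \code{reactivated}: active in MM and in B cells but not plasma
#'     cells;
#'   \item \code{de_novo}: active only in MM;
#'   \item \code{lost}: inactive in MM but active in B cells or plasma cells;
#'   \item \code{unknown}: inactive throughout.
#' }
#' \code{de_novo} and \code{reactivated} together are the "dormant" enhancers:
#' inactive in normal plasma cells yet active in myeloma.
#'
#' @param b,pc,mm Logical vectors of equal length: stage activity.
#' @return Factor with levels
#'   \code{de_novo, reactivated, preserved, lost, unknown}.
#' @examples
#' classifyStabilo(b = FALSE, pc = FALSE, mm = TRUE)  # de_novo
#' @export
classifyStabilo <- function(b, pc, mm) {
    stopifnot(length(b) == length(pc), length(pc) == length(mm))
    cls <- ifelse(mm,
                  ifelse(pc, "preserved",
                         ifelse(b, "reactivated", "de_novo")),
                  ifelse(b | pc, "lost", "unknown"))
    factor(cls, levels = c("de_novo", "reactivated", "preserved", "lost",
                           "unknown"))
}

#' Full STABILO classification of loci against a segmentation set
#'
#' @inheritParams groupActivity
#' @return The input \code{loci} with added metadata columns
#'   \code{b_active}, \code{pc_active}, \code{mm_active},
#'   \code{stabilo_class} and \code{dormant} (TRUE for de_novo/reactivated).
#' @export
stabiloClassify <- function(loci, segset, activeStates, minFraction = 0.5) {
    act <- groupActivity(loci, segset, activeStates, minFraction)
    cls <- classifyStabilo(act$b_active, act$pc_active, act$mm_active)
    mcols(loci)$b_active <- act$b_active
    mcols(loci)$pc_active <- act$pc_active
    mcols(loci)$mm_active <- act$mm_active
    mcols(loci)$stabilo_class <- cls
    mcols(loci)$dormant <- cls %in% c("de_novo", "reactivated")
    loci
}
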