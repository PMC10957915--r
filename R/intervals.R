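## Interval algebra and standard-format I/O. All in-memory coordinates are
## 1-based closed (GRanges convention); all files read/written are BED-family,
## 0-based half-open. Conversion happens only at the I/O boundary.

#' Read a BED3/BED4/BED5 peak file
#'
#' Reads tab-separated BED with optional name (column 4) and signal
#' (column 5). Coordinates in the file are 0-based half-open and are converted
#' to the 1-based \code{GRanges} convention. Malformed lines (non-integer
#' coordinates, start >= end, fewer than three columns) raise an error naming
#' the offending line numbers.
#'
#' @param path Path to the BED file.
#' @param sampleId Optional sample identifier stored in the \code{sample_id}
#'   metadata column.
#' @return A \code{GRanges} sorted by (chrom, start) with metadata columns
#'   \code{name}, \code{signal} (NA when absent) and \code{sample_id}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t500\tp1\t7.5", bed)
#' readPeakBED(bed)
#' @export
readPeakBED <- function(path, sampleId = NA_character_) {
    if (!file.exists(path))
        stop("peak file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(GRanges(name = character(), signal = numeric(),
                       sample_id = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    bad <- which(ncols < 3L)
    if (length(bad))
        stop("BED format error in ", path, ": fewer than 3 columns at line(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
    chrom <- vapply(fields, `[[`, "", 1L)
    startTxt <- vapply(fields, `[[`, "", 2L)
    endTxt <- vapply(fields, `[[`, "", 3L)
    start0 <- suppressWarnings(as.numeric(startTxt))
    end0 <- suppressWarnings(as.numeric(endTxt))
    bad <- which(is.na(start0) | is.na(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
    if (length(bad))
        stop("BED format error in ", path,
             ": non-integer coordinates at line(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
    bad <- which(start0 >= end0 | start0 < 0)
    if (length(bad))
        stop("BED format error in ", path, ": start >= end at line(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
    name <- ifelse(ncols >= 4L,
                   vapply(fields, function(f) if (length(f) >= 4L) f[[4L]]
                          else NA_character_, ""),
                   NA_character_)
    signal <- rep(NA_real_, length(fields))
    hasSig <- ncols >= 5L
    if (any(hasSig)) {
        sigTxt <- vapply(fields[hasSig], `[[`, "", 5L)
        sig <- suppressWarnings(as.numeric(sigTxt))
        if (anyNA(sig))
            stop("BED format error in ", path,
                 ": non-numeric signal at line(s) ",
                 paste(utils::head(which(hasSig)[is.na(sig)], 5L),
                       collapse = ", "))
        signal[hasSig] <- sig
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0),
                  name = name, signal = signal,
                  sample_id = rep(sampleId, length(chrom)))
    sortIntervals(gr)
}

## sort by (chrom as character, start, end) — stable across seqlevel orderings
sortIntervals <- function(gr) {
    gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' Write a GRanges as BED
#'
#' Coordinates are converted back to 0-based half-open. Any metadata columns
#' given in \code{extraCols} are appended after chrom/start/end (lists are
#' collapsed with commas).
#'
#' @param gr A \code{GRanges}.
#' @param path Output path.
#' @param extraCols Character vector of metadata column names to append.
#' @return Invisibly, \code{path}.
#' @export
writeBED <- function(gr, path, extraCols = character()) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     stringsAsFactors = FALSE)
    for (col in extraCols) {
        v <- mcols(gr)[[col]]
        if (is(v, "List") || is.list(v))
            v <- vapply(as.list(v), paste, "", collapse = ",")
        df[[col]] <- v
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Fraction of a target interval covered by a set of intervals
#'
#' Computes, for every range in \code{target}, the fraction of its bases
#' covered by the union of \code{others} on the same chromosome. Overlapping
#' members of \code{others} are merged first so bases are never
#' double-counted. Strand is ignored.
#'
#' @param target A \code{GRanges} of query intervals.
#' @param others A \code{GRanges} whose union provides the coverage.
#' @return Numeric vector in [0, 1], parallel to \code{target}.
#' @examples
#' tgt <- GRanges("chr1", IRanges(1, 1000))
#' cov <- GRanges("chr1", IRanges(c(1, 301), c(400, 700)))
#' overlapFraction(tgt, cov)  # 0.7
#' @export
overlapFraction <- function(target, others) {
    covered <- numeric(length(target))
    if (length(others) == 0L || length(target) == 0L)
        return(covered)
    red <- reduce(others, ignore.strand = TRUE)
    ## targets on chromosomes absent from `others` simply score 0
    hits <- suppressWarnings(findOverlaps(target, red, ignore.strand = TRUE))
    if (length(hits)) {
        w <- width(pintersect(target[queryHits(hits)], red[subjectHits(hits)],
                              ignore.strand = TRUE))
        agg <- tapply(w, queryHits(hits), sum)
        covered[as.integer(names(agg))] <- as.numeric(agg)
    }
    covered / width(target)
}

#' Consensus peaks across replicates
#'
#' Merges overlapping peaks across replicate peak sets, keeps merged regions
#' supported by at least \code{minSupport} distinct replicates, and replaces
#' each retained region by a fixed-width interval (500 bp by default) centred
#' on the midpoint of the merged region, mirroring the common practice of
#' resizing consensus peaks to a uniform width centred on the peak middle.
#'
#' @param replicatePeaks A \code{GRangesList} or plain list of \code{GRanges},
#'   one per replicate.
#' @param minSupport Minimum number of distinct replicates a merged region
#'   must be supported by (default 2, i.e. "in at least two replicates").
#' @param consensusWidth Width of the output intervals (default 500 bp).
#' @return A \code{GRanges} of \code{consensusWidth}-wide peaks with metadata
#'   columns \code{support} (replicate count) and \code{peak_id}
#'   (\code{enh_<chrom>_<0-based start>}).
#' @examples
#' reps <- GRangesList(A = GRanges("chr1", IRanges(101, 600)),
#'                     B = GRanges("chr1", IRanges(401, 900)))
#' consensusPeaks(reps)  # one 500 bp peak centred at the merged midpoint
#' @export
consensusPeaks <- function(replicatePeaks, minSupport = 2L,
                           consensusWidth = 500L) {
    if (is.list(replicatePeaks) && !is(replicatePeaks, "GRangesList"))
        replicatePeaks <- GRangesList(replicatePeaks)
    nrep <- length(replicatePeaks)
    if (nrep < 1L)
        stop("at least one replicate peak set is required")
    if (minSupport > nrep)
        stop("minSupport (", minSupport, ") exceeds the number of replicates (",
             nrep, ")")
    allPeaks <- unlist(replicatePeaks, use.names = FALSE)
    if (length(allPeaks) == 0L)
        return(GRanges(support = integer(), peak_id = character()))
    repIdx <- rep(seq_len(nrep), lengths(replicatePeaks))
    merged <- reduce(allPeaks, ignore.strand = TRUE)
    hits <- findOverlaps(merged, allPeaks, ignore.strand = TRUE)
    support <- vapply(split(repIdx[subjectHits(hits)], queryHits(hits)),
                      function(i) length(unique(i)), 0L)
    supportAll <- integer(length(merged))
    supportAll[as.integer(names(support))] <- support
    keep <- supportAll >= minSupport
    merged <- merged[keep]
    supportAll <- supportAll[keep]
    ## midpoint in 0-based coordinates: floor((start0 + end0) / 2)
    mid0 <- floor((start(merged) - 1L + end(merged)) / 2)
    half <- floor(consensusWidth / 2)
    out <- GRanges(seqnames(merged),
                   IRanges(start = mid0 - half + 1L,
                           width = consensusWidth))
    mcols(out)$support <- supportAll
    mcols(out)$peak_id <- sprintf("enh_%s_%d", as.character(seqnames(out)),
                                  start(out) - 1L)
    sortIntervals(out)
}

#' Read gene models from a GTF file
#'
#' Imports \code{gene} and \code{exon} features only, keyed by the
#' \code{gene_id} attribute. The transcription start site is the 5' end of the
#' gene on its strand.
#'
#' @param path Path to a GTF file.
#' @return A list with \code{genes} (a \code{GRanges} with metadata columns
#'   \code{gene_id} and \code{tss}, the 1-based TSS position) and \code{exons}
#'   (a \code{GRangesList} keyed by gene_id; empty for genes without exon
#'   records).
#' @export
readGeneModels <- function(path) {
    gtf <- rtracklayer::import(path, format = "gtf")
    genes <- gtf[gtf$type == "gene"]
    if (length(genes) == 0L)
        stop("no gene features found in ", path)
    if (is.null(genes$gene_id) || anyNA(genes$gene_id))
        stop("GTF gene features must carry a gene_id attribute")
    mcols(genes) <- DataFrame(gene_id = genes$gene_id)
    mcols(genes)$tss <- ifelse(as.character(strand(genes)) == "-",
                               end(genes), start(genes))
    exons <- gtf[gtf$type == "exon"]
    exonsByGene <- GRangesList()
    if (length(exons) > 0L)
        exonsByGene <- GenomicRanges::split(exons, exons$gene_id)
    list(genes = genes, exons = exonsByGene)
}

#' Promoter window around the TSS
#'
#' Strand-aware promoter window extending \code{up} bp upstream and
#' \code{down} bp downstream of each gene's TSS (defaults 2000/500). Windows
#' are clipped at the chromosome start.
#'
#' @param genes A \code{GRanges} of genes with strand (+/-).
#' @param up,down Upstream / downstream extents in bp.
#' @return A \code{GRanges} of promoter windows, carrying the input metadata.
#' @examples
#' g <- GRanges("chr1", IRanges(10001, 12000), strand = "+")
#' promoterWindows(g)  # 8001-10500 (1-based), i.e. [8000, 10500) in BED
#' @export
promoterWindows <- function(genes, up = 2000L, down = 500L) {
    p <- promoters(genes, upstream = up, downstream = down)
    ## clip at chromosome start (no seqlengths assumed)
    clipped <- start(p) < 1L
    if (any(clipped))
        start(p)[clipped] <- 1L
    p
}

midpoint0 <- function(gr) floor((start(gr) - 1L + end(gr)) / 2)

## 1-bp GRanges at each interval's midpoint
midpointRanges <- function(gr) {
    GRanges(seqnames(gr), IRanges(midpoint0(gr) + 1L, width = 1L))
}

#' Classify peaks by genomic feature context
#'
#' Assigns each peak exactly one class by the position of its midpoint, with
#' priority promoter > exonic > intronic > intergenic. The promoter window is
#' strand-aware around the TSS (default -2000/+500).
#'
#' @param peaks A \code{GRanges} of peaks.
#' @param genes A \code{GRanges} of genes (as from \code{readGeneModels}).
#' @param exons Optional \code{GRangesList} of exons per gene.
#' @param promoterUp,promoterDown Promoter window extents in bp.
#' @return Factor parallel to \code{peaks} with levels
#'   \code{promoter, exonic, intronic, intergenic}.
#' @export
annotateFeatureClass <- function(peaks, genes, exons = NULL,
                                 promoterUp = 2000L, promoterDown = 500L) {
    mids <- midpointRanges(peaks)
    cls <- rep("intergenic", length(peaks))
    inGene <- overlapsAny(mids, genes, ignore.strand = TRUE)
    cls[inGene] <- "intronic"
    if (!is.null(exons) && length(exons)) {
        inExon <- overlapsAny(mids, unlist(exons, use.names = FALSE),
                              ignore.strand = TRUE)
        cls[inExon] <- "exonic"
    }
    prom <- promoterWindows(genes, up = promoterUp, down = promoterDown)
    inProm <- overlapsAny(mids, prom, ignore.strand = TRUE)
    cls[inProm] <- "promoter"
    factor(cls, levels = c("promoter", "exonic", "intronic", "intergenic"))
}

#' Nearest genes to a peak
#'
#' Ranks genes on the peak's chromosome by distance from the peak midpoint to
#' each gene's TSS and returns the closest \code{n} gene identifiers. Ties are
#' broken by lexicographic gene_id so the ranking is deterministic.
#'
#' @param peak A length-1 \code{GRanges}.
#' @param genes A \code{GRanges} with \code{gene_id} and \code{tss} metadata
#'   columns (as from \code{readGeneModels}).
#' @param n Number of genes to return (default 5); fewer are returned when the
#'   chromosome has fewer genes.
#' @return Character vector of gene identifiers, nearest first.
#' @export
nearestGenes <- function(peak, genes, n = 5L) {
    stopifnot(length(peak) == 1L, n >= 1L)
    onChrom <- genes[as.character(seqnames(genes)) ==
                     as.character(seqnames(peak))]
    if (length(onChrom) == 0L)
        return(character())
    mid <- midpoint0(peak) + 1L
    d <- abs(onChrom$tss - mid)
    ord <- order(d, onChrom$gene_id)
    onChrom$gene_id[utils::head(ord, n)]
}
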