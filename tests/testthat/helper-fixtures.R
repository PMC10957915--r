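## Small builders shared across test files. Coordinates in tests are written
## 0-based half-open (as in BED files) and converted here to GRanges.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
})

gr0 <- function(chrom, start0, end0, ...) {
    GRanges(chrom, IRanges(start0 + 1L, end0), ...)
}

## base-by-base coverage oracle: fraction of integer bp of the 0-based
## half-open target covered by the union of others
bruteOverlapFraction <- function(tStart0, tEnd0, othersStart0, othersEnd0) {
    bp <- tStart0:(tEnd0 - 1L)
    covered <- rep(FALSE, length(bp))
    for (i in seq_along(othersStart0))
        covered <- covered | (bp >= othersStart0[i] & bp < othersEnd0[i])
    mean(covered)
}

## pad-by-d/2, merge touching-or-overlapping by sort-and-sweep, unpad
bruteStitch <- function(start0, end0, d) {
    o <- order(start0)
    s <- start0[o] - d / 2; e <- end0[o] + d / 2
    outS <- s[1]; outE <- e[1]
    for (i in seq_along(s)[-1]) {
        if (s[i] <= outE[length(outE)]) {
            outE[length(outE)] <- max(outE[length(outE)], e[i])
        } else {
            outS <- c(outS, s[i]); outE <- c(outE, e[i])
        }
    }
    data.frame(start0 = outS + d / 2, end0 = outE - d / 2)
}

## chord-geometry oracle for the tangent cutoff: scan every candidate index,
## measure how far the curve sits below the chord, take the furthest point
## (largest index on ties)
bruteTangentCutoff <- function(y) {
    ys <- sort(y)
    n <- length(ys)
    chord <- ys[1] + (ys[n] - ys[1]) / (n - 1) * (seq_len(n) - 1)
    below <- chord - ys
    t <- max(which(abs(below - max(below)) < 1e-12))
    ys[t]
}

## a tiny gene set: two genes per chromosome on opposite strands
tinyGenes <- function() {
    g <- gr0(c("chr1", "chr1"), c(10000, 50000), c(12000, 52000),
             strand = c("+", "-"))
    g$gene_id <- c("GA", "GB")
    g$tss <- ifelse(as.character(strand(g)) == "-", end(g), start(g))
    g
}

randomSmallConfig <- function(seed = 11L) {
    syntheticConfig(seed = seed, nLoci = 100L, nGenes = 60L, nLoops = 80L,
                    cohortSize = 30L, nClustersPerChrom = 3L)
}
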