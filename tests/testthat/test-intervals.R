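test_that("readPeakBED parses fields and rejects malformed lines by number", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t0\t500\tp1\t7.5", bed)
    pk <- readPeakBED(bed)
    expect_equal(as.character(seqnames(pk)), "chr1")
    expect_equal(start(pk) - 1L, 0L)
    expect_equal(end(pk), 500L)
    expect_equal(pk$name, "p1")
    expect_equal(pk$signal, 7.5)

    writeLines(character(), bed)
    expect_length(readPeakBED(bed), 0L)

    writeLines("chr1\t500\t100", bed)
    expect_error(readPeakBED(bed), "line\\(s\\) 1")
    writeLines(c("chr1\t0\t500", "chr1\tx\t900"), bed)
    expect_error(readPeakBED(bed), "non-integer.*2")
})

test_that("readPeakBED output is sorted by chrom then start", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr2\t10\t20", "chr1\t500\t900", "chr1\t5\t50"), bed)
    pk <- readPeakBED(bed)
    expect_equal(as.character(seqnames(pk)), c("chr1", "chr1", "chr2"))
    expect_equal(start(pk), c(6L, 501L, 11L))
})

test_that("overlapFraction counts union coverage of the target", {
    tgt <- gr0("chr1", 0, 1000)
    expect_equal(overlapFraction(tgt, gr0("chr1", 0, 500)), 0.5)
    expect_equal(overlapFraction(tgt, GRanges()), 0)
    ## overlapping others are not double-counted
    others <- gr0(c("chr1", "chr1"), c(0, 300), c(400, 700))
    expect_equal(overlapFraction(tgt, others), 0.7)
    expect_equal(bruteOverlapFraction(0, 1000, c(0, 300), c(400, 700)), 0.7)
})

test_that("overlapFraction matches a base-by-base oracle on random layouts", {
    set.seed(401)
    for (rep in 1:25) {
        t0 <- sample(0:500, 1); t1 <- t0 + sample(50:400, 1)
        n <- sample(1:6, 1)
        s0 <- sample(0:900, n, replace = TRUE)
        e0 <- s0 + sample(20:300, n, replace = TRUE)
        got <- overlapFraction(gr0("chr1", t0, t1), gr0("chr1", s0, e0))
        expect_equal(got, bruteOverlapFraction(t0, t1, s0, e0))
    }
})

test_that("overlapFraction is invariant to order and to splitting others", {
    tgt <- gr0("chr1", 0, 1000)
    others <- gr0(rep("chr1", 3), c(100, 600, 350), c(400, 900, 700))
    base <- overlapFraction(tgt, others)
    expect_equal(overlapFraction(tgt, rev(others)), base)
    split <- gr0(rep("chr1", 5), c(100, 250, 600, 350, 500),
                 c(250, 400, 900, 500, 700))
    expect_equal(overlapFraction(tgt, split), base)
})

test_that("consensusPeaks merges, filters by support and resizes to 500 bp", {
    reps <- GRangesList(A = gr0("chr1", 100, 600), B = gr0("chr1", 400, 900))
    cp <- consensusPeaks(reps, minSupport = 2L)
    expect_length(cp, 1L)
    expect_equal(start(cp) - 1L, 250L)
    expect_equal(end(cp), 750L)
    expect_equal(cp$support, 2L)

    ## a peak present in one replicate only is dropped at min_support 2
    reps <- GRangesList(A = gr0(c("chr1", "chr1"), c(0, 5000), c(100, 5600)),
                        B = gr0("chr1", 5400, 5900))
    cp <- consensusPeaks(reps, minSupport = 2L)
    expect_length(cp, 1L)
    expect_true(all(width(cp) == 500L))

    expect_error(consensusPeaks(GRangesList(A = gr0("chr1", 0, 100)),
                                minSupport = 2L), "exceeds")
})

test_that("consensusPeaks is independent of replicate order, width always 500", {
    set.seed(402)
    reps <- lapply(1:3, function(i) {
        s0 <- sort(sample(seq(0, 5e4, by = 100), 12))
        gr0("chr1", s0, s0 + sample(200:800, 12, replace = TRUE))
    })
    names(reps) <- c("A", "B", "C")
    a <- consensusPeaks(GRangesList(reps))
    b <- consensusPeaks(GRangesList(reps[c(3, 1, 2)]))
    expect_true(all(width(a) == 500L))
    expect_identical(granges(a), granges(b))
    expect_identical(a$support, b$support)
})

test_that("promoterWindows follows the strand-aware -2000/+500 rule", {
    plus <- gr0("chr1", 10000, 12000, strand = "+")
    p <- promoterWindows(plus)
    expect_equal(start(p) - 1L, 8000L)
    expect_equal(end(p), 10500L)

    minus <- gr0("chr1", 8000, 10001, strand = "-")  # tss0 = 10000
    p <- promoterWindows(minus)
    expect_equal(start(p) - 1L, 9501L)
    expect_equal(end(p), 12001L)

    nearEdge <- gr0("chr1", 1000, 3000, strand = "+")
    p <- promoterWindows(nearEdge)
    expect_equal(start(p), 1L)
    expect_equal(end(p), 1500L)

    ## width = up + down whenever no clipping occurs
    expect_equal(width(promoterWindows(plus, up = 1500, down = 300)), 1800L)
})

test_that("annotateFeatureClass assigns one class per peak with priority", {
    genes <- tinyGenes()
    exons <- GRangesList(GA = gr0("chr1", 11000, 11300),
                         GB = gr0("chr1", 50000, 50300))
    peaks <- gr0(rep("chr1", 4),
                 c(9000, 11000, 11500, 200000),
                 c(9400, 11400, 11900, 200400))
    cls <- annotateFeatureClass(peaks, genes, exons)
    expect_equal(as.character(cls),
                 c("promoter", "exonic", "intronic", "intergenic"))
    expect_false(anyNA(cls))
})

test_that("nearestGenes ranks by midpoint-to-TSS distance with id tie-break", {
    genes <- gr0(rep("chr1", 6), seq(1000, 6000, by = 1000) * 10,
                 seq(1000, 6000, by = 1000) * 10 + 2000, strand = "+")
    genes$gene_id <- paste0("G", 1:6)
    genes$tss <- start(genes)
    pk <- gr0("chr1", 9000, 9400)
    expect_equal(nearestGenes(pk, genes, n = 5), paste0("G", 1:5))
    expect_equal(nearestGenes(pk, genes[1:2], n = 5), c("G1", "G2"))

    ## random layout equals an exhaustive sort oracle
    set.seed(403)
    gs0 <- sample(1:5e6, 50)
    g <- gr0(rep("chr1", 50), gs0, gs0 + 2000, strand = "+")
    g$gene_id <- sprintf("G%02d", sample(50))
    g$tss <- start(g)
    mid <- 2500000
    pk <- gr0("chr1", mid - 200, mid + 200)
    oracle <- g$gene_id[order(abs(g$tss - (mid + 1)), g$gene_id)][1:5]
    expect_equal(nearestGenes(pk, g, n = 5), oracle)
})

test_that("GTF gene models round-trip through the generator's writer", {
    dir <- withr::local_tempdir()
    gen <- generateSyntheticData(randomSmallConfig(), dir)
    gm <- readGeneModels(gen$manifest$genes_gtf)
    expect_equal(length(gm$genes), 60L)
    expect_true(all(c("gene_id", "tss") %in% names(mcols(gm$genes))))
    expect_true(all(lengths(gm$exons) == 2L))
    minus <- gm$genes[as.character(strand(gm$genes)) == "-"]
    expect_equal(minus$tss, end(minus))
})
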