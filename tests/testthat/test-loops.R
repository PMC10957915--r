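mkFeatures <- function(mid0, prefix = "E") {
    g <- gr0(rep("chr1", length(mid0)), mid0 - 250, mid0 + 250)
    if (prefix == "E") g$peak_id <- paste0("E", seq_along(mid0))
    else g$gene_id <- paste0("P", seq_along(mid0))
    g
}

mkLoop <- function(m1, m2, ...) {
    LoopSet(gr0("chr1", m1 - 1250, m1 + 1250),
            gr0("chr1", m2 - 1250, m2 + 1250), ...)
}

test_that("LoopSet enforces anchor width and the 10 kb - 2 Mb distance window", {
    ls <- mkLoop(20000, 50000, loop_id = "l1", log2fc = -1, fdr = 0.01)
    expect_equal(loopDistance(ls), 30000)
    expect_error(LoopSet(gr0("chr1", 0, 2000), gr0("chr1", 50000, 52500)),
                 "2500")
    expect_error(mkLoop(20000, 29000), "separation")       # 9 kb apart
    expect_error(mkLoop(20000, 2.5e6), "separation")       # beyond 2 Mb
    expect_error(LoopSet(gr0("chr1", 0, 2500), gr0("chr2", 50000, 52500)),
                 "intra-chromosomal")
})

test_that("anchor annotation reports every >=1 bp overlap split by kind", {
    enh <- mkFeatures(c(20000, 21000))
    prom <- mkFeatures(50000, prefix = "P")
    anchors <- gr0(rep("chr1", 3), c(19000, 49000, 200000),
                   c(21500, 51500, 202500))
    ann <- annotateAnchor(anchors, enh, prom)
    expect_setequal(ann$enhancers[[1]], c("E1", "E2"))
    expect_length(ann$promoters[[1]], 0L)
    expect_equal(ann$promoters[[2]], "P1")
    expect_length(ann$enhancers[[3]], 0L)

    ## random anchors/features equal a brute-force all-pairs overlap
    set.seed(801)
    feats <- mkFeatures(sort(sample(seq(1000, 9e5, by = 700), 200)))
    a0 <- sample(seq(0, 9e5, by = 500), 200)
    anchors <- gr0(rep("chr1", 200), a0, a0 + 2500)
    ann <- annotateAnchor(anchors, feats, GRanges())
    for (i in sample(200, 25)) {
        oracle <- feats$peak_id[start(feats) <= end(anchors)[i] &
                                end(feats) >= start(anchors)[i]]
        expect_setequal(ann$enhancers[[i]], oracle)
    }
})

test_that("inclusive classification emits every cross-anchor pair once", {
    enh <- mkFeatures(c(20000, 21000, 60000, 100000))
    prom <- mkFeatures(c(20500, 61000, 140000), prefix = "P")

    ## ann1 = {E1}, ann2 = {P3}: a single EP pair, enhancer first
    ls <- mkLoop(100000, 140000, loop_id = "a", log2fc = 0, fdr = 0.5)
    out <- classifyLoops(ls, enh[4], prom[3])
    expect_equal(nrow(out), 1L)
    expect_equal(out$type, "EP")
    expect_equal(out$feature1, "E4")
    expect_equal(out$feature2, "P3")

    ## ann1 = {E1, E2, P1}, ann2 = {E3, P2}: full cartesian product
    ls <- mkLoop(20500, 60500, loop_id = "b", log2fc = 0, fdr = 0.5)
    out <- classifyLoops(ls, enh, prom)
    expect_equal(nrow(out), 6L)
    expect_equal(sum(out$type == "EE"), 2L)
    expect_equal(sum(out$type == "EP"), 3L)
    expect_equal(sum(out$type == "PP"), 1L)

    ## an anchor with no features yields one unassigned record
    ls <- mkLoop(200000, 240000, loop_id = "c", log2fc = 0, fdr = 0.5)
    out <- classifyLoops(ls, enh, prom)
    expect_equal(out$type, "unassigned")
    expect_true(is.na(out$feature1))
})

test_that("classification equals the cartesian-product oracle and is symmetric", {
    set.seed(802)
    ## features tiled so anchor placement controls the annotation sets
    enh <- mkFeatures(seq(5000, 995000, by = 5000))
    prom <- mkFeatures(seq(7500, 997500, by = 5000), prefix = "P")
    m1 <- sample(seq(10000, 4e5, by = 500), 120)
    m2 <- m1 + sample(seq(15000, 1.5e6, by = 500), 120, replace = TRUE)
    ls <- LoopSet(gr0(rep("chr1", 120), m1 - 1250, m1 + 1250),
                  gr0(rep("chr1", 120), m2 - 1250, m2 + 1250),
                  loop_id = sprintf("l%03d", 1:120),
                  log2fc = rnorm(120), fdr = runif(120))
    out <- classifyLoops(ls, enh, prom)
    ann1 <- annotateAnchor(anchorOne(ls), enh, prom)
    ann2 <- annotateAnchor(anchorTwo(ls), enh, prom)
    for (i in seq_len(length(ls))) {
        rows <- out[out$loop_id == sprintf("l%03d", i), ]
        f1 <- c(ann1$enhancers[[i]], ann1$promoters[[i]])
        f2 <- c(ann2$enhancers[[i]], ann2$promoters[[i]])
        if (length(f1) == 0L || length(f2) == 0L) {
            expect_equal(rows$type, "unassigned")
            next
        }
        oracle <- unique(t(apply(expand.grid(f1, f2,
                                             stringsAsFactors = FALSE),
                                 1, sort)))
        expect_equal(nrow(rows), nrow(oracle))
        got <- t(apply(rows[, c("feature1", "feature2")], 1, sort))
        expect_setequal(paste(got[, 1], got[, 2]),
                        paste(oracle[, 1], oracle[, 2]))
    }
    ## swapping the anchors yields the same pair set
    swapped <- LoopSet(anchorTwo(ls), anchorOne(ls),
                       loop_id = loopData(ls)$loop_id,
                       log2fc = loopData(ls)$log2fc, fdr = loopData(ls)$fdr)
    out2 <- classifyLoops(swapped, enh, prom)
    key <- function(d) sort(paste(d$loop_id, pmin(d$feature1, d$feature2),
                                  pmax(d$feature1, d$feature2), d$type))
    expect_equal(key(out), key(out2))
})

test_that("BEDPE round-trips through the reader and writer", {
    ls <- mkLoop(c(20000, 50000), c(50000, 90000),
                 loop_id = c("l1", "l2"), contact_a = c(10, 20),
                 contact_b = c(5, 40), log2fc = c(-1, 1),
                 fdr = c(0.01, 0.8))
    f <- withr::local_tempfile(fileext = ".bedpe")
    writeLoopsBEDPE(ls, f)
    back <- readLoopsBEDPE(f)
    expect_equal(granges(anchorOne(back)), granges(anchorOne(ls)))
    expect_equal(loopData(back)$log2fc, loopData(ls)$log2fc)
    expect_equal(loopData(back)$loop_id, c("l1", "l2"))
})

test_that("master table joins dynamics and flags without dropping rows", {
    enh <- mkFeatures(c(20000, 60000))
    prom <- mkFeatures(c(50000, 100000), prefix = "P")
    ls <- mkLoop(c(20000, 60000, 60000), c(50000, 100000, 100000),
                 loop_id = c("l1", "l2", "l3"),
                 log2fc = c(-1.5, 0.2, -0.7), fdr = c(0.01, 0.04, 0.02))
    pairs <- classifyLoops(ls, enh, prom)
    enhDiff <- data.frame(feature_id = c("E1", "E2"), log2fc = c(-2, 0.1),
                          fdr = c(0.001, 0.6))
    geneDiff <- data.frame(feature_id = "P1", log2fc = -1.1, fdr = 0.02)
    p52 <- gr0("chr1", 19900, 20300)
    ses <- gr0("chr1", 59000, 62000)
    stab <- enh
    stab$stabilo_class <- factor(c("de_novo", "preserved"),
                                 levels = levels(classifyStabilo(TRUE, TRUE,
                                                                 TRUE)))
    expect_message(
        mt <- buildMasterTable(pairs, enh, enhDiff, geneDiff, p52Peaks = p52,
                               consensusSEs = ses, stabiloCalls = stab,
                               patientEpigenome = data.frame(
                                   feature_id = "E1", log2fc = 2, fdr = 0.01),
                               patientExpression = data.frame(
                                   feature_id = "P1", log2fc = -1, fdr = 0.01),
                               essentialGenes = "P2"),
        "absent")
    ## one row per (enhancer, gene, loop): the repeated EP pair keeps both loops
    expect_equal(nrow(mt), 3L)
    expect_equal(sum(mt$loop_id == "l3"), 1L)
    r1 <- mt[mt$loop_id == "l1", ]
    expect_equal(r1$enh_log2fc, -2)
    expect_equal(r1$gene_log2fc, -1.1)
    expect_true(r1$p52_bound)
    expect_false(r1$se_member)
    expect_equal(r1$stabilo_class, "de_novo")
    expect_true(r1$nfkb_enriched_epigenome)
    expect_false(r1$nfkb_enriched_expression)  # negative log2fc
    expect_false(r1$essential)
    r2 <- mt[mt$loop_id == "l2", ]
    expect_true(r2$se_member)
    expect_true(is.na(r2$gene_log2fc))  # P2 missing from the table, kept
    expect_true(r2$essential)
})

test_that("summaries reproduce printed count/percent arithmetic", {
    expect_equal(countPercent(889, 2868)$percent, 31)
    expect_equal(countPercent(180, 2606)$percent, 7)
    s <- loopDiffSummary(44476, 30651)
    expect_equal(s$percent, 69)
    expect_equal(loopDiffSummary(10, 0)$percent, 0)
    expect_error(loopDiffSummary(0, 0), "no loops")
    expect_error(loopDiffSummary(5, 6), "subset")
    ## random subsets match direct division
    set.seed(803)
    for (rep in 1:20) {
        n <- sample(50:5000, 1); k <- sample(0:n, 1)
        expect_equal(loopDiffSummary(n, k)$percent, floor(100 * k / n + 0.5))
    }
})

test_that("concordance reports correlations and significance categories", {
    df <- data.frame(enh_log2fc = c(-2, -1, 1, 2), gene_log2fc = c(-2, -1, 1, 2),
                     enh_fdr = 0.01, gene_fdr = 0.01)
    cs <- concordanceSummary(df)
    expect_equal(cs$pearson, 1)
    expect_equal(cs$spearman, 1)
    expect_equal(cs$categories$concordant_down$count, 2)
    expect_equal(cs$categories$concordant_down$percent, 50)
    ## degenerate variance -> undefined correlation
    df$gene_log2fc <- 0
    expect_true(is.na(concordanceSummary(df)$pearson))
    expect_error(concordanceSummary(df[1:2, ]), "at least 3")
})
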