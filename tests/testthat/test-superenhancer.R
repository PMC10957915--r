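sigPeaks <- function(start0, end0, signal) {
    g <- gr0(rep("chr1", length(start0)), start0, end0)
    g$signal <- signal
    g
}

test_that("TSS exclusion removes peaks overlapping the 2.5 kb windows", {
    genes <- tinyGenes()  # TSS at 10000 (+) and 52000 (-)
    peaks <- sigPeaks(c(9000, 200000, 51000), c(9400, 200500, 51200),
                      c(1, 2, 3))
    kept <- excludeTSSPeaks(peaks, genes)
    expect_equal(kept$signal, 2)

    ## random layout equals a brute-force window-overlap filter
    set.seed(701)
    rs0 <- sample(0:3e5, 60)
    pk <- sigPeaks(rs0, rs0 + 400, runif(60))
    kept <- excludeTSSPeaks(pk, genes)
    tss0 <- genes$tss - 1L
    overlapsWin <- function(s0, e0)
        any(s0 < tss0 + 2500 & e0 > tss0 - 2500)
    keepOracle <- !mapply(overlapsWin, start(pk) - 1L, end(pk))
    expect_equal(start(kept), start(pk)[keepOracle])
})

test_that("stitching merges peaks by the 12.5 kb gap rule", {
    r <- stitchPeaks(sigPeaks(c(0, 12000), c(500, 12500), c(5, 7)))
    expect_length(r, 1L)
    expect_equal(c(start(r) - 1L, end(r)), c(0, 12500))
    expect_equal(r$signal, 12)
    expect_equal(r$n_constituents, 2L)

    r <- stitchPeaks(sigPeaks(c(0, 13100), c(500, 13600), c(5, 7)))
    expect_length(r, 2L)
    ## boundary: gap of exactly 12500 still merges
    r <- stitchPeaks(sigPeaks(c(0, 13000), c(500, 13500), c(5, 7)))
    expect_length(r, 1L)
})

test_that("stitch equals the pad-merge-unpad oracle and is idempotent", {
    set.seed(702)
    for (rep in 1:30) {
        n <- sample(5:50, 1)
        s0 <- sort(sample(seq(0, 8e5, by = 50), n))
        e0 <- s0 + sample(200:2000, n, replace = TRUE)
        pk <- sigPeaks(s0, e0, runif(n, 1, 10))
        got <- stitchPeaks(pk)
        oracle <- bruteStitch(s0, e0, 12500)
        expect_equal(start(got) - 1L, oracle$start0)
        expect_equal(end(got), oracle$end0)
        expect_equal(sum(got$signal), sum(pk$signal))
        ## idempotence: restitching the stitched regions changes nothing
    	again <- stitchPeaks(got)
        expect_equal(granges(again), granges(got))
        expect_equal(again$signal, got$signal)
    }
})

test_that("tangent cutoff flags the hockey-stick outlier and no more", {
    r <- tangentCutoff(stitchPeaks(sigPeaks(seq(0, 4) * 1e5,
                                            seq(0, 4) * 1e5 + 500,
                                            c(1, 1, 1, 1, 100))))
    expect_equal(r$is_super, r$signal == 100)
    expect_equal(r$rank[r$signal == 100], 1L)

    ## perfectly linear signals: the curve never exceeds its chord interiorly
    lin <- tangentCutoff(stitchPeaks(sigPeaks(seq(0, 9) * 1e5,
                                              seq(0, 9) * 1e5 + 500, 1:10)))
    expect_false(any(lin$is_super))

    expect_error(tangentCutoff(stitchPeaks(sigPeaks(c(0, 1e5),
                                                    c(500, 1e5 + 500),
                                                    c(1, 2)))),
                 "at least 3")
    expect_warning(
        flat <- tangentCutoff(stitchPeaks(sigPeaks(seq(0, 4) * 1e5,
                                                   seq(0, 4) * 1e5 + 500,
                                                   rep(2, 5)))),
        "identical")
    expect_false(any(flat$is_super))
})

test_that("cutoff matches the brute-force chord scan and is affine-invariant", {
    set.seed(703)
    for (rep in 1:100) {
        n <- sample(5:60, 1)
        y <- switch(sample(3, 1),
                    rlnorm(n, 1, 1),
                    c(runif(n - 2, 0, 5), runif(2, 50, 100)),
                    runif(n, 0, 10))
        regions <- stitchPeaks(sigPeaks(seq_len(n) * 1e5,
                                        seq_len(n) * 1e5 + 500, y))
        got <- tangentCutoff(regions)
        cutoff <- bruteTangentCutoff(y)
        expect_equal(got$is_super, got$signal > cutoff)
        expect_lte(sum(got$is_super), n - 1L)
        ## positive affine rescaling leaves the assignment unchanged
        a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
        mcols(regions)$signal <- a * y + b
        expect_equal(tangentCutoff(regions)$is_super, got$is_super)
    }
})

test_that("consensus SEs merge across samples with >=50% re-assignment", {
    se <- gr0("chr1", 10000, 30000)
    cons <- consensusSE(list(s1 = se, s2 = se))
    expect_length(cons, 1L)
    expect_setequal(cons$member_samples[[1]], c("s1", "s2"))

    ## membership is measured on the original sample SE length
    consensus <- gr0("chr1", 0, 10000)
    short <- gr0("chr1", 6000, 16000)   # 40% inside -> not a member
    long <- gr0("chr1", 4000, 14000)    # 60% inside -> member
    mem <- assignSEMembership(consensus, list(a = short, b = long))
    expect_equal(mem[[1]], "b")

    ## random layouts equal a brute-force membership oracle
    set.seed(704)
    for (rep in 1:20) {
        samples <- lapply(1:3, function(i) {
            s0 <- sort(sample(seq(0, 5e5, by = 1000), 5))
            gr0(rep("chr1", 5), s0, s0 + sample(5000:20000, 5, replace = TRUE))
        })
        names(samples) <- paste0("s", 1:3)
        cons <- consensusSE(samples)
        for (ci in seq_along(cons)) {
            expected <- names(samples)[vapply(samples, function(gg) {
                ov <- pmin(end(gg), end(cons)[ci]) -
                    pmax(start(gg), start(cons)[ci]) + 1
                any(ov / width(gg) >= 0.5)
            }, logical(1))]
            expect_setequal(cons$member_samples[[ci]], expected)
        }
    }
})

test_that("constituents attach by midpoint containment only", {
    ses <- gr0("chr1", 10000, 20000)
    ses$se_id <- "se_1"
    peaks <- gr0(rep("chr1", 3), c(12000, 9600, 50000),
                 c(12500, 10100, 50500))
    peaks$peak_id <- c("in", "edge", "out")
    asg <- assignConstituents(ses, peaks)
    expect_equal(asg$peaks$se_member, c(TRUE, FALSE, FALSE))
    expect_equal(asg$ses$constituents[[1]], 1L)
})
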