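# brute-force clustering oracle: transitive closure of the gap relation,
# then greedy left-to-right width splitting by midpoint
bruteClusters <- function(f, tol) {
    o <- order(f$chrom, f$start)
    f <- f[o, ]
    id <- integer(nrow(f)); id[1] <- 1
    for (i in seq_len(nrow(f))[-1])
        id[i] <- if (f$chrom[i] == f$chrom[i - 1] &&
                     f$start[i] - f$end[i - 1] <= tol) id[i - 1] else
                     id[i - 1] + 1
    out <- integer(nrow(f)); out[o] <- id
    out
}

test_that("gap tolerance links at exactly tol and breaks beyond", {
    f1 <- data.frame(chrom = "chr1", start = c(0, 560), end = c(300, 800))
    expect_equal(as.vector(mergeWindows(f1, tol = 260)), c(1L, 1L))
    f2 <- data.frame(chrom = "chr1", start = c(0, 561), end = c(300, 800))
    expect_equal(as.vector(mergeWindows(f2, tol = 260)), c(1L, 2L))
    f3 <- data.frame(chrom = "chr1", start = 100, end = 200)
    expect_equal(as.vector(mergeWindows(f3)), 1L)
    # chromosome change always breaks
    f4 <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 300),
                     end = c(300, 400))
    expect_equal(as.vector(mergeWindows(f4, tol = 1e6)), c(1L, 2L))
})

test_that("clustering matches the brute-force oracle on random layouts", {
    set.seed(30)
    for (i in 1:10) {
        n <- 80
        widths <- sample(50:400, n, replace = TRUE)
        gaps <- sample(0:600, n, replace = TRUE)
        start <- cumsum(gaps) + cumsum(c(0, widths[-n]))
        f <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        start = start, end = start + widths)
        f <- f[order(f$chrom, f$start), ]
        cl <- as.vector(mergeWindows(f, tol = 260, maxWidth = 1e9))
        expect_equal(cl, bruteClusters(f, 260))
        # with the width cap: no cluster span exceeds maxWidth and no
        # within-cluster gap exceeds tol
        cl2 <- as.vector(mergeWindows(f, tol = 260, maxWidth = 3000))
        for (k in unique(cl2)) {
            m <- f[cl2 == k, ]
            expect_lte(max(m$end) - min(m$start), 3000)
            if (nrow(m) > 1)
                expect_true(all(m$start[-1] - m$end[-nrow(m)] <= 260))
        }
        # splitting refines, never re-merges
        expect_true(all(tapply(cl, cl2, function(v) length(unique(v))) == 1))
    }
})

test_that("Simes combination follows min_k(m p_(k) / k) with BH across regions", {
    tests <- data.frame(chrom = "chr1",
                        start = c(0, 100, 200, 1000, 2000),
                        end = c(100, 200, 300, 1100, 2100),
                        index = 1:5,
                        logFC = c(1.2, 0.1, -0.4, 2.0, 0.7),
                        p.value = c(0.01, 0.04, 0.9, 0.01, 0.02))
    cl <- c(1L, 1L, 1L, 2L, 3L)
    reg <- combineTests(tests, cl)
    expect_equal(reg$p.simes, c(0.03, 0.01, 0.02))  # {3p/k} = {.03,.06,.9}
    expect_equal(reg$n.members, c(3L, 1L, 1L))
    # representative logFC comes from the smallest-p member
    expect_equal(reg$logFC, c(1.2, 2.0, 0.7))
    expect_equal(reg$best, c(1L, 4L, 5L))
    # BH by hand on {0.03, 0.01, 0.02}: {0.03, 0.03, 0.03}
    expect_equal(reg$fdr, rep(0.03, 3))
    expect_equal(reg$members, list(c(1L, 2L, 3L), 4L, 5L))
})

test_that("Simes p dominates m * min(p) and reduces to p for singletons", {
    set.seed(31)
    for (i in 1:50) {
        m <- sample(1:10, 1)
        p <- runif(m)
        tests <- data.frame(chrom = "chr1", start = (1:m) * 100,
                            end = (1:m) * 100 + 50, index = 1:m,
                            logFC = rnorm(m), p.value = p)
        reg <- combineTests(tests, rep(1L, m))
        ps <- sort(p)
        expect_equal(reg$p.simes, min(m * ps / seq_len(m)))
        expect_lte(reg$p.simes, m * min(p) + 1e-12)
        expect_gte(reg$p.simes, min(p) - 1e-12)
    }
})

test_that("peak calls apply strict FDR and positive-logFC thresholds", {
    reg <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350), n.members = 1L,
                      p.simes = 0.01, logFC = c(1.2, 0.3, 1.0, -2.0),
                      best = 1:4, fdr = c(0.05, 0.05, 0.10, 0.01))
    reg$members <- as.list(1:4)
    called <- callPeaks(reg, fdr = 0.1, minLogfc = 0.5)
    # 0.10 exactly fails "smaller than"; 0.3 fails logFC; -2 fails direction
    expect_equal(called$start, 0)
    expect_equal(callPeaks(reg, fdr = 0.1, minLogfc = 0.5)$logFC, 1.2)
})

test_that("high-confidence selection applies log2 and CV cutoffs on POI CPM", {
    # three DamPOI replicates, library sizes 1e6 -> CPM == counts
    counts <- cbind(Dam = c(1, 1, 1), Dam2 = c(1, 1, 1),
                    P1 = c(30, 100, 22), P2 = c(30, 1, 23),
                    P3 = c(30, 1, 22))
    cm <- countMatrixFixture(counts,
                             c("Dam", "Dam", "DamPOI", "DamPOI", "DamPOI"),
                             libSizes = rep(1e6, 5))
    peaks <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                        end = c(100, 200, 300), n.members = 1L,
                        p.simes = 0.01, logFC = 1, best = 1:3,
                        fdr = 0.01)
    peaks$members <- list(1L, 2L, 3L)
    hc <- selectHighConfidence(peaks, cm)
    # peak 1: CPM {30,30,30}: mean log2 = 4.907 > 4.5, CV = 0 -> kept
    # peak 2: CPM {100,1,1}: CV = sd/mean = 1.68 -> dropped
    # peak 3: CPM {22,23,22}: mean log2 = 4.48 < 4.5 (strict) -> dropped
    expect_equal(hc$start, 0)
    expect_equal(hc$cv, 0)
    expect_equal(hc$mean.log2.cpm, log2(30), tolerance = 1e-12)
    expect_error(selectHighConfidence(peaks, countMatrixFixture(
        counts[, 1:3], c("Dam", "Dam", "DamPOI"), rep(1e6, 3))),
        "replicates")
})

test_that("peak sets round-trip through BED/TSV with capped scores", {
    reg <- data.frame(chrom = c("chr1", "chr1"), start = c(0, 500),
                      end = c(300, 900), n.members = c(2L, 1L),
                      p.simes = c(1e-4, 0.2), logFC = c(1.5, 0.2),
                      best = c(1L, 3L), fdr = c(0, 0.2))
    reg$members <- list(c(1L, 2L), 3L)
    prefix <- withr::local_tempfile()
    writePeaks(reg, prefix)
    bed <- utils::read.table(paste0(prefix, ".bed"), sep = "\t")
    expect_equal(bed$V5, c(1000, pmin(round(-log10(0.2), 3), 1000)))
    back <- readPeaks(paste0(prefix, ".tsv"))
    expect_equal(back$members, reg$members)
    expect_equal(back$fdr, reg$fdr)
    # empty set still writes valid files
    writePeaks(reg[0, ], prefix)
    expect_equal(length(readLines(paste0(prefix, ".bed"))), 0L)
})
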