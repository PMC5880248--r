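test_that("aveLogCPM follows its closed form and is scale-invariant", {
    cm <- countMatrixFixture(matrix(10, 1, 2), c("Dam", "DamPOI"),
                             libSizes = c(1e6, 1e6))
    expect_equal(aveLogCpm(cm), log2(12e6 / (1e6 + 4)), tolerance = 1e-10)
    # zero counts stay finite through the pseudocount
    cm0 <- countMatrixFixture(matrix(0, 3, 2), c("Dam", "DamPOI"),
                              libSizes = c(1e5, 1e5))
    expect_true(all(is.finite(aveLogCpm(cm0))))
    expect_equal(aveLogCpm(cm0), rep(log2(2 / (1e5 + 4) * 1e6), 3))
    # doubling counts and libraries is invariant up to the fixed pseudocount
    # (exactly invariant when the pseudocount doubles with the depth)
    set.seed(1)
    y <- matrix(rpois(60, 50), 20, 3)
    a1 <- aveLogCpm(countMatrixFixture(y, c("Dam", "Dam", "DamPOI"),
                                       libSizes = c(1e6, 1e6, 1e6)))
    cm2x <- countMatrixFixture(2 * y, c("Dam", "Dam", "DamPOI"),
                               libSizes = c(2e6, 2e6, 2e6))
    expect_equal(a1, aveLogCpm(cm2x), tolerance = 0.05)
    expect_equal(a1, aveLogCpm(cm2x, prior = 4), tolerance = 1e-10)
    expect_error(aveLogCpm(countMatrixFixture(y, c("Dam", "Dam", "DamPOI"),
                                              libSizes = c(0, 1, 1))),
                 "library")
})

test_that("the 10-count abundance filter drops '10 or lower' inclusively", {
    counts <- rbind(rep(10, 4), rep(11, 4), rep(300, 4), rep(0, 4))
    cm <- countMatrixFixture(counts, c("Dam", "Dam", "DamPOI", "DamPOI"),
                             libSizes = rep(1e6, 4))
    filt <- filterLowAbundance(cm, countThreshold = 10)
    expect_equal(attr(filt, "retained"), c(2L, 3L))  # 10 exactly is removed
    expect_equal(filt$fragments$index, c(2L, 3L))
    # threshold 0 with prior 0 keeps everything with any count
    filt0 <- filterLowAbundance(cm, countThreshold = 0, prior = 0)
    expect_equal(attr(filt0, "retained"), c(1L, 2L, 3L))
    expect_error(filterLowAbundance(cm, countThreshold = -1), "negative")
    # removing fragments never changes the survivors' aveLogCPM
    expect_equal(aveLogCpm(filt), aveLogCpm(cm)[attr(filt, "retained")])
})

test_that("TMM factors recover known scalings and agree with edgeR", {
    set.seed(5)
    base <- rpois(500, 100)
    counts <- cbind(base, base)
    cm <- countMatrixFixture(counts, c("Dam", "DamPOI"),
                             libSizes = c(sum(base), sum(base)))
    expect_equal(unname(tmmFactors(cm)), c(1, 1))
    # one column doubled at equal recorded library sizes: all M equal,
    # factors are {1/sqrt(2), sqrt(2)} after geometric-mean rescaling
    cm2 <- countMatrixFixture(cbind(base, 2 * base), c("Dam", "DamPOI"),
                              libSizes = c(1e5, 1e5))
    f2 <- unname(tmmFactors(cm2))
    expect_equal(sort(f2), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
    expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
    # cross-check against the independent reference implementation
    skip_if_not_installed("edgeR")
    set.seed(6)
    y <- matrix(rnbinom(4000, mu = 80, size = 5), 1000, 4)
    y[1:50, 3:4] <- y[1:50, 3:4] * 4L
    libs <- colSums(y)
    cm3 <- countMatrixFixture(y, c("Dam", "Dam", "DamPOI", "DamPOI"),
                              libSizes = libs)
    ours <- unname(tmmFactors(cm3))
    ref <- unname(edgeR::calcNormFactors(y, lib.size = libs, method = "TMM"))
    expect_equal(ours, ref, tolerance = 0.02)
})

test_that("logCPM reduces to the plain formula at unit factors", {
    set.seed(2)
    y <- matrix(rpois(30, 40), 10, 3)
    cm <- countMatrixFixture(y, c("Dam", "Dam", "DamPOI"),
                             libSizes = rep(2e5, 3))
    lc <- logCpm(cm)
    expect_equal(unname(lc), log2((y + 2) / (2e5 + 4) * 1e6),
                 ignore_attr = TRUE)
    # all-zero rows give constant columns when libraries are equal
    cm0 <- countMatrixFixture(matrix(0, 4, 3), c("Dam", "Dam", "DamPOI"),
                              libSizes = rep(1e5, 3))
    expect_equal(length(unique(as.vector(logCpm(cm0)))), 1L)
    # consistency with aveLogCPM at equal depth and equal per-sample counts
    yc <- matrix(rep(rpois(10, 40), 3), 10, 3)
    cmc <- countMatrixFixture(yc, c("Dam", "Dam", "DamPOI"),
                              libSizes = rep(2e5, 3))
    expect_equal(rowMeans(logCpm(cmc)), aveLogCpm(cmc), tolerance = 1e-6)
})

# brute-force quantile normalization: every column gets the mean sorted value
bruteQuantileNorm <- function(x) {
    ref <- rowMeans(apply(x, 2, sort))
    apply(x, 2, function(col) {
        out <- numeric(length(col))
        out[order(col)] <- ref
        stats::ave(out, col, FUN = mean)
    })
}

test_that("qsmooth degenerates to quantile normalization for one group", {
    set.seed(7)
    x <- matrix(rnorm(600, sd = 2) + rep(rnorm(6, sd = 0.5), each = 100),
                100, 6)
    qs <- qsmooth(x, rep("Dam", 6))
    expect_equal(unname(qs), unname(bruteQuantileNorm(x)), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("qsmooth preserves genuine group structure (weights near zero)", {
    set.seed(8)
    base <- sort(rnorm(200))
    # identical columns within group, constant shift between groups:
    # all variability is between-group, so w ~ 0 and the shift survives
    x <- cbind(base, base, base + 5, base + 5)
    qs <- qsmooth(x, c("Dam", "Dam", "DamPOI", "DamPOI"))
    expect_lt(max(attr(qs, "weights")), 1e-8)
    expect_equal(unname(qs[, 3] - qs[, 1]), rep(5, 200))
    # within-sample ranks never change (monotone map)
    set.seed(9)
    y <- matrix(rnorm(500), 100, 5)
    qy <- qsmooth(y, c("Dam", "Dam", "Dam", "DamPOI", "DamPOI"))
    for (s in 1:5)
        expect_equal(stats::cor(y[, s], qy[, s], method = "spearman"), 1)
})

test_that("qsmooth is idempotent and matches brute force at forced weights", {
    set.seed(10)
    x <- matrix(rnorm(400), 100, 4)
    g <- c("Dam", "Dam", "DamPOI", "DamPOI")
    once <- qsmooth(x, g)
    twice <- qsmooth(once, g)
    expect_equal(unname(twice), unname(once), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # w == 1 everywhere equals full quantile normalization: single group
    # forces SSB = 0, checked above; w == 0 equals within-group quantile
    # normalization, brute-forced here via the shifted construction
    base <- sort(rexp(150))
    z <- cbind(base, base, base + 3, base + 3)
    qz <- qsmooth(z, g)
    withinRef <- cbind(bruteQuantileNorm(z[, 1:2]), bruteQuantileNorm(z[, 3:4]))
    expect_equal(unname(qz), unname(withinRef), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("tie handling averages tied positions deterministically", {
    x <- cbind(c(1, 1, 5, 7), c(2, 4, 4, 9))
    qs <- qsmooth(x, c("Dam", "Dam"))
    ref <- rowMeans(apply(x, 2, sort))
    expect_equal(qs[1, 1], mean(ref[1:2]))
    expect_equal(qs[2, 1], mean(ref[1:2]))
    expect_equal(qs[2, 2], mean(ref[2:3]))
    expect_equal(qs[3, 2], mean(ref[2:3]))
})

test_that("the distribution-difference permutation test behaves at the extremes", {
    # identical columns in both groups: statistic guarded to 0, p = 1
    x <- matrix(rep(sort(rnorm(50)), 4), 50, 4)
    res <- quantroTest(x, c("Dam", "Dam", "DamPOI", "DamPOI"), nPerm = 19,
                       seed = 1)
    expect_equal(res$statistic, 0)
    expect_equal(res$p.value, 1)
    # a 5-SD group shift is detected at 19 permutations; n = 4+4 keeps the
    # share of group-equivalent relabelings (which always tie the observed
    # statistic) below the permutation resolution
    set.seed(12)
    y <- cbind(matrix(rnorm(400), 100, 4), matrix(rnorm(400, 5), 100, 4))
    g <- rep(c("Dam", "DamPOI"), each = 4)
    res2 <- quantroTest(y, g, nPerm = 19, seed = 2)
    expect_lte(res2$p.value, 0.1)
    # reproducible under the seed contract
    res3 <- quantroTest(y, g, nPerm = 19, seed = 2)
    expect_identical(res2, res3)
    expect_error(quantroTest(y, g, nPerm = 0), "nPerm")
    expect_error(quantroTest(y, rep("Dam", 6)), "two groups")
})
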