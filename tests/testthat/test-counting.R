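test_that("alignment filtering keeps primary mapped reads and reports stats", {
    sam <- withr::local_tempfile(fileext = ".sam")
    writeSamFixture(sam, c(chr1 = 1000L), list(
        list(chrom = "chr1", pos1 = 11, cigar = "50M", flag = 0),
        list(chrom = "chr1", pos1 = 21, cigar = "50M", flag = 256),
        list(chrom = "chr1", pos1 = 1, cigar = "50M", flag = 4),
        list(chrom = "chr1", pos1 = 31, cigar = "50M", flag = 2048)))
    fa <- filterAlignments(sam)
    expect_equal(nrow(fa$reads), 1L)
    expect_equal(fa$reads$start, 10L)   # SAM POS 11 -> 0-based 10
    expect_equal(fa$reads$end, 60L)
    expect_equal(unname(fa$stats[c("unmapped", "secondary", "supplementary",
                                   "retained")]),
                 c(1, 1, 1, 1))
})

test_that("uninformative contigs and blacklist overlaps are removed", {
    sam <- withr::local_tempfile(fileext = ".sam")
    writeSamFixture(sam, c(chr1 = 1000L, chrM = 500L, chr1_random = 500L),
                    list(
        list(chrom = "chr1", pos1 = 101, cigar = "50M", flag = 0),
        list(chrom = "chrM", pos1 = 11, cigar = "50M", flag = 0),
        list(chrom = "chr1_random", pos1 = 11, cigar = "50M", flag = 0),
        # [151, 201) overlaps the exclusion interval [200, 250) by exactly 1 bp
        list(chrom = "chr1", pos1 = 152, cigar = "50M", flag = 0),
        list(chrom = "chr1", pos1 = 251, cigar = "50M", flag = 0)))
    bl <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t200\t250", bl)
    fa <- filterAlignments(sam, readFilterPolicy(exclusionBed = bl))
    expect_equal(unname(fa$stats[["excluded_contig"]]), 2)
    expect_equal(unname(fa$stats[["blacklisted"]]), 1)
    expect_equal(fa$reads$start, c(100L, 250L))
    # exclusion region on unknown contig warns and is ignored
    bl2 <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr9\t0\t100", bl2)
    expect_warning(filterAlignments(sam, readFilterPolicy(exclusionBed = bl2)),
                   "chr9")
})

test_that("counts follow full containment; boundary-spanners count nowhere", {
    map <- mapFromWidths(c(100L, 100L, 50L))
    reads <- data.frame(
        chrom = "chr1",
        start = c(10L, 90L, 0L, 100L, 150L, 200L, 230L),
        end   = c(60L, 140L, 100L, 200L, 200L, 250L, 260L))
    cm <- countFragments(map, list(s1 = reads), groups = "Dam")
    # [10,60) in frag1; [90,140) spans cut; [0,100) == frag1 bounds counts;
    # [100,200) == frag2; [150,200) in frag2; [200,250) == frag3;
    # [230,260) beyond frag3 end -> nowhere
    expect_equal(unname(cm$counts[, 1]), c(2L, 2L, 1L))
    expect_equal(cm$samples$lib.size, 7)  # library = all filtered reads
})

test_that("counting matches a brute-force containment oracle and is order-independent", {
    set.seed(11)
    for (rep in 1:5) {
        map <- mapFromWidths(sample(20:200, 30, replace = TRUE))
        len <- attr(map, "seqlengths")[[1]]
        n <- 300
        st <- sample(0:(len - 30), n, replace = TRUE)
        reads <- data.frame(chrom = "chr1", start = st,
                            end = st + sample(20:60, n, replace = TRUE))
        reads$end <- pmin(reads$end, len)
        cm <- countFragments(map, list(a = reads), groups = "Dam")
        brute <- vapply(seq_len(nrow(map)), function(f)
            sum(reads$start >= map$start[f] & reads$end <= map$end[f]),
            integer(1))
        expect_equal(unname(cm$counts[, 1]), brute)
        expect_lte(sum(cm$counts[, 1]), cm$samples$lib.size[1])
        shuf <- countFragments(map, list(a = reads[sample(n), ]),
                               groups = "Dam")
        expect_equal(shuf$counts, cm$counts)
    }
})

test_that("count matrices round-trip through TSV including huge counts", {
    set.seed(3)
    counts <- matrix(rpois(40, 20), 10, 4)
    counts[1, 1] <- 2^31  # beyond 32-bit integers
    cm <- countMatrixFixture(counts, c("Dam", "Dam", "DamPOI", "DamPOI"),
                             libSizes = c(1e6, 2e6, 1.5e6, 3e9))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeCounts(cm, tsv)
    back <- readCounts(tsv)
    expect_equal(unname(back$counts), unname(cm$counts * 1.0))
    expect_equal(back$samples, cm$samples)
    expect_equal(back$fragments$start, cm$fragments$start)
    # malformed header rejected
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(readLines(tsv)[-1], bad)
    expect_error(readCounts(bad), "header")
})

test_that("a sample sheet with an unreadable file names the sample", {
    map <- mapFromWidths(c(100L))
    sheet <- data.frame(sample = "bad_sample", group = "Dam", replicate = 1,
                        path = "/no/such/file.bam", stringsAsFactors = FALSE)
    expect_error(countFragments(map, sheet), "bad_sample")
})
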