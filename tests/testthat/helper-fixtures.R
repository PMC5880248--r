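# Small in-code fixtures shared across test files.

dnaSet <- function(...) Biostrings::DNAStringSet(c(...))

# FragmentMap over explicit 0-based half-open widths on one chromosome
mapFromWidths <- function(widths, chrom = "chr1") {
    ends <- cumsum(widths)
    m <- data.frame(chrom = chrom, start = c(0L, ends[-length(ends)]),
                    end = ends, index = seq_along(widths),
                    stringsAsFactors = FALSE)
    attr(m, "seqlengths") <- stats::setNames(ends[length(ends)], chrom)
    attr(m, "genome") <- "fixture"
    class(m) <- c("FragmentMap", "data.frame")
    m
}

countMatrixFixture <- function(counts, groups, libSizes = colSums(counts),
                               widths = NULL) {
    counts <- as.matrix(counts)
    if (is.null(widths)) widths <- rep(100L, nrow(counts))
    m <- mapFromWidths(widths)
    colnames(counts) <- sprintf("%s_rep%d", groups,
                                stats::ave(seq_along(groups), groups,
                                           FUN = seq_along))
    damidcall:::newCountMatrix(
        counts,
        data.frame(sample = colnames(counts), group = groups,
                   replicate = stats::ave(seq_along(groups), groups,
                                          FUN = seq_along),
                   lib.size = as.numeric(libSizes), stringsAsFactors = FALSE),
        as.data.frame(m))
}

# Write a tiny SAM file from a record list; each record is
# list(chrom, pos1, cigar, flag)
writeSamFixture <- function(path, targets, recs) {
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets))
    body <- vapply(seq_along(recs), function(i) {
        r <- recs[[i]]
        sprintf("r%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                i, r$flag, r$chrom, r$pos1, r$cigar)
    }, character(1))
    writeLines(c(hdr, body), path)
    path
}

trackFromRuns <- function(chrom, start, end, value, seqlengths) {
    damidcall:::newCoverageTrack(
        data.frame(chrom = chrom, start = start, end = end, value = value,
                   stringsAsFactors = FALSE),
        seqlengths)
}
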