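#' Genome read coverage as a run-length track
#'
#' Per-base read depth collapsed to runs of equal value (bedGraph-style,
#' 0-based half-open, zero-depth runs omitted). Reads extending beyond the
#' chromosome end are clipped with a warning. Total area (value x length
#' summed over runs) equals the total clipped read length.
#'
#' @param reads \code{data.frame} with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), e.g. \code{filterAlignments()$reads}.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return A \code{CoverageTrack}: \code{data.frame} (\code{chrom},
#'   \code{start}, \code{end}, \code{value}) with attributes
#'   \code{seqlengths} and \code{scale.factor}.
#' @export
genomeCoverage <- function(reads, seqlengths) {
    runs <- list()
    for (chr in intersect(names(seqlengths), unique(reads$chrom))) {
        r <- reads[reads$chrom == chr, , drop = FALSE]
        len <- seqlengths[[chr]]
        if (any(r$end > len)) {
            warning("reads beyond end of ", chr, " clipped")
            r$end <- pmin(r$end, len)
            r <- r[r$start < r$end, , drop = FALSE]
        }
        if (!nrow(r)) next
        cov <- IRanges::coverage(IRanges::IRanges(r$start + 1L, r$end),
                                 width = len)
        ends <- cumsum(S4Vectors::runLength(cov))
        starts <- c(0L, ends[-length(ends)])
        val <- as.numeric(S4Vectors::runValue(cov))
        keep <- val != 0
        if (any(keep))
            runs[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                                      end = ends[keep], value = val[keep],
                                      stringsAsFactors = FALSE)
    }
    out <- if (length(runs)) do.call(rbind, runs) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), value = numeric(0))
    rownames(out) <- NULL
    newCoverageTrack(out, seqlengths, scale = 1)
}

newCoverageTrack <- function(runs, seqlengths, scale = 1) {
    runs <- canonicalizeRuns(runs)
    structure(runs, seqlengths = seqlengths, scale.factor = scale,
              class = c("CoverageTrack", "data.frame"))
}

# canonical form: sorted, adjacent equal-value runs merged, no zero runs
canonicalizeRuns <- function(runs) {
    if (!nrow(runs)) return(runs)
    runs <- runs[runs$value != 0, , drop = FALSE]
    if (!nrow(runs)) { rownames(runs) <- NULL; return(runs) }
    runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
    n <- nrow(runs)
    joins <- c(FALSE, runs$chrom[-1L] == runs$chrom[-n] &
                      runs$start[-1L] == runs$end[-n] &
                      runs$value[-1L] == runs$value[-n])
    grp <- cumsum(!joins)
    out <- data.frame(chrom = runs$chrom[!joins],
                      start = runs$start[!joins],
                      end = vapply(split(runs$end, grp), max, numeric(1)),
                      value = runs$value[!joins],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Scale a coverage track
#'
#' Multiplies every run value by \code{factor}; for depth normalization use
#' the CPM scale \code{1e6 / effective library size} with the effective
#' library sizes from the peak-calling normalization.
#'
#' @param track A \code{CoverageTrack}.
#' @param factor Positive scale factor.
#' @export
scaleCoverage <- function(track, factor) {
    stopifnot(inherits(track, "CoverageTrack"), factor > 0)
    track$value <- track$value * factor
    attr(track, "scale.factor") <- attr(track, "scale.factor") * factor
    track
}

#' Dam-subtracted coverage track
#'
#' Piecewise difference \code{damPOI - dam} over the union of breakpoints;
#' negative values are retained (Dam-only excess). Chromosome sets are
#' restricted to the intersection with a warning when they differ.
#'
#' @param damPOI,dam Scaled \code{CoverageTrack}s on the same chromosomes.
#' @export
subtractTracks <- function(damPOI, dam) {
    stopifnot(inherits(damPOI, "CoverageTrack"), inherits(dam, "CoverageTrack"))
    slA <- attr(damPOI, "seqlengths"); slB <- attr(dam, "seqlengths")
    common <- intersect(names(slA), names(slB))
    if (!setequal(names(slA), names(slB)))
        warning("chromosome sets differ; restricting to intersection")
    runs <- list()
    for (chr in common) {
        len <- slA[[chr]]
        a <- trackRle(damPOI, chr, len)
        b <- trackRle(dam, chr, len)
        d <- a - b
        ends <- cumsum(S4Vectors::runLength(d))
        starts <- c(0, ends[-length(ends)])
        val <- S4Vectors::runValue(d)
        keep <- val != 0
        if (any(keep))
            runs[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                                      end = ends[keep], value = val[keep],
                                      stringsAsFactors = FALSE)
    }
    out <- if (length(runs)) do.call(rbind, runs) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), value = numeric(0))
    newCoverageTrack(out, slA[common], scale = 1)
}

trackRle <- function(track, chr, len) {
    r <- track[track$chrom == chr, , drop = FALSE]
    rle <- S4Vectors::Rle(0, len)
    if (nrow(r))
        rle[IRanges::IRanges(r$start + 1L, r$end)] <- S4Vectors::Rle(
            r$value, r$end - r$start)
    rle
}

#' Average replicate tracks into one group track
#'
#' Mean of per-replicate scaled tracks over the union of breakpoints.
#'
#' @param tracks List of \code{CoverageTrack}s (same chromosome set).
#' @export
meanTracks <- function(tracks) {
    stopifnot(length(tracks) >= 1)
    acc <- tracks[[1]]
    if (length(tracks) == 1L) return(acc)
    sl <- attr(acc, "seqlengths")
    runs <- list()
    for (chr in names(sl)) {
        len <- sl[[chr]]
        s <- trackRle(tracks[[1]], chr, len)
        for (t in tracks[-1]) s <- s + trackRle(t, chr, len)
        s <- s / length(tracks)
        ends <- cumsum(S4Vectors::runLength(s))
        starts <- c(0, ends[-length(ends)])
        val <- S4Vectors::runValue(s)
        keep <- val != 0
        if (any(keep))
            runs[[chr]] <- data.frame(chrom = chr, start = starts[keep],
                                      end = ends[keep], value = val[keep],
                                      stringsAsFactors = FALSE)
    }
    out <- if (length(runs)) do.call(rbind, runs) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), value = numeric(0))
    newCoverageTrack(out, sl, scale = 1)
}

#' Write / read a bedGraph track
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open,
#' sorted, adjacent equal-value runs merged before writing.
#'
#' @param track A \code{CoverageTrack}.
#' @param path Output path.
#' @export
writeBedgraph <- function(track, path) {
    stopifnot(inherits(track, "CoverageTrack"))
    runs <- canonicalizeRuns(as.data.frame(track))
    old <- options(scipen = 15)
    on.exit(options(old))
    utils::write.table(runs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBedgraph
#' @param seqlengths Chromosome lengths for the reconstructed track.
#' @export
readBedgraph <- function(path, seqlengths) {
    runs <- if (file.size(path) > 0)
        utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), value = numeric(0))
    newCoverageTrack(runs, seqlengths, scale = 1)
}

#' Write a bigWig track when the capability is available
#'
#' Uses \pkg{rtracklayer} when installed; otherwise writes bedGraph next to
#' the requested path with a notice.
#'
#' @inheritParams writeBedgraph
#' @export
writeBigwig <- function(track, path) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
        alt <- sub("\\.bw$|\\.bigwig$", ".bedgraph", path, ignore.case = TRUE)
        message("bigWig support unavailable; writing bedGraph to ", alt)
        return(writeBedgraph(track, alt))
    }
    sl <- attr(track, "seqlengths")
    gr <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L, track$end),
                                 score = track$value,
                                 seqlengths = sl)
    rtracklayer::export.bw(gr, path)
    invisible(path)
}
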