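#' Cluster tested fragments into candidate regions
#'
#' Adjacent fragments on one chromosome are linked when the gap between them
#' (next start minus previous end) is at most \code{tol}; the default 260 bp
#' is the median GATC fragment size of the mm10 assembly, so a single
#' filtered-out fragment of typical size does not break a region. A linked
#' run whose genomic span exceeds \code{maxWidth} is split into
#' \code{ceiling(span / maxWidth)} consecutive sub-clusters of near-equal
#' span, fragments assigned by midpoint, keeping region-level p-values from
#' diluting over arbitrarily wide intervals.
#'
#' @param fragments \code{data.frame} with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) for the retained fragments.
#' @param tol Gap tolerance in bp (default 260); a gap of exactly \code{tol}
#'   still links.
#' @param maxWidth Maximum region span in bp (default 10000).
#' @return Integer cluster ids, contiguous and increasing in genomic order,
#'   aligned with the (sorted) input rows; the sorted order is returned in
#'   \code{attr(, "order")} when sorting was needed.
#' @export
mergeWindows <- function(fragments, tol = 260, maxWidth = 10000) {
    stopifnot(tol >= 0, maxWidth > 0)
    o <- order(fragments$chrom, fragments$start)
    if (is.unsorted(o)) warning("fragments were not sorted; sorting internally")
    f <- fragments[o, , drop = FALSE]
    n <- nrow(f)
    if (n == 0L) return(integer(0))
    newClust <- c(TRUE, f$chrom[-1L] != f$chrom[-n] |
                        f$start[-1L] - f$end[-n] > tol)
    id <- cumsum(newClust)
    # width cap: split over-wide clusters into near-equal spans by midpoint
    out <- integer(n)
    nxt <- 0L
    for (cl in unique(id)) {
        sel <- which(id == cl)
        span <- f$end[sel[length(sel)]] - f$start[sel[1L]]
        k <- max(1L, ceiling(span / maxWidth))
        if (k == 1L) {
            nxt <- nxt + 1L
            out[sel] <- nxt
        } else {
            mid <- (f$start[sel] + f$end[sel]) / 2
            sub <- pmin(floor((mid - f$start[sel[1L]]) / (span / k)), k - 1L)
            sub <- cumsum(c(TRUE, diff(sub) != 0))  # contiguous renumbering
            out[sel] <- nxt + sub
            nxt <- nxt + max(sub)
        }
    }
    res <- integer(n)
    res[o] <- out
    attr(res, "order") <- o
    res
}

#' Combine fragment tests into region-level results
#'
#' Per cluster the member p-values are combined with the Simes method,
#' \code{p_simes = min_k (m * p_(k) / k)} over the m sorted member p-values
#' — valid under positive dependence of neighbouring fragments and equal to
#' the member p for singletons. Benjamini-Hochberg adjustment across all
#' regions yields the region FDR. The representative log fold change is that
#' of the member with the smallest p (ties broken by smallest fragment
#' index), following the representative-test convention for merged genomic
#' windows.
#'
#' @param tests A \link{testFragments} result carrying \code{chrom},
#'   \code{start}, \code{end}, \code{index}, \code{logFC}, \code{p.value}.
#' @param clusters Integer cluster id per row, as from \link{mergeWindows}.
#' @return \code{data.frame} of regions: coordinates, \code{n.members},
#'   \code{p.simes}, \code{fdr}, representative \code{logFC}, \code{best}
#'   fragment index; member fragment indices in the list column
#'   \code{members}.
#' @export
combineTests <- function(tests, clusters) {
    stopifnot(nrow(tests) == length(clusters), !anyNA(clusters))
    regions <- lapply(split(seq_len(nrow(tests)), clusters), function(sel) {
        p <- tests$p.value[sel]
        m <- length(p)
        simes <- min(sort(p) * m / seq_len(m))
        bestLocal <- sel[order(p, tests$index[sel])][1L]
        data.frame(chrom = tests$chrom[sel[1L]],
                   start = min(tests$start[sel]),
                   end = max(tests$end[sel]),
                   n.members = m,
                   p.simes = simes,
                   logFC = tests$logFC[bestLocal],
                   best = tests$index[bestLocal],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, regions)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out$fdr <- stats::p.adjust(out$p.simes, method = "BH")
    # member lists aligned to the sorted region order
    key <- paste(out$chrom, out$start)
    mem <- lapply(split(seq_len(nrow(tests)), clusters), function(sel)
        sort(tests$index[sel]))
    memKey <- vapply(split(seq_len(nrow(tests)), clusters), function(sel)
        paste(tests$chrom[sel[1L]], min(tests$start[sel])), character(1))
    out$members <- unname(mem[match(key, memKey)])
    out
}

#' Call peaks from combined regions
#'
#' A region is a peak iff its FDR is strictly below \code{fdr} and its
#' representative log fold change strictly exceeds \code{minLogfc} — the
#' positive direction only, since peaks are enrichments of Dam-POI over
#' Dam-only; depleted regions remain in the region table but are never
#' called.
#'
#' @param regions A \link{combineTests} result.
#' @param fdr FDR threshold (default 0.1, strict).
#' @param minLogfc Minimum representative log2 fold change (default 0.5,
#'   strict).
#' @return The called subset of \code{regions}, with the thresholds recorded
#'   in attributes.
#' @export
callPeaks <- function(regions, fdr = 0.1, minLogfc = 0.5) {
    stopifnot(fdr > 0, fdr <= 1)
    out <- regions[regions$fdr < fdr & regions$logFC > minLogfc, ,
                   drop = FALSE]
    rownames(out) <- NULL
    attr(out, "fdr.threshold") <- fdr
    attr(out, "min.logfc") <- minLogfc
    out
}

#' High-confidence peak selection
#'
#' For noisy replicate sets (e.g. single-embryo libraries) peaks are further
#' filtered to those with consistently high signal: mean log2 peak-level CPM
#' across Dam-POI replicates strictly above \code{minLog2} and coefficient
#' of variation (sd/mean of peak CPM over Dam-POI replicates) strictly below
#' \code{maxCV}. Peak-level CPM is the sum of member-fragment CPM
#' (\code{count / lib.size * 1e6}).
#'
#' @param peaks A \link{callPeaks} result (needs the \code{members} column).
#' @param cm The \emph{unfiltered-row order} \code{CountMatrix} whose
#'   fragment indices match \code{members}.
#' @param minLog2 Minimum mean log2 CPM (default 4.5).
#' @param maxCV Maximum coefficient of variation (default 0.75).
#' @return Subset of \code{peaks} with added \code{mean.log2.cpm} and
#'   \code{cv} columns.
#' @export
selectHighConfidence <- function(peaks, cm, minLog2 = 4.5, maxCV = 0.75) {
    stopifnot(inherits(cm, "CountMatrix"))
    poi <- cm$samples$group == "DamPOI"
    if (sum(poi) < 2)
        stop("coefficient of variation needs at least 2 Dam-POI replicates")
    cpm <- sweep(cm$counts[, poi, drop = FALSE], 2,
                 cm$samples$lib.size[poi] / 1e6, "/")
    rowOf <- match(seq_len(max(cm$fragments$index)), cm$fragments$index)
    stat <- t(vapply(peaks$members, function(idx) {
        pk <- colSums(cpm[rowOf[idx], , drop = FALSE])
        c(mean(log2(pk)), stats::sd(pk) / mean(pk))
    }, numeric(2)))
    peaks$mean.log2.cpm <- stat[, 1]
    peaks$cv <- stat[, 2]
    out <- peaks[peaks$mean.log2.cpm > minLog2 & peaks$cv < maxCV, ,
                 drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a peak set as BED and TSV
#'
#' BED score is \code{-log10(fdr)} capped at 1000; the TSV carries all
#' region fields (member indices comma-separated) and round-trips through
#' \link{readPeaks}.
#'
#' @param peaks Region/peak \code{data.frame}.
#' @param prefix Output path prefix; writes \code{<prefix>.bed} and
#'   \code{<prefix>.tsv}.
#' @export
writePeaks <- function(peaks, prefix) {
    score <- ifelse(peaks$fdr <= 0, 1000,
                    pmin(round(-log10(peaks$fdr), 3), 1000))
    bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                      sprintf("peak_%d", seq_len(nrow(peaks))), score)
    utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    tsv <- peaks
    tsv$members <- vapply(peaks$members, paste, character(1), collapse = ",")
    utils::write.table(tsv, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(prefix)
}

#' @rdname writePeaks
#' @param path Path to a TSV written by \code{writePeaks}.
#' @export
readPeaks <- function(path) {
    tsv <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(members = "character"))
    tsv$members <- lapply(strsplit(as.character(tsv$members), ","),
                          as.integer)
    tsv
}
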