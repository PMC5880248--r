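#' Read-filtering policy for DamID-seq alignments
#'
#' DamID-seq counting keeps primary mapped alignments only; unmapped,
#' secondary and supplementary records are dropped, as are reads on
#' uninformative contigs (alternative/unplaced/mitochondrial by default) and
#' reads overlapping an exclusion list (e.g. the ENCODE blacklist) by at
#' least 1 bp. PCR duplicates are deliberately retained: reads originate from
#' discrete GATC fragments, so apparent duplicates are expected from genuine
#' methylation signal and duplicate removal would censor it.
#'
#' @param excludedContigPatterns Regular expressions; any contig whose name
#'   matches one of them is dropped entirely.
#' @param exclusionBed Optional path to a BED file of regions whose
#'   overlapping reads are discarded (any overlap suffices).
#' @return A \code{ReadFilterPolicy} list.
#' @export
readFilterPolicy <- function(excludedContigPatterns = c("_alt$", "_random$",
                                                        "^chrUn", "^chrM$",
                                                        "^MT$"),
                             exclusionBed = NULL) {
    excl <- NULL
    if (!is.null(exclusionBed)) {
        excl <- utils::read.table(exclusionBed, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[, 1:3]
        names(excl) <- c("chrom", "start", "end")
        excl$chrom <- as.character(excl$chrom)
    }
    structure(list(excludedContigPatterns = excludedContigPatterns,
                   exclusionRegions = excl,
                   keepDuplicates = TRUE),
              class = "ReadFilterPolicy")
}

#' Filter a SAM/BAM file to the reads used for counting
#'
#' @param file Path to a SAM or BAM file with a header. SAM input is
#'   converted on the fly.
#' @param policy A \link{readFilterPolicy}.
#' @return A list with \code{reads} — a \code{data.frame} of retained
#'   alignments (\code{chrom}, \code{start}, \code{end}; 0-based half-open
#'   reference coordinates) — and \code{stats}, the number of records removed
#'   per rule plus \code{retained} and \code{total}.
#' @export
filterAlignments <- function(file, policy = readFilterPolicy()) {
    if (!file.exists(file)) stop("alignment file not found: ", file)
    bam <- file
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                                indexDestination = FALSE)
    }
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]
    if (length(hdr$targets) == 0L)
        stop("missing or empty header in ", file)
    p <- Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "cigar"))
    x <- Rsamtools::scanBam(bam, param = p)[[1]]
    flag <- x$flag
    unmapped <- bitwAnd(flag, 4L) != 0L
    secondary <- bitwAnd(flag, 256L) != 0L
    supplementary <- bitwAnd(flag, 2048L) != 0L
    keep <- !(unmapped | secondary | supplementary)

    chrom <- as.character(x$rname)
    excludedContig <- rep(FALSE, length(flag))
    for (pat in policy$excludedContigPatterns)
        excludedContig <- excludedContig | (!is.na(chrom) & grepl(pat, chrom))
    excludedContig <- excludedContig & keep
    keep <- keep & !excludedContig

    start0 <- x$pos - 1L  # SAM POS is 1-based
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
    end0 <- start0 + width

    blacklisted <- rep(FALSE, length(flag))
    if (!is.null(policy$exclusionRegions) && any(keep)) {
        ex <- policy$exclusionRegions
        unknown <- setdiff(unique(ex$chrom), names(hdr$targets))
        if (length(unknown)) {
            warning("exclusion regions on contigs absent from header ignored: ",
                    paste(unknown, collapse = ", "))
            ex <- ex[!ex$chrom %in% unknown, , drop = FALSE]
        }
        for (chr in unique(ex$chrom)) {
            on <- keep & !is.na(chrom) & chrom == chr
            if (!any(on)) next
            exc <- ex[ex$chrom == chr, ]
            hits <- IRanges::overlapsAny(
                IRanges::IRanges(start0[on] + 1L, end0[on]),
                IRanges::IRanges(exc$start + 1L, exc$end))
            idx <- which(on)[hits]
            blacklisted[idx] <- TRUE
        }
        keep <- keep & !blacklisted
    }

    list(reads = data.frame(chrom = chrom[keep], start = start0[keep],
                            end = end0[keep], stringsAsFactors = FALSE),
         stats = c(total = length(flag),
                   unmapped = sum(unmapped),
                   secondary = sum(secondary & !unmapped),
                   supplementary = sum(supplementary & !unmapped & !secondary),
                   excluded_contig = sum(excludedContig),
                   blacklisted = sum(blacklisted),
                   retained = sum(keep)))
}

#' Read a DamID-seq sample sheet
#'
#' Tab-separated columns \code{sample}, \code{group}, \code{replicate},
#' \code{path}; \code{group} must be \code{Dam} or \code{DamPOI}.
#'
#' @param path TSV path.
#' @return \code{data.frame} with the four columns.
#' @export
readSampleSheet <- function(path) {
    ss <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("sample", "group", "replicate", "path")
    if (!all(need %in% names(ss)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(ss$sample)) stop("duplicated sample identifiers")
    if (!all(ss$group %in% c("Dam", "DamPOI")))
        stop("group must be 'Dam' or 'DamPOI'")
    ss
}

#' Count reads fully contained in GATC fragments
#'
#' A read increments exactly one fragment, and only when the alignment is
#' fully contained in it (alignment start >= fragment start and alignment
#' end <= fragment end, half-open coordinates); reads spanning a GATC cut
#' increment nothing. Library size is the number of reads passing the filter
#' policy, whether or not they were assigned — normalization tracks
#' sequencing depth, not assignability.
#'
#' @param map A \link{buildFragmentMap} result.
#' @param sampleSheet A \link{readSampleSheet} data.frame (paths point at
#'   SAM/BAM files), or a named list of pre-filtered read \code{data.frame}s
#'   (as returned in \code{filterAlignments()$reads}) together with
#'   \code{groups}/\code{libSizes}.
#' @param policy Filter policy applied to each file.
#' @param groups,replicates,libSizes Only used when \code{sampleSheet} is a
#'   list of read tables: per-sample group labels, replicate numbers, and
#'   library sizes (defaults to the number of reads supplied).
#' @return A \code{CountMatrix}: list with integer \code{counts}
#'   (fragments x samples), \code{samples} (sample, group, replicate,
#'   lib.size) and the fragment table.
#' @export
countFragments <- function(map, sampleSheet, policy = readFilterPolicy(),
                           groups = NULL, replicates = NULL, libSizes = NULL) {
    stopifnot(inherits(map, "FragmentMap"))
    if (is.data.frame(sampleSheet)) {
        readsets <- vector("list", nrow(sampleSheet))
        names(readsets) <- sampleSheet$sample
        libSizes <- integer(nrow(sampleSheet))
        for (i in seq_len(nrow(sampleSheet))) {
            fa <- tryCatch(filterAlignments(sampleSheet$path[i], policy),
                           error = function(e)
                               stop("sample '", sampleSheet$sample[i], "': ",
                                    conditionMessage(e)))
            readsets[[i]] <- fa$reads
            libSizes[i] <- fa$stats[["retained"]]
        }
        groups <- sampleSheet$group
        replicates <- sampleSheet$replicate
    } else {
        readsets <- sampleSheet
        if (is.null(groups) || length(groups) != length(readsets))
            stop("supply one group label per read set")
        if (is.null(libSizes))
            libSizes <- vapply(readsets, nrow, integer(1))
        if (is.null(replicates)) replicates <- seq_along(readsets)
    }
    counts <- vapply(readsets, function(r) countOneSample(map, r),
                     integer(nrow(map)))
    counts <- matrix(as.integer(counts), nrow = nrow(map),
                     dimnames = list(NULL, names(readsets)))
    newCountMatrix(counts,
                   data.frame(sample = names(readsets),
                              group = as.character(groups),
                              replicate = as.integer(replicates),
                              lib.size = as.numeric(libSizes),
                              stringsAsFactors = FALSE),
                   as.data.frame(map))
}

# Assignment by full containment: the candidate fragment is the one whose
# start interval contains the read start; the read counts iff its end also
# fits. findInterval is O(log n) per read because fragments tile the genome.
countOneSample <- function(map, reads) {
    n <- tabulate(assignFragment(map, reads), nbins = nrow(map))
    as.integer(n)
}

assignFragment <- function(map, reads) {
    out <- rep(NA_integer_, nrow(reads))
    for (chr in unique(reads$chrom)) {
        fsel <- which(map$chrom == chr)
        if (!length(fsel)) next
        rsel <- which(reads$chrom == chr)
        idx <- findInterval(reads$start[rsel], map$start[fsel])
        ok <- idx >= 1L & reads$start[rsel] >= 0L &
            reads$end[rsel] <= map$end[fsel][pmax(idx, 1L)]
        out[rsel[ok]] <- map$index[fsel][idx[ok]]
    }
    out
}

newCountMatrix <- function(counts, samples, fragments) {
    stopifnot(nrow(counts) == nrow(fragments),
              ncol(counts) == nrow(samples),
              all(counts >= 0))
    structure(list(counts = counts, samples = samples, fragments = fragments),
              class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
    cat(sprintf("CountMatrix: %d fragments x %d samples (%s)\n",
                nrow(x$counts), ncol(x$counts),
                paste(sprintf("%s=%d", unique(x$samples$group),
                              table(x$samples$group)[unique(x$samples$group)]),
                      collapse = ", ")))
    invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' The header block (lines starting with \code{#}) carries per-sample group,
#' replicate and library size, so the round trip is lossless.
#'
#' @param cm A \code{CountMatrix}.
#' @param path Output path.
#' @export
writeCounts <- function(cm, path) {
    stopifnot(inherits(cm, "CountMatrix"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# damidcall counts v1", con)
    s <- cm$samples
    for (i in seq_len(nrow(s)))
        writeLines(sprintf("# sample\t%s\t%s\t%d\t%.10g", s$sample[i],
                           s$group[i], s$replicate[i], s$lib.size[i]), con)
    tab <- cbind(cm$fragments[, c("index", "chrom", "start", "end")],
                 as.data.frame(cm$counts))
    old <- options(scipen = 15)
    on.exit(options(old), add = TRUE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta <- lines[hdr]
    if (!length(meta) || meta[1] != "# damidcall counts v1")
        stop("malformed counts header: missing '# damidcall counts v1'")
    sm <- meta[grepl("^# sample\t", meta)]
    if (!length(sm)) stop("malformed counts header: no sample lines")
    parts <- do.call(rbind, strsplit(sub("^# sample\t", "", sm), "\t"))
    samples <- data.frame(sample = parts[, 1], group = parts[, 2],
                          replicate = as.integer(parts[, 3]),
                          lib.size = as.numeric(parts[, 4]),
                          stringsAsFactors = FALSE)
    if (!all(samples$group %in% c("Dam", "DamPOI")))
        stop("malformed counts header: bad group label")
    tab <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, samples$sample, drop = FALSE])
    storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
    newCountMatrix(counts, samples,
                   tab[, c("chrom", "start", "end", "index")])
}
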