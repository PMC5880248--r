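#' Simulation settings for synthetic DamID-seq data
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' genome whose GATC density matches uniform base composition (one motif per
#' 256 positions), a Dam-only background driven by fragment-level chromatin
#' accessibility (log-normal propensity shared between groups — untethered
#' Dam preferentially methylates accessible DNA), a small fraction of
#' fragments carrying extra Dam-POI methylation with a fixed log2 effect,
#' negative-binomial replicate noise, and reads emitted fully inside
#' fragments.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Chromosome length in bp.
#' @param gatcRate Per-position motif rate (default 1/256, the uniform-
#'   composition density; expected fragment size is about \code{1/gatcRate}).
#' @param samplesPerGroup Replicates per group (default 3).
#' @param depth Expected reads per fragment (default 50).
#' @param accessSdlog Log-normal sd of the fragment accessibility propensity
#'   (default 1: about an order of magnitude of background variation).
#' @param bindingFraction Share of fragments carrying POI signal
#'   (default 0.01).
#' @param effect Log2 enrichment of bound fragments in Dam-POI samples
#'   (default 2).
#' @param dispersion Negative-binomial dispersion phi (default 0.1;
#'   0 gives Poisson noise).
#' @param readLength Read length in bp (default 50, single-end).
#' @param seed Integer seed; all randomness flows from it.
#' @return A \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nChrom = 1, chromLength = 5.2e6,
                             gatcRate = 1 / 256, samplesPerGroup = 3,
                             depth = 50, accessSdlog = 1,
                             bindingFraction = 0.01, effect = 2,
                             dispersion = 0.1, readLength = 50, seed = 1) {
    stopifnot(nChrom >= 1, chromLength > 0, gatcRate > 0, gatcRate < 1,
              samplesPerGroup >= 1, depth > 0, accessSdlog >= 0,
              bindingFraction >= 0, bindingFraction <= 1, effect >= 0,
              dispersion >= 0, readLength >= 1)
    structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a genome with GATC fragments and planted binding truth
#'
#' Motif spacings are geometric at the configured rate; inter-motif fill is
#' i.i.d. nucleotides with any accidentally formed GATC destroyed by a
#' single-base substitution, so the realized density matches the target.
#' The fragment map is built by scanning the emitted sequence (never assumed
#' from the construction), and binding fragments are then sampled uniformly
#' without replacement.
#'
#' @param config A \link{simulationConfig}.
#' @param fasta Optional path; when given the genome is also written as
#'   FASTA (byte-identical under a fixed seed).
#' @return List: \code{genome} (DNAStringSet), \code{map} (FragmentMap),
#'   \code{truth} (\code{data.frame} of binding fragment \code{index} and
#'   true \code{beta}).
#' @export
simulateGenome <- function(config, fasta = NULL) {
    stopifnot(inherits(config, "SimulationConfig"))
    withr::local_seed(config$seed)
    seqs <- character(config$nChrom)
    for (i in seq_len(config$nChrom))
        seqs[i] <- simulateChromSequence(config$chromLength, config$gatcRate)
    names(seqs) <- sprintf("chr%d", seq_len(config$nChrom))
    genome <- Biostrings::DNAStringSet(seqs)
    map <- buildFragmentMap(genome, label = "simulated")
    nBind <- round(config$bindingFraction * nrow(map))
    idx <- sort(sample(map$index, nBind))
    truth <- data.frame(index = idx,
                        beta = rep(config$effect, nBind))
    if (!is.null(fasta))
        Biostrings::writeXStringSet(genome, fasta)
    list(genome = genome, map = map, truth = truth)
}

simulateChromSequence <- function(len, rate) {
    # geometric gaps between planted motifs; generous overshoot then truncate
    nMotif <- ceiling(len * rate * 1.5) + 25L
    gaps <- stats::rgeom(nMotif, rate)
    starts <- cumsum(gaps + 4L) - 3L   # 1-based motif starts
    starts <- starts[starts + 3L <= len]
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    motifPos <- as.vector(outer(0:3, starts, "+"))
    chars[motifPos] <- rep(c("G", "A", "T", "C"), length(starts))
    seq <- paste(chars, collapse = "")
    # destroy accidental motifs in the fill: mutating the final C to A can
    # never create a new GATC, so one pass suffices
    hits <- gregexpr("GATC", seq, fixed = TRUE)[[1]]
    extra <- setdiff(hits[hits > 0], starts)
    if (length(extra)) {
        chars[extra + 3L] <- "A"
        seq <- paste(chars, collapse = "")
    }
    seq
}

#' Simulate a fragment layout without sequence
#'
#' Fast path for counts-level benchmarking: fragment widths are
#' \code{4 + Geometric(gatcRate)} (motif plus geometric spacing), tiled on
#' one synthetic chromosome, with binding fragments sampled uniformly.
#' Statistically equivalent to scanning a \link{simulateGenome} sequence but
#' skips sequence construction.
#'
#' @inheritParams simulateGenome
#' @param nFragments Number of fragments (default 20000).
#' @return List: \code{map}, \code{truth} as in \link{simulateGenome}.
#' @export
simulateFragmentLayout <- function(config, nFragments = 20000) {
    stopifnot(inherits(config, "SimulationConfig"))
    withr::local_seed(config$seed)
    widths <- 4L + stats::rgeom(nFragments, config$gatcRate)
    ends <- cumsum(widths)
    map <- data.frame(chrom = "chr1", start = c(0L, ends[-nFragments]),
                      end = ends, index = seq_len(nFragments),
                      stringsAsFactors = FALSE)
    attr(map, "seqlengths") <- c(chr1 = ends[nFragments])
    attr(map, "genome") <- "simulated-layout"
    class(map) <- c("FragmentMap", "data.frame")
    nBind <- round(config$bindingFraction * nFragments)
    idx <- sort(sample.int(nFragments, nBind))
    list(map = map,
         truth = data.frame(index = idx, beta = rep(config$effect, nBind)))
}

#' Simulate a fragment count matrix
#'
#' Mean for fragment f in sample s:
#' \code{mu_fs = depth * nFragments * w_fs / sum_f(w_fs)} with
#' \code{w_fs = a_f * 2^(beta_f)} in Dam-POI samples and \code{a_f} in
#' Dam-only samples, where \code{a_f} is the shared log-normal accessibility
#' propensity — so expected library sizes match the configured depth and
#' Dam-POI enrichment competes for depth exactly as in a real library.
#' Counts are negative-binomial with dispersion phi.
#'
#' @param config A \link{simulationConfig}.
#' @param map FragmentMap from \link{simulateGenome} or
#'   \link{simulateFragmentLayout}.
#' @param truth Matching ground-truth table.
#' @param seed Optional seed overriding \code{config$seed} (so one layout
#'   can yield many replicate datasets).
#' @return A \code{CountMatrix}; library sizes are the column sums (every
#'   simulated read lies fully inside its fragment).
#' @export
simulateCounts <- function(config, map, truth, seed = config$seed) {
    stopifnot(inherits(config, "SimulationConfig"), inherits(map, "FragmentMap"))
    withr::local_seed(seed)
    n <- nrow(map)
    k <- config$samplesPerGroup
    groups <- rep(c("Dam", "DamPOI"), each = k)
    a <- stats::rlnorm(n, meanlog = -config$accessSdlog^2 / 2,
                       sdlog = config$accessSdlog)
    beta <- numeric(n)
    beta[match(truth$index, map$index)] <- truth$beta
    counts <- matrix(0L, n, 2L * k)
    for (s in seq_len(2L * k)) {
        w <- if (groups[s] == "DamPOI") a * 2^beta else a
        mu <- config$depth * n * w / sum(w)
        counts[, s] <- if (config$dispersion == 0) stats::rpois(n, mu)
                       else stats::rnbinom(n, mu = mu,
                                           size = 1 / config$dispersion)
    }
    colnames(counts) <- sprintf("%s_rep%d", groups, rep(seq_len(k), 2))
    newCountMatrix(counts,
                   data.frame(sample = colnames(counts), group = groups,
                              replicate = rep(seq_len(k), 2),
                              lib.size = as.numeric(colSums(counts)),
                              stringsAsFactors = FALSE),
                   as.data.frame(map))
}

#' Realize a count matrix as single-end SAM files
#'
#' Each fragment's count becomes that many primary mapped reads of the
#' configured length placed uniformly fully inside the fragment (fragments
#' shorter than the read length emit reads spanning the whole fragment), so
#' \link{countFragments} on the emitted files reproduces the matrix exactly.
#'
#' @param config A \link{simulationConfig}.
#' @param map FragmentMap the counts refer to.
#' @param cm CountMatrix to realize.
#' @param dir Output directory for one SAM file per sample.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return A sample sheet \code{data.frame} (sample, group, replicate,
#'   path) pointing at the SAM files.
#' @export
simulateReads <- function(config, map, cm, dir, seed = config$seed) {
    stopifnot(inherits(cm, "CountMatrix"))
    withr::local_seed(seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sl <- attr(map, "seqlengths")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    paths <- character(ncol(cm$counts))
    for (s in seq_len(ncol(cm$counts))) {
        cnt <- cm$counts[, s]
        tot <- sum(cnt)
        recs <- character(0)
        if (tot > 0) {
            fi <- rep(seq_len(nrow(map)), cnt)
            width <- pmin(config$readLength, map$end[fi] - map$start[fi])
            lastStart <- map$end[fi] - width          # max 0-based start
            start0 <- map$start[fi] +
                floor(stats::runif(tot) * (lastStart - map$start[fi] + 1L))
            recs <- sprintf("%s_r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                            cm$samples$sample[s], seq_len(tot),
                            map$chrom[fi], start0 + 1L, width)
        }
        paths[s] <- file.path(dir, paste0(cm$samples$sample[s], ".sam"))
        writeLines(c(hdr, recs), paths[s])
    }
    data.frame(sample = cm$samples$sample, group = cm$samples$group,
               replicate = cm$samples$replicate, path = paths,
               stringsAsFactors = FALSE)
}

#' Score called peaks against the simulation truth
#'
#' A called region is a true positive iff it overlaps at least one binding
#' fragment. Recall is the share of binding fragments covered by (i.e.
#' overlapping) any called region; the false-discovery proportion is the
#' share of called regions overlapping none. An empty peak set scores
#' recall 0 and FDP 0 by convention.
#'
#' @param peaks Called regions (chrom, start, end).
#' @param truth Ground-truth table with binding fragment \code{index}.
#' @param map The FragmentMap giving those fragments' coordinates.
#' @return List: \code{recall}, \code{fdp}, \code{n.called}, \code{n.true}.
#' @export
evaluateCalls <- function(peaks, truth, map) {
    nTrue <- nrow(truth)
    if (nrow(peaks) == 0L)
        return(list(recall = 0, fdp = 0, n.called = 0L, n.true = nTrue))
    bind <- map[match(truth$index, map$index), , drop = FALSE]
    hitFrag <- logical(nTrue)
    hitPeak <- logical(nrow(peaks))
    for (chr in unique(peaks$chrom)) {
        ps <- which(peaks$chrom == chr)
        bs <- which(bind$chrom == chr)
        if (!length(bs)) next
        ov <- IRanges::findOverlaps(
            IRanges::IRanges(bind$start[bs] + 1L, bind$end[bs]),
            IRanges::IRanges(peaks$start[ps] + 1L, peaks$end[ps]))
        hitFrag[bs[S4Vectors::queryHits(ov)]] <- TRUE
        hitPeak[ps[S4Vectors::subjectHits(ov)]] <- TRUE
    }
    list(recall = if (nTrue) mean(hitFrag) else 0,
         fdp = mean(!hitPeak),
         n.called = nrow(peaks), n.true = nTrue)
}
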