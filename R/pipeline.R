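#' Default pipeline parameters
#'
#' The defaults of the whole workflow in one place: abundance filter at the
#' 10-read equivalent, logCPM pseudocount 2, smooth-quantile span 0.05,
#' variance-trend span 0.4 with robust prior estimation, merge tolerance
#' 260 bp with a 10 kb width cap, and peak thresholds FDR < 0.1 with
#' logFC > 0.5.
#'
#' @return Named list of parameters.
#' @export
defaultPipelineParams <- function() {
    list(minCount = 10, prior = 2, qsmoothSpan = 0.05,
         trendSpan = 0.4, robust = TRUE,
         tol = 260, maxWidth = 10000,
         fdr = 0.1, minLogfc = 0.5,
         quantroPerms = 0, seed = 1)
}

#' Peak calling from a fragment count matrix
#'
#' The statistical core of the workflow: abundance filtering, TMM factors,
#' logCPM, smooth quantile normalization, per-fragment moderated t-tests
#' with a trended robust empirical-Bayes prior, gap-tolerance merging,
#' Simes combination with BH FDR control, and thresholding into peaks.
#'
#' @param cm A \code{CountMatrix} (Dam and DamPOI samples).
#' @param params Parameter list as from \link{defaultPipelineParams};
#'   entries given here override the defaults.
#' @return List: \code{filtered} count matrix, \code{factors},
#'   \code{normalized} matrix, \code{tests}, \code{regions}, \code{peaks},
#'   and \code{quantro} (NULL unless \code{quantroPerms > 0}).
#' @export
damidPeakCall <- function(cm, params = list()) {
    p <- utils::modifyList(defaultPipelineParams(), params)
    filtered <- filterLowAbundance(cm, p$minCount, p$prior)
    if (nrow(filtered$counts) < 10)
        stop("fewer than 10 fragments pass the abundance filter")
    groups <- filtered$samples$group
    factors <- tmmFactors(filtered)
    lc <- logCpm(filtered, factors, p$prior)
    qt <- NULL
    if (p$quantroPerms > 0)
        qt <- quantroTest(lc, groups, nPerm = p$quantroPerms, seed = p$seed)
    norm <- qsmooth(lc, groups, span = p$qsmoothSpan)
    abundance <- aveLogCpm(filtered, p$prior)
    tests <- testFragments(norm, groups, abundance, filtered$fragments,
                           trend = TRUE, robust = p$robust, span = p$trendSpan)
    clusters <- mergeWindows(tests, tol = p$tol, maxWidth = p$maxWidth)
    regions <- combineTests(tests, clusters)
    peaks <- callPeaks(regions, fdr = p$fdr, minLogfc = p$minLogfc)
    list(filtered = filtered, factors = factors, normalized = norm,
         tests = tests, regions = regions, peaks = peaks, quantro = qt,
         params = p)
}

#' Run the full DamID-seq workflow
#'
#' From a genome FASTA and a sample sheet of aligned SAM/BAM files to called
#' peaks, per-sample scaled coverage tracks and the Dam-subtracted group
#' track. All primary outputs are written under \code{outDir} when given
#' (fragments BED, counts TSV, test TSV, region/peak TSV+BED, bedGraphs,
#' resolved parameters as YAML); reruns with identical inputs and seed are
#' byte-identical.
#'
#' @param genome FASTA path or DNAStringSet.
#' @param sampleSheet Path to a sample-sheet TSV or an equivalent
#'   \code{data.frame} (see \link{readSampleSheet}).
#' @param params Parameter overrides (see \link{defaultPipelineParams}).
#' @param policy Read filter policy (see \link{readFilterPolicy}).
#' @param outDir Optional output directory.
#' @return The \link{damidPeakCall} result, plus \code{map}, \code{counts},
#'   \code{tracks} (per-sample scaled) and \code{subtracted}.
#' @export
runPipeline <- function(genome, sampleSheet, params = list(),
                        policy = readFilterPolicy(), outDir = NULL) {
    stage <- function(name, expr) {
        message("[damidcall] ", name)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    map <- stage("fragments", buildFragmentMap(genome))
    if (is.character(sampleSheet))
        sampleSheet <- stage("samples", readSampleSheet(sampleSheet))
    filt <- stage("filter", lapply(stats::setNames(sampleSheet$path,
                                                   sampleSheet$sample),
                                   filterAlignments, policy = policy))
    reads <- lapply(filt, `[[`, "reads")
    libs <- vapply(filt, function(f) f$stats[["retained"]], numeric(1))
    cm <- stage("count", countFragments(map, reads,
                                        groups = sampleSheet$group,
                                        replicates = sampleSheet$replicate,
                                        libSizes = libs))
    res <- stage("peak calling", damidPeakCall(cm, params))
    sl <- attr(map, "seqlengths")
    eff <- cm$samples$lib.size *
        res$factors[match(cm$samples$sample, names(res$factors))]
    tracks <- stage("tracks", mapply(function(r, e)
        scaleCoverage(genomeCoverage(r, sl), 1e6 / e),
        reads, eff, SIMPLIFY = FALSE))
    grp <- cm$samples$group
    sub <- stage("subtract",
                 subtractTracks(meanTracks(tracks[grp == "DamPOI"]),
                                meanTracks(tracks[grp == "Dam"])))
    out <- c(res, list(map = map, counts = cm, tracks = tracks,
                       subtracted = sub))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeFragmentBed(map, file.path(outDir, "fragments.bed"))
        writeCounts(cm, file.path(outDir, "counts.tsv"))
        utils::write.table(res$tests, file.path(outDir, "tests.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writePeaks(res$regions, file.path(outDir, "regions"))
        writePeaks(res$peaks, file.path(outDir, "peaks"))
        for (s in names(tracks))
            writeBedgraph(tracks[[s]],
                          file.path(outDir, paste0(s, ".bedgraph")))
        writeBedgraph(sub, file.path(outDir, "subtracted.bedgraph"))
        yaml::write_yaml(res$params, file.path(outDir, "params.yml"))
    }
    out
}

#' Load a pipeline configuration file
#'
#' YAML with any subset of the \link{defaultPipelineParams} keys plus the
#' path keys \code{genome}, \code{samples}, \code{blacklist}, \code{outDir};
#' unknown keys are rejected, missing keys filled with defaults. An empty
#' file yields all defaults.
#'
#' @param path YAML path.
#' @return Resolved parameter list.
#' @export
loadConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    valid <- c(names(defaultPipelineParams()),
               "genome", "samples", "blacklist", "outDir")
    bad <- setdiff(names(cfg), valid)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "),
             "; valid keys: ", paste(valid, collapse = ", "))
    utils::modifyList(defaultPipelineParams(), cfg)
}
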