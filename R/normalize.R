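#' Average log2 counts-per-million abundance
#'
#' Per fragment: \code{log2((ybar + prior) / (Lbar + 2*prior) * 1e6)} with
#' \code{ybar} the mean count across samples and \code{Lbar} the mean library
#' size. The pseudocount keeps zero-count fragments finite.
#'
#' @param cm A \code{CountMatrix}.
#' @param prior Pseudocount (default 2).
#' @return Numeric vector, one value per fragment.
#' @export
aveLogCpm <- function(cm, prior = 2) {
    stopifnot(inherits(cm, "CountMatrix"))
    if (any(cm$samples$lib.size <= 0)) stop("library sizes must be positive")
    ybar <- rowMeans(cm$counts)
    Lbar <- mean(cm$samples$lib.size)
    log2((ybar + prior) / (Lbar + 2 * prior) * 1e6)
}

#' Remove low-abundance background fragments
#'
#' Fragments whose abundance corresponds to \code{countThreshold} reads or
#' fewer (on the aveLogCPM scale, at the mean library size) are background:
#' removing them reduces the multiple-testing burden and increases power.
#' The cutoff is \code{log2((countThreshold + prior) / (Lbar + 2*prior) *
#' 1e6)} and fragments at or below it are dropped, so a fragment averaging
#' exactly \code{countThreshold} reads is removed. Genomic order is
#' preserved.
#'
#' @inheritParams aveLogCpm
#' @param countThreshold Read-count equivalent of the abundance cutoff
#'   (default 10).
#' @return The filtered \code{CountMatrix}; retained row positions (relative
#'   to the input) in \code{attr(, "retained")}.
#' @export
filterLowAbundance <- function(cm, countThreshold = 10, prior = 2) {
    if (countThreshold < 0) stop("countThreshold must be non-negative")
    a <- aveLogCpm(cm, prior)
    Lbar <- mean(cm$samples$lib.size)
    cutoff <- log2((countThreshold + prior) / (Lbar + 2 * prior) * 1e6)
    keep <- a > cutoff
    out <- newCountMatrix(cm$counts[keep, , drop = FALSE], cm$samples,
                          cm$fragments[keep, , drop = FALSE])
    attr(out, "retained") <- which(keep)
    out
}

#' Trimmed-mean-of-M (TMM) composition normalization factors
#'
#' Between-sample scale factors correcting for composition bias: genuinely
#' enriched fragments in the Dam-POI libraries consume sequencing depth that
#' would otherwise fall on background, so raw library sizes misstate the
#' background sequencing rate. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean; per sample the
#' factor is 2 to the weighted mean of log2 count-ratio M values after
#' trimming 30\% on M and 5\% on A, weighted by inverse asymptotic binomial
#' variance. Factors are rescaled to geometric mean 1.
#'
#' @param cm A \code{CountMatrix} (at least two samples).
#' @return Named numeric vector of factors; effective library size is
#'   \code{lib.size * factor}.
#' @export
tmmFactors <- function(cm) {
    stopifnot(inherits(cm, "CountMatrix"))
    y <- cm$counts
    lib <- cm$samples$lib.size
    if (ncol(y) < 2L) stop("TMM needs at least two samples")
    f75 <- vapply(seq_len(ncol(y)), function(s)
        stats::quantile(y[, s] / lib[s], 0.75, names = FALSE), numeric(1))
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(y)), function(s)
        tmmPair(y[, s], y[, ref], lib[s], lib[ref]), numeric(1))
    f <- f / exp(mean(log(f)))
    stats::setNames(f, cm$samples$sample)
}

tmmPair <- function(obs, ref, nO, nR, logratioTrim = 0.3, sumTrim = 0.05) {
    pos <- obs > 0 & ref > 0
    if (!any(pos)) {
        warning("no co-detected fragments with reference; factor set to 1")
        return(1)
    }
    obs <- obs[pos]; ref <- ref[pos]
    M <- log2((obs / nO) / (ref / nR))
    A <- (log2(obs / nO) + log2(ref / nR)) / 2
    # inverse asymptotic variance of M under binomial sampling
    w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

#' log2 counts-per-million on effective library sizes
#'
#' Per cell: \code{log2((y + p_s) / (E_s + 2*p_s) * 1e6)} with effective
#' library \code{E_s = lib.size * factor} and library-proportional
#' pseudocount \code{p_s = prior * E_s / mean(E)}, so equal-abundance
#' fragments get equal values regardless of depth.
#'
#' @inheritParams aveLogCpm
#' @param factors Normalization factors as from \link{tmmFactors}; defaults
#'   to all 1.
#' @return Numeric matrix, fragments x samples, with provenance attribute
#'   \code{"raw"}.
#' @export
logCpm <- function(cm, factors = NULL, prior = 2) {
    stopifnot(inherits(cm, "CountMatrix"))
    if (is.null(factors)) factors <- rep(1, ncol(cm$counts))
    E <- cm$samples$lib.size * factors
    if (any(E <= 0)) stop("effective library sizes must be positive")
    p <- prior * E / mean(E)
    out <- log2(sweep(sweep(cm$counts, 2, p, "+"), 2, (E + 2 * p) / 1e6, "/"))
    dimnames(out) <- list(NULL, cm$samples$sample)
    attr(out, "provenance") <- "raw"
    out
}

#' Smooth quantile normalization
#'
#' Quantile normalization that respects group-level distributional
#' differences. Plain quantile normalization forces every sample onto one
#' reference distribution, which erases the global Dam-POI vs Dam-only
#' methylation shift that carries the biology. Here each quantile is mapped
#' to a weighted blend of the overall reference and its group-specific
#' reference: the weight is 1 (fully shared) where samples agree across
#' groups and approaches 0 where the between-group spread explains the
#' variability.
#'
#' Algorithm: sort each column into a quantile matrix Q; compute the overall
#' rowwise reference and the within-group references; raw weight
#' \code{w = clamp(1 - SSB/SST, 0, 1)} per quantile (w = 1 where SST = 0);
#' smooth w with a running median over \code{round(span * n)} quantiles;
#' normalized sorted value = \code{w * refAll + (1 - w) * refGroup}; restore
#' each column's original order, ties receiving the mean of their tied
#' positions' values.
#'
#' @param values Numeric matrix (e.g. \link{logCpm} output), samples in
#'   columns.
#' @param groups Character/factor group label per column.
#' @param span Fraction of quantiles in the running-median window
#'   (default 0.05).
#' @return Matrix of the same shape, provenance attribute \code{"qsmooth"};
#'   the smoothed weights in \code{attr(, "weights")}.
#' @export
qsmooth <- function(values, groups, span = 0.05) {
    stopifnot(is.matrix(values), ncol(values) >= 2,
              length(groups) == ncol(values), span > 0, span <= 1)
    groups <- as.character(groups)
    n <- nrow(values)
    ord <- apply(values, 2, order)
    Q <- vapply(seq_len(ncol(values)),
                function(s) values[ord[, s], s], numeric(n))
    refAll <- rowMeans(Q)
    glev <- unique(groups)
    refGroup <- vapply(glev, function(g)
        rowMeans(Q[, groups == g, drop = FALSE]), numeric(n))
    ng <- vapply(glev, function(g) sum(groups == g), numeric(1))
    SST <- rowSums((Q - refAll)^2)
    SSB <- as.vector((refGroup - refAll)^2 %*% ng)
    w <- ifelse(SST == 0, 1, pmin(pmax(1 - SSB / SST, 0), 1))
    k <- round(span * n)
    if (k >= 2) {
        if (k %% 2 == 0) k <- k + 1
        w <- stats::runmed(w, k, endrule = "constant")
        w <- pmin(pmax(w, 0), 1)
    }
    out <- values
    for (s in seq_len(ncol(values))) {
        norm <- w * refAll + (1 - w) * refGroup[, groups[s]]
        col <- numeric(n)
        col[ord[, s]] <- norm
        col <- stats::ave(col, values[, s], FUN = mean)  # exact ties share
        out[, s] <- col
    }
    attr(out, "provenance") <- "qsmooth"
    attr(out, "weights") <- w
    out
}

#' Permutation test for global distributional differences between groups
#'
#' Decides whether the Dam-POI and Dam-only read-count distributions differ
#' globally — the condition under which smooth quantile normalization is
#' preferred over plain quantile normalization. The statistic is an F-like
#' ratio over the quantile matrix: mean between-group quantile variability
#' over mean within-group variability; its null distribution is obtained by
#' permuting column group labels.
#'
#' @inheritParams qsmooth
#' @param nPerm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return List: \code{statistic}, \code{p.value} (resolution
#'   \code{1/(nPerm+1)}), \code{nPerm}.
#' @export
quantroTest <- function(values, groups, nPerm = 1000, seed = 1) {
    stopifnot(is.matrix(values))
    groups <- as.character(groups)
    if (length(unique(groups)) < 2) stop("need at least two groups")
    if (min(table(groups)) < 2) stop("need at least two samples per group")
    if (nPerm < 1) stop("nPerm must be at least 1")
    Q <- apply(values, 2, sort)
    obs <- quantroStat(Q, groups)
    withr::local_seed(seed)
    perm <- vapply(seq_len(nPerm),
                   function(i) quantroStat(Q, sample(groups)), numeric(1))
    list(statistic = obs,
         p.value = (1 + sum(perm >= obs)) / (nPerm + 1),
         nPerm = nPerm)
}

quantroStat <- function(Q, groups) {
    glev <- unique(groups)
    G <- length(glev); n <- length(groups)
    refAll <- rowMeans(Q)
    refGroup <- vapply(glev, function(g)
        rowMeans(Q[, groups == g, drop = FALSE]), numeric(nrow(Q)))
    ng <- vapply(glev, function(g) sum(groups == g), numeric(1))
    SST <- rowSums((Q - refAll)^2)
    SSB <- as.vector((refGroup - refAll)^2 %*% ng)
    num <- mean(SSB / (G - 1))
    den <- mean((SST - SSB) / (n - G))
    if (num == 0 && den == 0) return(0)
    if (den == 0) return(Inf)
    num / den
}
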