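#' Per-fragment two-group linear model fits
#'
#' Ordinary least squares per fragment for the two-group Dam vs Dam-POI
#' design (intercept + group indicator). For this design the coefficient is
#' the group-mean difference, the residual variance is the pooled variance on
#' \code{d = n - 2} degrees of freedom, and the unscaled coefficient variance
#' is \code{c = 1/n1 + 1/n2}.
#'
#' @param values Numeric matrix of normalized log2 CPM, fragments x samples.
#' @param groups Label per column; \code{"Dam"} is the baseline and
#'   \code{"DamPOI"} the enriched condition.
#' @return List: \code{logFC} (DamPOI - Dam), \code{s2} residual variances,
#'   \code{df} residual degrees of freedom, \code{c} coefficient variance
#'   multiplier.
#' @export
fitLinearModels <- function(values, groups) {
    stopifnot(is.matrix(values))
    groups <- as.character(groups)
    dam <- groups == "Dam"; poi <- groups == "DamPOI"
    if (!any(dam) || !any(poi))
        stop("both groups (Dam, DamPOI) must be represented")
    n1 <- sum(dam); n2 <- sum(poi); n <- n1 + n2
    if (n < 3) stop("need at least 3 samples for a residual degree of freedom")
    m1 <- rowMeans(values[, dam, drop = FALSE])
    m2 <- rowMeans(values[, poi, drop = FALSE])
    rss <- rowSums((values[, dam, drop = FALSE] - m1)^2) +
        rowSums((values[, poi, drop = FALSE] - m2)^2)
    d <- n - 2L
    list(logFC = m2 - m1, s2 = rss / d, df = d, c = 1 / n1 + 1 / n2)
}

#' Intensity-dependent variance trend
#'
#' Residual variances in log-expression data depend systematically on
#' abundance; the trend captures that dependence so that the empirical-Bayes
#' prior can vary with it. Fits a lowess of \code{log(s2 + eps)} on
#' abundance, corrected for the downward bias of the log of a chi-square
#' variance estimate (\code{E[log(chi2_d/d)] = digamma(d/2) - log(d/2)})
#' before exponentiating.
#'
#' @param s2 Residual variances.
#' @param abundance aveLogCPM per fragment.
#' @param df Residual degrees of freedom of \code{s2}.
#' @param span Lowess span (default 0.4).
#' @param eps Floor inside the log (default 1e-8).
#' @return Per-fragment trend variances \code{s02} (positive).
#' @export
fitVarianceTrend <- function(s2, abundance, df, span = 0.4, eps = 1e-8) {
    stopifnot(length(s2) == length(abundance), df >= 1)
    if (length(s2) < 10)
        stop("need at least 10 fragments for a stable trend")
    if (all(s2 == 0)) {
        warning("all residual variances are zero; using a constant floor trend")
        return(rep(eps, length(s2)))
    }
    z <- log(s2 + eps)
    fit <- stats::lowess(abundance, z, f = span)
    zhat <- stats::approx(fit$x, fit$y, xout = abundance, rule = 2,
                          ties = mean)$y
    bias <- digamma(df / 2) - log(df / 2)
    exp(zhat - bias)
}

#' Empirical-Bayes variance squeezing
#'
#' Models the true variances as scattered around the trend with an
#' inverse-chi-square prior on \code{d0} degrees of freedom, estimated by
#' moment matching on \code{z = log(s2/s02)}; under the model
#' \code{s2/s02 ~ F(d, d0)}, so \code{var(z) = trigamma(d/2) +
#' trigamma(d0/2)}, solved for \code{d0} by monotone root finding. When the
#' robust flag is set, z is winsorized at the given quantile limits before
#' matching — so hypervariable outlier fragments do not inflate the apparent
#' prior spread — and the matching target is the correspondingly winsorized
#' variance of the log-F distribution (computed by numeric integration), so
#' winsorization does not bias the estimate. No solution (observed spread at
#' or below the pure-sampling spread) gives \code{d0 = Inf} and full
#' shrinkage to the trend. Posterior variance:
#' \code{s2tilde = (d0*s02 + d*s2) / (d0 + d)}.
#'
#' @param s2 Residual variances.
#' @param s02 Trend variances from \link{fitVarianceTrend}.
#' @param df Residual degrees of freedom.
#' @param robust Winsorize before moment matching (default TRUE).
#' @param winsor Winsorization quantile limits (default 0.05, 0.95).
#' @return List: \code{d0} prior degrees of freedom (possibly \code{Inf}),
#'   \code{s2tilde} posterior variances.
#' @export
squeezeVariances <- function(s2, s02, df, robust = TRUE,
                             winsor = c(0.05, 0.95)) {
    stopifnot(length(s2) == length(s02), df >= 1)
    z <- log(pmax(s2, 1e-12) / s02)
    d0 <- if (robust) {
        qs <- stats::quantile(z, winsor, names = FALSE)
        zw <- pmin(pmax(z, qs[1]), qs[2])
        matchWinsorizedLogF(stats::var(zw), df, winsor)
    } else {
        excess <- stats::var(z) - trigamma(df / 2)
        if (is.na(excess) || excess <= 0) Inf
        else 2 * trigammaInverse(excess)
    }
    s2tilde <- if (is.infinite(d0)) s02 else (d0 * s02 + df * s2) / (d0 + df)
    list(d0 = d0, s2tilde = s2tilde)
}

# Variance of log F(d1, d2) winsorized at its own (p_lo, p_hi) quantiles.
# Integrated on the probability scale (u -> log qf(u)), which stays bounded
# and smooth even for tiny d2 where the F tail is extreme.
winsorizedLogFVar <- function(d1, d2, winsor) {
    zlo <- log(stats::qf(winsor[1], d1, d2))
    zhi <- log(stats::qf(winsor[2], d1, d2))
    mom <- function(pow) {
        mid <- stats::integrate(function(u)
            log(stats::qf(u, d1, d2))^pow, winsor[1], winsor[2],
            rel.tol = 1e-8)$value
        mid + winsor[1] * zlo^pow + (1 - winsor[2]) * zhi^pow
    }
    mom(2) - mom(1)^2
}

# Invert winsorizedLogFVar over d2 (monotone decreasing to the d2 = Inf
# limit, a scaled chi-square). Observed variance at or below that limit
# means no detectable prior scatter: d0 = Inf.
matchWinsorizedLogF <- function(obsVar, d, winsor) {
    if (is.na(obsVar)) return(Inf)
    floorVar <- winsorizedLogChisqVar(d, winsor)
    if (obsVar <= floorVar * (1 + 1e-6)) return(Inf)
    g <- function(logd0) winsorizedLogFVar(d, exp(logd0), winsor) - obsVar
    lo <- log(0.05); hi <- log(5e5)
    if (g(lo) < 0) return(exp(lo))    # more scatter than any prior allows
    if (g(hi) > 0) return(Inf)
    exp(stats::uniroot(g, c(lo, hi), tol = 1e-6)$root)
}

winsorizedLogChisqVar <- function(d, winsor) {
    zlo <- log(stats::qchisq(winsor[1], d) / d)
    zhi <- log(stats::qchisq(winsor[2], d) / d)
    mom <- function(pow) {
        mid <- stats::integrate(function(u)
            log(stats::qchisq(u, d) / d)^pow, winsor[1], winsor[2],
            rel.tol = 1e-8)$value
        mid + winsor[1] * zlo^pow + (1 - winsor[2]) * zhi^pow
    }
    mom(2) - mom(1)^2
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on a monotone,
# convex-in-1/y function; trigamma is strictly decreasing so the root is
# unique. Very small x means a huge y (flat prior): cap at Inf.
trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2)
        y <- y + dif
        if (abs(dif) / y < 1e-8) break
    }
    y
}

#' Moderated t-test per fragment
#'
#' \code{t = logFC / sqrt(s2tilde * c)} referred to a t distribution on
#' \code{d0 + d} degrees of freedom (normal when \code{d0 = Inf}); p-values
#' are two-sided.
#'
#' @param logFC Log2 fold changes (DamPOI - Dam).
#' @param s2tilde Posterior variances.
#' @param d0 Prior degrees of freedom.
#' @param df Residual degrees of freedom.
#' @param c Coefficient variance multiplier (\code{1/n1 + 1/n2}).
#' @return List: \code{t}, \code{p.value}, \code{df.total}.
#' @export
moderatedTTest <- function(logFC, s2tilde, d0, df, c) {
    stopifnot(length(logFC) == length(s2tilde), c > 0)
    dfTotal <- d0 + df
    tstat <- logFC / sqrt(s2tilde * c)
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    deg <- s2tilde == 0
    if (any(deg)) {
        p[deg] <- ifelse(logFC[deg] == 0, 1, 0)
        tstat[deg] <- ifelse(logFC[deg] == 0, 0, sign(logFC[deg]) * Inf)
    }
    list(t = tstat, p.value = p, df.total = dfTotal)
}

#' Differential methylation test across all fragments
#'
#' Convenience wrapper running \link{fitLinearModels},
#' \link{fitVarianceTrend}, \link{squeezeVariances} and
#' \link{moderatedTTest} on a normalized matrix.
#'
#' @inheritParams fitLinearModels
#' @param abundance aveLogCPM per fragment (needed when \code{trend}).
#' @param fragments Optional fragment table (chrom, start, end, index) bound
#'   onto the result.
#' @param trend Fit the intensity-dependent prior trend (default TRUE);
#'   otherwise the prior is the mean residual variance.
#' @param robust Robust (winsorized) prior-df estimation (default TRUE).
#' @param span Lowess span for the trend.
#' @return \code{data.frame}: per fragment logFC, aveLogCPM, s2, s02,
#'   s2tilde, t, p.value, plus coordinates when supplied; prior df in
#'   \code{attr(, "d0")}.
#' @export
testFragments <- function(values, groups, abundance = NULL, fragments = NULL,
                          trend = TRUE, robust = TRUE, span = 0.4) {
    fit <- fitLinearModels(values, groups)
    s02 <- if (trend) {
        if (is.null(abundance)) stop("abundance required when trend = TRUE")
        fitVarianceTrend(fit$s2, abundance, fit$df, span)
    } else rep(mean(fit$s2), length(fit$s2))
    sq <- squeezeVariances(fit$s2, s02, fit$df, robust)
    mt <- moderatedTTest(fit$logFC, sq$s2tilde, sq$d0, fit$df, fit$c)
    out <- data.frame(logFC = fit$logFC,
                      aveLogCPM = if (is.null(abundance)) NA_real_ else abundance,
                      s2 = fit$s2, s02 = s02, s2tilde = sq$s2tilde,
                      t = mt$t, p.value = mt$p.value)
    if (!is.null(fragments))
        out <- cbind(fragments[, c("index", "chrom", "start", "end")], out)
    attr(out, "d0") <- sq$d0
    attr(out, "df.residual") <- fit$df
    out
}
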