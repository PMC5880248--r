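#' Percent methylation at a GATC site from qPCR quantities
#'
#' qDamID measures Dam methylation at individual GATC sites by qPCR across
#' the site on genomic DNA digested (+DpnII) or not (-DpnII): DpnII cuts
#' unmethylated GATC, so template surviving digestion is methylated. With
#' absolute quantities from a standard curve,
#' \code{\% = digested / undigested * 100}.
#'
#' Values above 100\% can arise from measurement noise and are retained;
#' values above 120\% trigger a warning as likely assay problems.
#'
#' @param digested,undigested Non-negative quantities in shared arbitrary
#'   units (typically the mean of qPCR triplicates); vectorized.
#' @return Percent methylation per site.
#' @export
percentMethylation <- function(digested, undigested) {
    stopifnot(length(digested) == length(undigested))
    if (any(digested < 0) || any(undigested < 0))
        stop("quantities must be non-negative")
    if (any(undigested == 0))
        stop("undigested quantity of 0 leaves percent methylation undefined")
    pct <- digested / undigested * 100
    if (any(pct > 120))
        warning(sum(pct > 120), " site(s) above 120% methylation; ",
                "check quantification")
    pct
}

#' Dam-subtracted qDamID enrichment score
#'
#' Enrichment of the POI fusion over untethered Dam at site x, expressed as
#' the difference of normalized shares:
#' \code{score_x = \%x^POI / sum_i(\%i^POI) - \%x^Dam / sum_i(\%i^Dam)}.
#' Scores over the assayed sites sum to zero by construction; they are
#' invariant to rescaling either condition and negate when the conditions
#' are swapped.
#'
#' @param percentPOI,percentDam Percent-methylation vectors over the same
#'   sites (names preserved).
#' @return Per-site subtract scores.
#' @export
damidSubtract <- function(percentPOI, percentDam) {
    if (length(percentPOI) != length(percentDam))
        stop("condition profiles must cover the same sites")
    sPOI <- sum(percentPOI); sDam <- sum(percentDam)
    if (sPOI <= 0) stop("zero total methylation in condition POI")
    if (sDam <= 0) stop("zero total methylation in condition Dam")
    percentPOI / sPOI - percentDam / sDam
}

#' Full qDamID profile from a measurement table
#'
#' @param x \code{data.frame} (or CSV path) with columns \code{site},
#'   \code{condition} (\code{Dam} or \code{POI}), \code{digested},
#'   \code{undigested}; replicate rows per (site, condition) are averaged
#'   before the formulas are applied.
#' @return \code{data.frame}: \code{site}, \code{pct_dam}, \code{pct_poi},
#'   \code{subtract}.
#' @export
qdamidProfile <- function(x) {
    if (is.character(x))
        x <- utils::read.csv(x, stringsAsFactors = FALSE)
    need <- c("site", "condition", "digested", "undigested")
    if (!all(need %in% names(x)))
        stop("input must have columns: ", paste(need, collapse = ", "))
    if (!all(x$condition %in% c("Dam", "POI")))
        stop("condition must be 'Dam' or 'POI'")
    agg <- stats::aggregate(cbind(digested, undigested) ~ site + condition,
                            data = x, FUN = mean)
    sites <- unique(x$site)  # preserve input site order
    getC <- function(cond) {
        a <- agg[agg$condition == cond, ]
        if (!all(sites %in% a$site))
            stop("condition ", cond, " missing sites: ",
                 paste(setdiff(sites, a$site), collapse = ", "))
        a <- a[match(sites, a$site), ]
        percentMethylation(a$digested, a$undigested)
    }
    pctDam <- getC("Dam")
    pctPOI <- getC("POI")
    data.frame(site = sites, pct_dam = pctDam, pct_poi = pctPOI,
               subtract = damidSubtract(pctPOI, pctDam),
               stringsAsFactors = FALSE)
}
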