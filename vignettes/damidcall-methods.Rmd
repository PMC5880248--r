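---
title: "Statistical methods behind damidcall"
author: "damidcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind damidcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidcall)
```

# The measurement model

DamID infers where a protein of interest (POI) binds the genome by fusing it
to the *E. coli* Dam adenine methyltransferase: wherever the fusion touches
DNA, nearby GATC motifs acquire 6mA. Cutting methylated GATC with DpnI,
amplifying, and sequencing yields reads whose genomic origin is a **GATC
fragment** — the interval between two consecutive DpnI cut sites. Because
untethered Dam also methylates DNA (preferentially accessible, nucleosome-free
chromatin), every experiment pairs Dam-POI samples with Dam-only controls, and
binding is inferred from *differential* methylation: fragments with
significantly more reads in Dam-POI than in Dam-only.

This makes the analysis a count-based two-group differential test over a fixed
genome partition, closer to RNA-seq differential expression than to ChIP-seq
peak calling, and the toolkit is built accordingly.

## The coordinate system: GATC fragments

`buildFragmentMap()` places a cut at offset +2 inside every GATC occurrence —
the blunt DpnI cleavage point between GA and TC. The motif cannot overlap
itself, so cut placement needs no tie-breaking; any ambiguity code (N) breaks
a match, and matching is case-insensitive. Fragments tile each chromosome
exactly: sorted, adjacent, jointly covering `[0, length)`, in 0-based
half-open coordinates throughout (BED output is therefore native). The exact
within-motif cut offset is a convention — any consistent choice shifts all
boundaries identically — but +2 matches the enzyme.

## Counting

Reads are filtered to primary mapped alignments; unmapped, secondary and
supplementary records are dropped, along with reads on alternative, unplaced
or mitochondrial contigs (configurable name patterns, since conventions vary
across assemblies) and reads overlapping an exclusion list by at least 1 bp.
**PCR duplicates are kept**: reads originate from a discrete set of fragment
ends, so duplicate coordinates are expected from genuine signal and removing
them would censor exactly the strongest fragments.

A read counts toward a fragment only when **fully contained** in it; reads
spanning a cut site count nowhere (they are evidence about the cut, not about
either fragment). A sample's library size is the number of reads passing the
filters, assigned or not — normalization should track sequencing depth, not
assignability. Reads exactly coinciding with fragment bounds are contained
(half-open intervals, inclusive on both comparisons).

# Normalization

## Abundance filter

Background fragments are removed before testing to lighten the
multiple-testing burden: a fragment is kept only when its average abundance
exceeds the 10-read equivalent on the aveLogCPM scale,

$$\mathrm{aveLogCPM}_f = \log_2\frac{\bar y_f + p}{\bar L + 2p}\cdot 10^6,
\qquad \text{cutoff} = \log_2\frac{10 + p}{\bar L + 2p}\cdot 10^6,$$

with pseudocount $p = 2$, $\bar y_f$ the mean count and $\bar L$ the mean
library size. "10 or lower" is inclusive: a fragment averaging exactly 10
reads is dropped.

## TMM scale factors

Composition bias matters here: genuinely enriched fragments in Dam-POI
libraries consume depth that would otherwise fall on background, deflating
background coverage relative to Dam-only at equal depth. Trimmed-mean-of-M
factors correct this: against a reference sample (upper-quartile count
fraction closest to the mean), each sample's factor is 2 to the weighted mean
of log2 ratios after trimming 30% on M and 5% on A, with inverse
asymptotic-variance weights, rescaled to geometric mean 1. Effective library
size is `lib.size * factor`; logCPM uses a library-proportional pseudocount
so equal-abundance fragments score equally at unequal depth.

## Smooth quantile normalization

DamID replicates — especially from few cells — vary strongly in their global
count distributions, but part of that difference *is the biology*: Dam-POI
and Dam-only samples genuinely differ globally. Plain quantile normalization
would erase that. Smooth quantile normalization interpolates per quantile
between the overall reference $\bar Q_i$ and the group reference
$\bar Q_{i,g}$ with weight

$$w_i = \mathrm{clamp}\!\left(1 - \mathrm{SSB}_i/\mathrm{SST}_i,\ 0,\ 1\right),$$

smoothed by a running median over 5% of the quantiles: where samples agree
across groups ($w \to 1$) everything is forced to one distribution; where the
between-group spread explains the variability ($w \to 0$) each group keeps its
own distribution. Ties on the original scale receive the mean of their tied
positions' normalized values, which makes the transform deterministic and
order-independent. A companion permutation test (`quantroTest()`) measures
whether group distributions differ globally at all — the condition under which
the smooth variant is preferred; it collapses the reference package's
two-stage ANOVA into a single quantile-level F-ratio, which is sufficient for
an appropriateness check (it is not used for inference). Note the resolution
limit at three-versus-three: about 10% of label permutations are
group-equivalent to the observed assignment and always tie the observed
statistic, so permutation p-values cannot fall much below 0.1 at that size.

# Differential testing

Per fragment, ordinary least squares on the two-group design gives the log2
fold change (Dam-POI minus Dam-only), the pooled residual variance $s^2$ on
$d = n - 2$ degrees of freedom, and the coefficient variance multiplier
$c = 1/n_1 + 1/n_2$. Moderation then borrows strength across fragments in
two steps.

**Trend.** Residual variance depends systematically on abundance, so the
prior follows a lowess of $\log(s^2 + 10^{-8})$ on aveLogCPM (span 0.4),
corrected for the bias $E[\log(\chi^2_d/d)] = \psi(d/2) - \log(d/2)$ before
exponentiating into the trend variance $s_0^2$.

**Empirical Bayes.** True variances are modeled as scattered around the trend
with a scaled inverse-chi-square prior on $d_0$ degrees of freedom, under
which $s^2/s_0^2 \sim F(d, d_0)$ and
$\mathrm{var}(\log s^2/s_0^2) = \psi'(d/2) + \psi'(d_0/2)$. Moment matching
on $z = \log(s^2/s_0^2)$ solves for $d_0$ by monotone root finding. The
robust variant winsorizes $z$ at the 5%/95% quantiles so hypervariable
outlier fragments do not inflate the apparent prior spread — and, because
winsorizing shrinks a variance, the matching target is the correspondingly
winsorized variance of the log-F distribution itself, computed by numeric
integration on the probability scale. Without that calibration the estimator
is badly biased toward $d_0 = \infty$; with it, simulations from a true
$d_0 = 4$ recover estimates within a few percent. Observed scatter at or
below the pure sampling floor yields $d_0 = \infty$ and full shrinkage to the
trend. The posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ always lies between $s^2$ and
$s_0^2$, and the moderated statistic
$t = \mathrm{logFC}/\sqrt{\tilde s^2 c}$ is referred to $t_{d_0+d}$
(standard normal at $d_0 = \infty$). Setting $d_0 = 0$ with a flat trend
recovers the classical pooled two-sample t-test exactly, which the test suite
uses as an oracle.

# From fragments to peaks

Retained fragments are clustered with a gap tolerance of 260 bp — the median
GATC fragment size of the mm10 assembly, so that a single filtered-out
fragment of typical size does not break a region — and clusters wider than
10 kb are split into near-equal spans with fragments assigned by midpoint
(any deterministic split respecting the cap is acceptable; this one is the
simplest to verify). Member p-values combine by Simes,
$p_{\mathrm{region}} = \min_k m\,p_{(k)}/k$, valid under the positive
dependence expected of neighboring fragments; Benjamini–Hochberg across
regions controls the FDR. A region's representative log fold change is that
of its smallest-p member (ties to the smallest fragment index). A region is
called a peak iff FDR < 0.1 **and** representative logFC > 0.5, both strict,
positive direction only — peaks are Dam-POI enrichments; depleted regions
stay in the region table but are never called.

For noisy replicate sets (e.g. single-embryo libraries) an optional
high-confidence filter keeps peaks with mean log2 peak-level CPM above 4.5
and coefficient of variation below 0.75, both computed over the Dam-POI
replicates (peak CPM = sum of member-fragment CPM). The reference sample set
and count scale for this filter are conventions of this package: mean log2
CPM over Dam-POI replicates, chosen as the most directly interpretable.

# Coverage tracks

`genomeCoverage()` collapses per-base depth into value runs (bedGraph
semantics, zero runs omitted); scaling uses counts-per-million on effective
(TMM-adjusted) library sizes — the same factors the tests use, recorded in
the track metadata since other conventions exist; group tracks are means of
per-replicate scaled tracks; and the Dam-subtracted track is the piecewise
difference over the breakpoint union, retaining negative values (Dam-only
excess is informative). All operations keep tracks canonical: sorted,
non-overlapping, no two adjacent runs sharing a value.

# qDamID

For site-level validation by qPCR, percent methylation at a site is
$[\mathrm{Digested}]/[\mathrm{Undigested}] \times 100$ on absolute quantities
(means of triplicates; DpnII cuts only unmethylated GATC, so surviving
template is methylated). Enrichment of the POI over Dam at site $x$ is the
difference of normalized shares across the assayed sites:

$$\mathrm{subtract}_x =
\frac{\%_x^{POI}}{\sum_i \%_i^{POI}} - \frac{\%_x^{Dam}}{\sum_i \%_i^{Dam}}.$$

Scores sum to zero over sites, are invariant to rescaling either condition,
and negate under condition swap. Percentages above 100 are retained as
measurement noise; above 120 they trigger a warning.

# The simulator, and what the benchmarks do and do not show

`simulateGenome()` plants GATC motifs at geometric spacing (default rate
1/256 per position, the density of uniform base composition) with i.i.d.
fill; accidental motifs in the fill are destroyed by a single base change, so
the realized density matches the target, and the fragment map is always
rebuilt by scanning the emitted sequence. `simulateCounts()` draws
negative-binomial counts (dispersion 0.1) around means proportional to a
log-normal fragment accessibility shared between groups — the key nuisance of
real DamID, an accessibility-driven Dam-only background — with bound
fragments (1% of the genome by default) boosted $2^\beta$-fold ($\beta = 2$)
in Dam-POI samples, under a normalizer that makes enrichment compete for
sequencing depth exactly as in a real library. The accessibility spread
(log sd 1, roughly an order of magnitude of background variation) is this
package's choice of a realistic chromatin profile. `simulateReads()`
realizes counts as uniformly placed reads fully inside fragments, so
counting them reproduces the matrix *exactly* — the identity the test suite
asserts end to end.

The standard benchmark runs 3-vs-3 at 20,000 fragments and mean depth 50
reads per fragment over 20 seeded replicates, consuming counts directly
(read realization being proven exact separately, the counts-level run is
equivalent and keeps the benchmark to seconds per replicate). Under those
conditions the workflow averages recall ≥ 0.8 on planted fragments with a
false-discovery proportion ≤ 0.15, and ≤ 1 called region on fully null data.

What the simulation does **not** model: mappability and GC bias, fragment-
size-dependent amplification, methylation carry-over between neighboring
sites, replicate-specific Dam expression levels, or sequence errors. Passing
benchmarks therefore demonstrate the statistics are correctly assembled and
calibrated under the stated model — not that real libraries meet that model.

# Numerical and design notes

- All randomness (simulator, permutation test) flows through explicit seed
  arguments via a local RNG scope; no function perturbs the caller's RNG
  state.
- The variance-trend lowess is evaluated by interpolation with boundary
  rule "nearest" and mean-tie handling; all-zero residual variances fall
  back to a constant floor trend with a warning.
- `quantroTest()` guards the 0/0 statistic (identical columns) to 0, and its
  p-value has resolution $1/(B+1)$.
- Degenerate moderated tests ($\tilde s^2 = 0$) report p = 0 for a nonzero
  logFC and p = 1 otherwise, flagged by an infinite statistic.
- The counts TSV stores counts as doubles on read-back, so values beyond
  32-bit range survive a round trip exactly.
- Paired-end data are outside the current scope (the protocol sequences
  50-bp single-end); a proper-pair outer-span extension is possible behind
  the same counting contract.
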