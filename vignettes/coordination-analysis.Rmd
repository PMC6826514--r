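---
title: "Expression variability and coordination analysis with genofabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression variability and coordination analysis with genofabric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofabric)
library(SummarizedExperiment)
```

## The model

Differential-expression analysis compares mean transcript abundances between
conditions.  genofabric implements a complementary view of a replicated
expression profile, built from three statistically independent per-gene
measures within each condition:

1. the **average expression level** of each transcript;
2. its **relative expression variability** (REV) across biological
   replicates -- a proxy for how tightly the cell's homeostatic machinery
   controls that transcript's abundance;
3. its **expression coordination** with every other gene -- the Pearson
   correlation of the two genes' expression across biological replicates of
   the *same* condition.

The premise is what one may call transcriptomic stoichiometry: genes acting
in a common pathway must be kept in definite mutual proportions, so their
responses to the small, uncontrolled fluctuations of the micro-environment
that distinguish biological replicates should be correlated.  Replicates
are therefore treated not as nuisance repetition but as probes of the
coupled response of the transcriptional network.

The package targets replicated two-colour microarray designs in which each
transcript is probed redundantly by $R_i \in \{1, \dots, 28\}$ spots and
each condition is measured in four biological replicates, but nothing in
the code is specific to those numbers.

## Spot filtering and normalization

`filterSpots()` removes, globally across all samples, control spots, spots
corrupted in any sample, and spots whose foreground is less than
`snr_factor` (default 2) times the background in *any* sample or channel.
The inequality is strict, so a spot sitting exactly at the factor is
retained, and removal is global because a spot that fails anywhere is
unreliable everywhere.  A removal is attributed to the first matching rule
in the order control, corrupted, low-signal, and tallied in a report.

`normalizeIterative()` alternates two scaling steps: an inter-array step
that divides each array by the median ratio of its spots to a cross-array
geometric-mean consensus, and an intra-array step that divides each array
by the median of its valid spots.  Each iteration therefore ends with every
array's median at exactly 1.  Iteration stops when an error functional --
by default the maximum absolute relative change of any value between
successive iterations -- falls below `tolerance` (default 0.05).  The
functional is pluggable because "maximum error of estimate" admits several
readings; the default is the simplest monotone criterion.  The procedure
is deterministic, idempotent at its fixed point, and invariant under global
rescaling of the input.

Two practical notes.  Two-colour inputs are reduced to one expression value
per spot as background-subtracted foreground (negatives clipped at a small
configurable floor), with the channel-combination rule (single channel,
ratio, or geometric mean) a dialect option, since raw two-colour data admit
several defensible conventions.  And median scale factors are only as
stable as the array is dense: with tens of thousands of spots the
per-sample scale noise is negligible, while toy examples with a few dozen
spots will show visible common-mode distortion.  Test fixtures in the
package therefore use hundreds of spots when correlation structure is under
scrutiny.

## REV: redundancy-corrected pooled variability

For transcript $i$ probed by spots $k = 1, \dots, R_i$, with per-spot
replicate means $\mu_{ik}$ and standard deviations $s_{ik}$ (n−1
denominator), `computeREV()` estimates

$$\mathrm{REV}_i \;=\; \underbrace{\frac12\!\left(
  \sqrt{\frac{\nu}{\chi^2_{1-\epsilon/2;\nu}}} +
  \sqrt{\frac{\nu}{\chi^2_{\epsilon/2;\nu}}}\right)}_{\text{redundancy
  correction}} \times\; 100\sqrt{\frac{1}{R_i}\sum_{k=1}^{R_i}
  \left(\frac{s_{ik}}{\mu_{ik}}\right)^{2}},$$

with $\nu = 4R_i - 1$ degrees of freedom and $\epsilon = 0.05$.  The right
factor is the root-mean-square of the per-spot CVs (in percent); the left
factor is the mid-point of a chi-square interval estimate, which shrinks
from about 2.15 at $R_i = 1$ toward 1 as redundancy grows, giving more
credit to transcripts probed by many spots.  REV is scale-free and reduces
to correction × CV for a single-spot transcript.

The chi-square quantile convention is configurable (`revConfig()`): the
default `"sigma-ci"` takes square roots of $\nu/\chi^2$ (the interval for a
standard deviation); `"variance-ci"` omits them.  Historically reported
endpoint values for this correction do not match either convention --- no
mid-point of an interval bracketing the point estimate can fall below 1 for
all $\nu$ --- so the convention in force and its $R = 1$ and $R = 28$
endpoints are recorded in the result metadata rather than silently
calibrated to any external anchor.

Regulation calls (`regulationCall()`) are a deliberately simple surrogate
labelled as such in the output: fold change as the ratio of combined means
(negative-reciprocal convention below 1, threshold 1.5×), a Welch t-test on
the replicate profiles, and a Bonferroni-style correction applied only
within the transcript's redundancy group (`min(1, R p)`), never across
distinct genes --- correcting across genes would treat the profiling of
different transcripts as repeated tests of one hypothesis, which it is not.

## Coordination: replicate-level correlation with redundancy-aware df

`coordinatePairs()` correlates, for every enumerated gene pair of a set,
the spot-averaged replicate profiles of the two genes, on the log2 scale by
default.  Significance uses a two-tailed t-test with
$df = 4R - 2$ where $R$ is the spot redundancy: redundant probing
contributes independent spot-level evidence, so two genes probed by two
spots each are tested at $df = 6$ rather than 2.  When redundancies differ
the conservative default takes $R = \min(R_i, R_j)$; an all-spot-pairings
alternative ($df = 4R_iR_j - 2$, correlating the stacked spot pairings) is
available but off by default because it overstates the information content.
The minimal significant $|\rho|$ is $t^*/\sqrt{t^{*2} + df}$ --- 0.95 at
$df = 2$, 0.71 at $df = 6$.

Each pair is classified **POS** ($\rho$ above the critical value), **NEG**
(below its negative), **IND** ($|\rho|$ under an independence threshold,
default 0.05 -- a configurable operationalisation of "significantly
uncorrelated", for which no exact test statistic is standard), or
**UNCLASSIFIED** (everything else, including undefined correlations from
constant profiles, which are surfaced rather than dropped: record counts
always equal `countPairs()` counts).  No multiple-testing correction is
applied across distinct pairs, for the same reason as above.

`detectReversals()` reports pairs significantly positive in one condition
and significantly negative in another -- the strongest qualitative
signature of network rewiring between conditions.  `buildNetwork()`
assembles signed graphs (isolated genes retained, IND/UNCLASSIFIED pairs
edgeless), `diffNetworks()` partitions pair changes into gained, lost,
sign-reversed and unchanged, and `exportGraph()` writes GraphML (round-trip
safe for status, sign, and rho), TSV edge lists, or DOT.

## Pair-wise relevance

`pwrScore()` ranks gene pairs by
$$\mathrm{PWR}_{ij} = \frac{\mu_i\mu_j}{\bar\mu^2}\;\rho_{ij}^2\;
  \frac{\overline{\mathrm{REV}}^2}{\mathrm{REV}_i\,\mathrm{REV}_j},$$
the product of a relative-expression term, a squared-correlation term, and
a relative-control term.  A pair is prominent when both genes are expressed
above the fabric average, strongly coordinated (either sign), and under
tighter-than-average abundance control.  The fabric means $\bar\mu$ and
$\overline{\mathrm{REV}}$ are arithmetic means over **all** quantified
unigenes of the condition, not over the analyzed subset -- this choice
matters (it changes every score by a common factor per condition) and makes
scores comparable across subsets.  PWR is symmetric, carries no
significance gate on $\rho$, and is invariant under global rescaling of all
expression levels or all REVs.  `pwrLandscape()` arranges cross-set scores
as a dense matrix (undefined entries are `NA`, never silent zeros) and
`topPairs()` extracts the top-k with deterministic lexicographic
tie-breaking.

## The synthetic-data generator

`simulateDataset()` emulates the study design the pipeline targets:
five conditions (one unstimulated, two stimulation patterns × two
durations), four biological replicates, spot redundancy drawn from a
distribution concentrated at 1 with a tail to 28, and two-channel-style
foreground/background intensities with injected control, corrupted and
low-signal spots for filter testing.

Replicate-level log2 expression of gene $g$ is
$$y_{gr} = b_g + \sigma_g\Big(\sum_m \sqrt{s_m}\,\lambda_{gm} f_{mr}
  + \sqrt{1 - \sum_m s_m\lambda_{gm}^2}\; e_{gr}\Big),$$
with standard-normal factor draws $f$ shared by all member genes of a
module and idiosyncratic draws $e$.  The log2-additive Gaussian model makes
programmed CVs translate analytically:
$\sigma_g = \sqrt{\log(1 + cv_g^2)}/\log 2$.  Two member genes with
loadings $\lambda_g, \lambda_h$ and factor share $s$ have true replicate
correlation $s\,\lambda_g\lambda_h$, so signed coordination (and its
reversal, via condition-restricted modules) is programmable.  Spot values
add independent log2 noise; foreground is `scale * 2^value` plus the
recorded background draw.  A factor share exceeding the total programmed
variance is rejected as an infeasible decomposition.

By default the generator standardizes second moments (`empirical = TRUE`,
in the spirit of `MASS::mvrnorm(empirical = TRUE)`): factor draws are
standardized per condition and idiosyncratic draws orthogonalized against
them, so each gene's realized replicate variance and each designated pair's
correlation sign match the programmed values exactly instead of up to
$n = 4$ sampling error (at four replicates the sample SD of a raw Gaussian
draw has a median about 11% below truth, which would dominate any recovery
comparison).  Monte-Carlo purists can set `empirical = FALSE`.

What the generator does **not** emulate: dye bias and dye swaps, spatial
(print-tip) artifacts, probe-sequence effects, intensity-dependent
(loess-type) trends, and outlier contamination.  Tests passing on this
synthetic data therefore validate the estimators and their bookkeeping
under the stated noise model, not robustness to those real-data pathologies.

## Numerical choices and problem sizes

* Quantiles come from `stats::qt`/`stats::qchisq`; tests verify them
  against numeric CDF inversions.
* Undefined correlations (constant profiles) propagate as `NA` /
  UNCLASSIFIED; zero REV is a domain error for PWR (infinite control
  term); zero spot means are a domain error for REV.
* Ties in `topPairs()` break lexicographically by pair key, making ranks
  stable under record order.
* The default test and verification runs use 60--500 simulated genes,
  redundancy 1--2, and 5--10 seeds per property; recovery medians are
  taken over hundreds of genes.  These sizes make the suite complete in
  well under a minute while leaving the sampling error of each checked
  statistic far below its asserted tolerance.

## Interface

The package's interface is its R API plus `runPipeline()`, which
orchestrates filter → normalize → summarize/REV → regulation →
coordination → PWR → networks → reversals from a single
`pipelineConfig()` (or a YAML file via `readPipelineConfig()`), writing
every stage output and a manifest carrying the configuration hash and
convention choices.  An analysis package of this kind is driven from R
scripts and vignettes rather than a shell; no separate command-line binary
is shipped.

## A short worked example

```{r example, eval = FALSE}
genes <- sprintf("G%04d", 1:60)
cfg <- simulationConfig(
    n_genes = 60, conditions = c("UNST", "STIM"), replicate_cv = 15,
    base_level_log2 = function(n) rnorm(n, 1.5, 1),
    redundancy_sampler = function(n) rep(2L, n),
    modules = list(list(genes = genes[1:5], loadings = rep(1, 5),
                        strength = 0.97, conditions = "STIM")))
ds <- simulateDataset(cfg, seed = 8)
st <- computeREV(summarizeTranscripts(
    normalizeIterative(filterSpots(rawData(ds)))))
rec <- coordinatePairs(st, "STIM", genes[1:10])
coordinationProfile(rec)
topPairs(pwrRecords(st, rec, "STIM"), 3)[, c("gene_a", "gene_b", "pwr")]
```

## Limitations

REV's chi-square correction assumes approximately normal replicate noise
on the measurement scale; heavy-tailed noise will widen it.  Pearson
coordination at four replicates has little power below $|\rho| \approx
0.95$ for single-spot genes -- the redundancy-based df gain is the lever,
and the independence class is a pragmatic cutoff, not an equivalence test.
PWR inherits the noise of all three ingredients and, like the correlation
itself, is symmetric: it cannot say which gene of a prominent pair drives
the other.
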