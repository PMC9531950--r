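---
title: "Methods: quantifying coupled transcription and translation under glucose starvation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying coupled transcription and translation under glucose starvation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcoupler)
```

txcoupler packages the quantitative layer of a common experimental design
in yeast stress biology: promoters of alternative glucose metabolism genes
couple the transcription of an mRNA to its cytoplasmic fate (granule
localization, translational repression) during glucose starvation, with
the Rvb1/Rvb2 AAA+ ATPases as the co-transcriptionally loaded adaptors.
Each module mirrors one assay family; this vignette records the models,
the tunable parameters, the numerical choices, and what the synthetic
data can and cannot establish.

## The kinetic model

Induced mRNA abundance is modeled by first-order synthesis and decay,

$$\frac{dX}{dt} = \beta - \alpha X,$$

with transcription rate $\beta$ (abundance units/min), degradation
constant $\alpha$ (/min), and initial abundance $X_0$. The closed form is

$$X(t) = X_0 + \left(\frac{\beta}{\alpha} - X_0\right)(1 - e^{-\alpha t}),$$

with steady state $X_{ss} = \beta/\alpha$, approach half-time
$\ln 2/\alpha$, and the linear limit $X(t) = X_0 + \beta t$ at
$\alpha = 0$. After transcription shut-off (1,10-phenanthroline in the
assay this emulates), $X(t) = X_0 e^{-\alpha t}$ and the half-life is
$\ln 2 / \alpha$; `fit_decay()` estimates it as $-1/\text{slope}$ of an
ordinary least-squares line through log2 abundance, pooling replicates.
Slopes within $10^{-12}$ of zero report the `+Inf` sentinel rather than
an absurd finite half-life.

All fitting operates on log2-transformed values. qPCR-derived abundances
carry multiplicative error — replicate scatter grows with the signal —
so a Gaussian model on the log scale is the natural error model and
matches how these time courses are plotted and compared.

### What is identifiable from fold data

Induction time courses are usually reported as fold over the pre-stress
baseline, $F(t) = X(t)/X_0$. `fit_induction()` therefore parameterizes by
$(\alpha, F_{ss})$ with $X_0 \equiv 1$:

$$F(t) = 1 + (F_{ss} - 1)(1 - e^{-\alpha t}).$$

$\beta$ is only recoverable as $\alpha F_{ss} X_0$ and the absolute
$X_0$ is not observable from folds, so $\beta$ is deliberately not
returned. The optimizer is Levenberg–Marquardt least squares
(minpack.lm) multi-started from a deterministic grid of decay constants
$\alpha_0 \in \{\ln 2/5,\ \ln 2/25,\ \ln 2/60\}$ /min — half-times of
5, 25 and 60 min bracket the range seen for stress-induced transcripts —
with box constraints $\alpha \in (10^{-5}, 10]$ and
$F_{ss} \in [1, 10^6]$. Multi-start from a fixed grid keeps fits
reproducible without any seed. A flat course leaves $\alpha$
unidentifiable; the fit returns `converged = FALSE` with $F_{ss} = 1$
instead of an arbitrary number.

### Discriminating a transcription change from a decay change

At constant $\alpha$, scaling $\beta$ shifts the log-scale fold curve up
by a constant; lowering $\alpha$ instead produces an offset that keeps
growing as the treated curve climbs toward a higher steady state it
approaches more slowly. `classify_mechanism()` makes this operational:
it computes per-time offsets
$d(t) = \log_2 F_{treated}(t) - \log_2 F_{control}(t)$ for
$t \ge t_{min}$ and regresses $d$ on $t$ by OLS. A significant trend
calls `decay_shift`; a flat trend with mean offset at least
`min_effect_log2` calls `transcription_shift`; a mean offset below the
floor is `indistinguishable`. The trend test is evaluated before the
effect floor because a growing offset is diagnostic of a decay change
even while its running mean is still small.

Defaults, all configurable:

* `t_min = 5` min — at $t = 0$ both folds are 1 by construction, so the
  earliest points carry no offset information and, away from the
  $X_0 \ll \beta/\alpha$ limit, contaminate the constant-shift
  prediction;
* `trend_alpha = 0.05` — conventional test size; it is also the
  irreducible misclassification rate for true transcription shifts;
* `min_effect_log2 = 0.25` — offsets below ~19% in linear scale are
  treated as biologically indistinguishable.

When replicate counts match between conditions, offsets are formed
replicate-by-replicate (replicates are exchangeable), which carries the
replicate scatter into the trend test and gives it realistic degrees of
freedom; with unequal counts the per-time means are used. Mismatched
time grids are linearly interpolated in $(t, \log_2 F)$, consistent with
the log-scale model — but piecewise-linear re-gridding of a curved
noiseless trajectory leaves curvature artifacts in the offsets, so a
shared sampling grid is preferred whenever the design allows it.

The constant-shift prediction under $\beta$ scaling is exact only in
the strong-induction limit $X_0 \ll \beta/\alpha$. The packaged
simulation study of the classifier therefore uses a control model with
$\alpha = \ln 2/25$ /min (the reporter half-life scale) and steady-state
fold 300 — a strongly induced gene whose pre-stress abundance is far
below its starved steady state — with lognormal noise CV 5%, 4
replicates, and the 6-point grid {0, 5, 10, 15, 30, 45} min. Across
$\beta$-scalings {2, 4, 8} and $\alpha$-scalings {0.5, 0.25} at 200
seeds each, the acceptance suite requires at least 95% correct calls.

## qPCR: ΔΔCt and the RIP cascade

Cycle thresholds are log2-linear in template abundance with perfect
doubling assumed (efficiency correction is out of scope). Replicate Cts
are averaged on the Ct scale before differencing; standard errors
propagate replicate variances on the log2 scale (the delta method is
exact there, since fold = $2^{-\Delta\Delta Ct}$).

`rip_enrichment()` implements the three-stage cascade used for RNA
immunoprecipitation: (1) target Ct minus reference-gene Ct within each
(strain, fraction); (2) IP minus input within each strain; (3) the
tagged strain's enrichment over the untagged wild-type IP control.
When wild-type records are absent the two-stage result is returned with
`wt_normalized = FALSE` and a warning — reporter-by-reporter designs
legitimately omit the WT arm, but the two quantities must not be
confused silently. The input dilution factor (an input that is 1% of
the lysate) is a constant log2 offset that cancels in stage 3; in
two-stage mode it can be applied via `input_fraction` (default 1,
i.e. no correction).

Outlier handling is manual by design: `read_ct_tsv(exclude = ...)`
accepts an exclusion list of flagged samples, mirroring how technically
aberrant qPCR samples are documented and removed; nothing is dropped
automatically.

## ChIP coverage, metagenes, and gene classes

Coverage enters as fixed-bin bedGraph tracks and BED6 annotations
(0-based, half-open — the BED convention, chosen for interoperability).
Enrichment is RPKM of ChIP over RPKM of input (`normalized_density()`),
or, for factor-versus-control-IP comparisons, depth-normalized target
over control density. The promoter window is the strand-aware
$[TSS-500, TSS)$ interval; since its length is constant across genes,
`promoter_enrichment()` uses raw counts with the control library scaled
to the target depth, and `log2((target + pc)/(control + pc))` with a
0.5-read pseudocount guarding sparse control windows. As the
pseudocount shrinks toward zero with strictly positive counts, ratios
converge to the raw ratio; the pseudocount also makes depth invariance
approximate rather than exact on the rescaled side, which is the usual
price of shrinkage.

`metagene()` lays each gene on a normalized axis: a 500 bp upstream
flank in 10 bp bins, the body mean-pooled to 100 bins, and a 500 bp
downstream flank, with minus-strand genes reversed so the axis always
runs promoter→terminator. Genes shorter than one body bin are excluded
with a warning. The bin defaults are conventional profile-tool
granularity and are configurable. Class-level comparison
(`class_compare()`) is a Welch two-sample t-test on per-gene log2
ratios plus empirical CDF coordinates; per-gene significance is
deliberately not computed — the biological claims this supports are
class-level. Gene classes (e.g. induced-and-well-translated class I
versus induced-and-granule-localized class II) come from a user-supplied
class table, not from expression data, which keeps the module free of
any particular induction-calling rule.

## Reporter expression and ribosome occupancy

`protein_rate()` is the luciferase arithmetic: OD-normalized
luminescence minus the OD-normalized reading of the paired
cycloheximide-treated well (translation stopped minutes earlier, so the
CHX well carries the translation-independent background). Negative
rates are reported with a `negative_rate` QC flag, never clamped —
a baseline exceeding the signal is an assay failure worth seeing.

Translatability is defined as log2 relative protein minus log2 relative
mRNA, both as fold over the same control. This direction is the only
one under which repressed translation with elevated mRNA yields a
negative value, which is how the quantity is used; the fold form
$2^{\text{translatability}}$ is also returned.

Ribosome occupancy is footprint RPM over mRNA RPM in the ORF region
from 120 nt after the AUG to the ORF end — the initiation region is
excluded because footprint pileups there reflect initiation, not
elongation flux. ORFs of 120 nt or less have no downstream region and
are rejected. Zero mRNA reads give an NA sentinel with a QC flag rather
than an infinite ratio. `positional_occupancy()` is the per-base
variant against the gene's mean mRNA density.

Foci scoring (`compare_foci()`) compares the fraction of cells with
reporter-mRNA granules by a t-test on replicate fractions (matching how
such percentages are typically analyzed with two biological replicates
of ~200 cells), with a pooled two-proportion test as an alternative
mode.

## The CoTrIP screen

`enrichment_volcano()` computes, per protein, the log2 fold change of
mean spectral counts between promoter groups (pseudocount 0.5) and a
Welch t-test on the counts, allowing the unbalanced 2-versus-3 replicate
design. The test runs on raw counts by default — matching how such
screens are usually reported — with a `log_counts` mode available; no
multiple-testing correction is applied, matching the screen's use of a
raw p < 0.05 shortlist. That is a deliberate caveat: the candidate list
is a hypothesis-generating ranking, not an error-controlled discovery
set. Candidates are ordered by fold change descending with ties broken
by protein id, so the list is a deterministic function of the input.
`background_filter()` drops candidates insufficiently enriched over a
user-supplied background proteome table; proteins absent from the
background are retained and flagged rather than silently kept or
dropped.

## Synthetic data: what it emulates and what it does not

The generators reproduce the statistical skeleton of each assay:

* time courses — closed-form trajectories times lognormal noise of unit
  mean and configured CV (default 5%, typical of replicate qPCR
  scatter), 4 replicates, grid {0, 5, 10, 15, 30, 45} min;
* Ct tables — $Ct = c_0 - \log_2(\text{abundance}) + N(0, \sigma)$ with
  the reference gene held constant;
* genomes — non-overlapping genes with random strands on a toy genome
  (60 genes, 2 chromosomes, 10 bp bins), Poisson bin counts, and
  class II promoter windows given an elevated mean in the target track
  only. Intergenic gaps are at least 1 kb so adjacent 500 bp promoter
  windows never overlap. All three tracks record the nominal library
  depth as their total: the generators emulate depth-matched libraries,
  as sequencing to a set depth produces;
* luciferase plates — paired wells with a CHX-resistant background
  term;
* counts — Poisson (region counts) or negative-binomial (spectral
  counts, dispersion 5 by default).

One global seed expands into fixed per-generator substreams, so outputs
are bit-reproducible and mutually independent; generators restore the
ambient RNG state. Files are written with 6 significant digits for
byte-stable output.

What passing on synthetic data does **not** show: real coverage has
mappability gaps, fragment-length autocorrelation and copy-number
structure that Poisson bins lack; real qPCR has efficiency drift and
plate effects beyond a global offset; real spectral counts share
peptides between proteins. The suite validates the estimators'
arithmetic, invariances and statistical calibration under the stated
noise models, not robustness to those artifacts.

## Problem sizes and runtime choices

The packaged checks use a 75-point $(\alpha, \beta, X_0)$ grid against
fixed-step RK4 integration (step 0.01 min over 0–120 min, agreement
within $10^{-6}$), 200-seed Monte-Carlo runs for classifier correctness
and parameter recovery, 100-seed runs for type-I calibration of the
decay comparison, and single-seed toy genomes of 20–60 genes at depth
$10^5$–$10^6$ for the coverage round-trips — sizes at which every
property is measurable with comfortable margin while the whole suite
runs in well under a minute.

## Known limitations

* The kinetic model assumes rates constant over the induction window;
  time-varying $\alpha(t)$, $\beta(t)$ and Bayesian inference are out
  of scope.
* Absolute $\beta$ cannot be fit from fold data (documented above).
* The classifier's transcription-shift accuracy is bounded by
  $1 - $ `trend_alpha` by construction, and degrades when induction is
  weak ($F_{ss}$ within an order of magnitude of 1), where the
  constant-shift prediction itself fails.
* The ChIP module consumes coverage, not alignments; alignment,
  deduplication and peak calling belong to upstream tools.
* Foci counts and region read counts are inputs; no image segmentation
  or P-site assignment is performed.
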