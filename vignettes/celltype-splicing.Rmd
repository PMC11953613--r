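---
title: "Calling cell-type-specific splicing and expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cell-type-specific splicing and expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecall)
```

# Scope and model

`splicecall` operates downstream of read alignment. Its inputs are junction
read counts per splicing event and sample, a raw gene-count matrix with
per-gene uniquely-mappable lengths, and a sample sheet assigning each
library to a cell type and an organ group (`root` or `aerial`). Organs are
always analysed separately: cell types within one organ share dissociation
and sorting conditions and form the natural comparison set, while
cross-organ contrasts would conflate organ identity with cell identity.

## PSI estimation

For a two-outcome event, inclusion is witnessed by two junctions (the two
exon–intron boundaries of a retained intron; the two flanking junctions of
a skipped exon) but exclusion by one. To keep both forms on a per-read
scale the inclusion evidence is the *mean* of the two junction counts:

$$\mathrm{PSI} = 100\,\frac{(j_1+j_2)/2}{(j_1+j_2)/2 + e}.$$

For alternative donor/acceptor events with $k \ge 2$ variant junctions,
variant $v$ gets $\mathrm{PSI}_v = 100\, r_v / \sum_i r_i$; the variant
PSIs of one event sum to 100 by construction, and the first declared
variant (`V1`) is the focal one reported in the event-level matrix.

Two conventions matter for degenerate inputs:

* A zero denominator yields a *missing* PSI, never 0 — absence of evidence
  is not evidence of exclusion.
* Half-counts produced by averaging are kept as reals in the PSI formula;
  the coverage tier is computed from the floored informative total, so
  tiers are integer-deterministic across platforms.

## Coverage tiers and event filtering

Each cell gets one of `N < VLOW < LOW < OK < SOK` from its informative
read total, with default cutoffs 10 / 15 / 20 / 100 (inclusive at each
boundary). The tier names are the conventional read-support labels for
inclusion tables; the numeric cutoffs are this package's fixed,
configurable choice. The default analysable set keeps events covered at
`LOW` or better in at least 10 samples across cell types.

## The intron-retention balance test

Reads supporting genuine retention should hit both exon–intron boundaries
at comparable rates; gross imbalance indicates mis-mapping or an
overlapping feature rather than a retained intron. Per (event, sample) we
test the upstream boundary count against Binomial(upstream + downstream,
0.5), exact and two-sided, and mask the cell when $p < 0.05$. Design
choices, all configurable:

* only the two boundary junctions enter the statistic;
* no multiplicity correction — this is per-sample evidence screening, not
  inference, and correction would only make an already conservative
  discrete test more permissive as a filter;
* both boundaries zero means there is no evidence of a real junction: the
  cell is treated as failing, even though PSI may be numerically 0 from
  exon–exon reads alone;
* masking happens *before* the 10-sample coverage count, so an IR event
  must be coverable with balanced evidence.

The exact test is conservative under discreteness: at $n = 50$ reads the
realised rejection rate at $\alpha = 0.05$ is about 0.033 (the largest
achievable level below 0.05), which the calibration test bounds at 0.06
and checks against the uniform by a one-sided Kolmogorov–Smirnov
comparison.

## Splicing specificity (DSE)

Within one organ, for event $e$ and target cell type $t$:

* **global** $\Delta\mathrm{PSI} = \bar{\mathrm{PSI}}_t -
  \bar{\mathrm{PSI}}_{\text{others}}$, where "others" pools all covered
  samples outside $t$, *sample*-weighted. Weighting samples rather than
  cell-type means is the literal reading of "average of all other
  samples"; a cell-type-weighted pool would down-weight cell types with
  more replicates. This is one of the two genuinely open readings we fixed
  (the other is the PSI range, below).
* **minimum** $\Delta\mathrm{PSI}$: over every other cell type with at
  least `min_replicates` covered values, the mean difference of smallest
  magnitude, sign preserved.
* **PSI range**: each cell type with any covered value contributes its
  maximum replicate PSI; the range is max − min of these maxima. The
  source phrasing ("the difference between the maximum value from a cell
  type with the maximum value from another") is ambiguous; we adopt the
  max-of-maxima minus min-of-maxima reading, which reduces to the plain
  two-cell-type difference when only two cell types are covered and
  otherwise asks whether *any* pair of cell types differs in attained PSI.

A call requires |global| > 25, |minimum| > 15 and range ≥ 2 (defaults).
The Δ-PSI comparisons are strict (`>`) — consistent with the "ΔPSI > 25"
convention of upset-style summaries — while the range is inclusive; both
are switchable. Sign agreement between the global and minimum ΔPSI is
*not* required by default (only magnitudes are thresholded); a
`require_sign_match` switch tightens this. Eligibility: ≥ 2 covered
replicates per cell type, ≥ 4 covered cell types per organ, otherwise the
event contributes nothing in that organ. One event may be called in
several cell types (e.g. up in one, down in another); non-overlap of calls
is a property of data, not enforced.

## Expression specificity (DEG)

Expression uses cRPKM — counts normalised by uniquely mappable positions
(the effective length actually usable by the aligner) and library size.
The four rules, evaluated per organ on cell-type medians: eligibility
(median cRPKM ≥ 5 somewhere), per-cell-type fold change ≥ 2, global fold
change ≥ 5 against the median of all other samples, absolute difference
≥ 2 cRPKM against every other cell type. Fold changes are linear and
symmetric (ratio ≥ x or ≤ 1/x); outputs report the global ratio as log2.
Where the source material labels figure axes "log2 FC ≥ 2" while its
methods say "fold change ≥ 2", we follow the methods and keep every
threshold configurable. Ratios are pseudocounted with 0.01 so zero-vs-zero
is neutral (ratio 1) and zero-vs-expressed is decisively large.

Size factors are plain median-of-ratios against the geometric-mean
pseudo-reference, excluding genes with any zero count; with an even number
of usable genes the *lower* median is taken so the factor is always an
observed ratio (and deterministic). A single sample gets factor 1; a
matrix with no zero-free gene is an error rather than a silent fallback.
One identifiability note: any relative normalisation of this kind
determines normalised counts only up to a common positive rescaling — if
one library's counts are multiplied by $c$, every factor picks up
$c^{-1/m}$ through the geometric-mean reference, and all normalised counts
a common $c^{1/m}$. The invariance test therefore asserts equality of
normalised counts up to one global scalar, with the scaled library's
factor absorbing the *relative* change exactly.

## Enrichment

Term over-representation uses the one-tailed hypergeometric
$P(X \ge k)$ and its conservative EASE variant $P(X \ge k-1)$, which
discounts one gene from the observed overlap so single-gene "enrichments"
score 1. The background is custom — it should be the genes that passed the
same quality filters as the calls, not the genome. Benjamini–Hochberg
adjusted EASE p-values are appended; raw values are retained because the
corresponding reference analyses report the unadjusted modified p-value.

# The simulator

`simulate_dataset()` emulates the target study design: 7 root + 4 aerial
cell types, 3 replicates (the reference design spans 3–6; 3 is the
modal/minimal choice and keeps eligibility tight), 1,000 events at class
proportions 0.65 IR / 0.17 ALTA / 0.08 ALTD / 0.10 EX — the prevalence
ranking reported for plant cell-type AS surveys, with intron retention
dominant — and 2,000 genes. Per event a baseline PSI is drawn uniformly on
[5, 95]; planted events (20% by default, assigned to cell types
round-robin so every cell type receives signal) shift the baseline by 40
PSI points in a feasible direction (clipped to [1, 99]; infeasible
baselines are redrawn and counted). Per sample the realised PSI is a beta
draw with mean equal to the true PSI and intra-class correlation
$\rho = 0.02$ (parameterised $a = m(1-\rho)/\rho$,
$b = (1-m)(1-\rho)/\rho$ — one intuitive dispersion knob), depth is
Poisson(100) informative reads, and inclusion units are binomial at the
realised PSI. Each inclusion unit contributes one read at *each* boundary
junction — the $2U$ boundary reads are split Binomial($2U$, 0.5) between
the two — so the boundary-averaging estimator is exactly unbiased and the
balance test sees balanced junctions by construction. Gene counts are
negative binomial (dispersion 0.1) around log-normal means
(meanlog = log 200, sdlog = 1), with a planted 8-fold change (up or down)
in the planted cell type; mappable lengths are uniform on [200, 3000].

What the simulator does **not** emulate: positional read biases,
overlapping genes and mis-mapping (the very artifacts the balance filter
exists for — simulated IR junctions are balanced by construction, so the
filter's false-negative cost on real artifacts is untested here),
correlated events within a gene, organ-level batch structure, and
library-size variation beyond NB noise. Passing recovery tests therefore
demonstrate that the callers implement their rules correctly and are
well-calibrated under the stated noise model — not that the thresholds are
optimal for any particular real data set.

# Verification design and problem sizes

* **Oracle equivalence.** Both callers are compared to independently
  written straight-line evaluators of the criteria on 500 random
  one-organ instances each (4 cell types, 2–3 replicates, uniform PSI
  with 15% missingness; log-normal cRPKM), requiring identical call sets.
* **Recovery.** The reference recovery run uses one organ with 4 cell
  types × 3 replicates, 1,000 events with 200 planted at ΔPSI 40, depth
  100, ρ = 0.02, and the analogous 8-fold expression planting; bounds are
  recall/precision ≥ 0.90 and direction accuracy ≥ 0.99. A signal-free
  twin bounds the false-call rate at 1%.
* **Estimator consistency.** At depth 1,000 with near-zero beta
  dispersion, the per-event mean PSI estimate over the 12 replicates must
  land within 2 points of the event's generative baseline for ≥ 95% of
  1,000 events. The per-event mean is the right unit here: a *single*
  sample's estimate at depth 1,000 carries irreducible binomial noise of
  ≈ 1.3 PSI points at mid-range PSI, so no unbiased per-sample estimator
  could meet a 2-point/95% bound — averaging replicates is also exactly
  how the calling criteria consume PSI.
* **Round-trip.** The PSI table dialect stores values at two decimals and
  balance p-values at six significant digits; `quantify_psi()` rounds to
  the same precision, so write → read is the identity and repeated
  serialisation is byte-stable. Pipeline outputs are byte-identical under
  a fixed seed.

These sizes keep the full suite under a minute while leaving wide margins
to every bound.

# Known limitations

* The balance statistic uses only the two boundary junctions; variants of
  the filter that also weigh the exon–exon junction would be stricter on
  borderline retention. The α and the statistic's scope are configurable.
* The rule-based callers provide no error control in the inferential
  sense — they are deterministic threshold screens, as in the reference
  procedure. The simulator quantifies their operating characteristics
  under an explicit noise model instead.
* `dpsi_min` compares only cell types with sufficient covered replicates;
  a cell type with one noisy replicate is invisible to that rule (it still
  enters the pooled global comparison and the PSI range).
* Focal-variant reporting for ALTA/ALTD condenses a $k$-way event to one
  PSI; the read-share PSIs of the remaining variants are recoverable from
  the junction table but are not carried in the matrix container.
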