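# splicecall

Cell-type-specific alternative-splicing and gene-expression calling for
sorted-cell RNA-seq designs, with a planted-signal simulator for
end-to-end validation.

## The problem

Surveys of alternative splicing (AS) across sorted cell populations — for
example FACS-isolated *Arabidopsis* protoplasts marked by cell-type-specific
promoters, split into root and aerial organ groups — need to answer two
questions per cell type: which splicing events are used differently in this
cell type than in every other, and which genes are expressed specifically
here? `splicecall` implements the full desk side of that analysis:

1. **PSI quantification.** For each event and sample, the percent
   spliced-in value is estimated from junction-spanning reads. For
   two-outcome events (intron retention IR, exon skipping EX) the two
   inclusion-supporting boundary junctions are averaged:
   `PSI = 100 · I / (I + E)` with `I = (j₁ + j₂)/2`; for alternative
   donor/acceptor events (ALTD/ALTA) a variant's PSI is its read share, so
   variant PSIs sum to 100. Every value carries a coverage tier
   (`N < VLOW < LOW < OK < SOK`) from its informative read total.
2. **Intron-retention balance filter.** Genuine retained introns
   accumulate reads at both exon–intron boundaries; a per-sample exact
   two-sided binomial test at p = 0.5 on the two boundary counts masks
   imbalanced (artifactual) retention signals at α = 0.05.
3. **Differentially spliced events (DSE).** Within each organ separately,
   a covered event (tier ≥ LOW in ≥ 10 samples) is specific to a cell type
   when |global ΔPSI| > 25 (target mean vs the pooled mean of all other
   same-organ samples), |minimum ΔPSI| > 15 against *every* other covered
   cell type, and the spread of per-cell-type maximum PSI is ≥ 2. A cell
   type needs ≥ 2 covered replicates; an organ needs ≥ 4 covered cell
   types.
4. **Differentially expressed genes (DEG).** On mappability-corrected
   expression, `cRPKM = raw · 10⁹ / (mappable positions · library size)`:
   eligibility median cRPKM ≥ 5 in some cell type, fold change ≥ 2 vs every
   other cell type's median, ≥ 5 vs the global median of all other samples,
   and absolute difference ≥ 2 cRPKM vs every other cell type. Size-factor
   (median-of-ratios) normalised counts are also produced.
5. **Downstream layers.** DEG/DSG overlap and upset intersection patterns,
   event-class proportions, gene-set (e.g. immunity list) subsetting,
   predicted protein-impact breakdowns, splicing-vs-expression quadrants,
   and term over-representation with the conservative EASE variant of the
   one-tailed Fisher test (`P(X ≥ k−1)` instead of `P(X ≥ k)`) against a
   custom background.
6. **Simulator.** A seeded generator plants nonoverlapping
   cell-type-specific splicing shifts (beta-binomial PSI noise, Poisson
   depth) and expression fold changes (negative-binomial counts) into a
   two-organ, multi-cell-type design and emits a truth table, so recall,
   precision and false-positive rates of the whole pipeline are measurable.

## Worked example

```r
library(splicecall)

cfg <- sim_config(n_cell_types_root = 4, n_cell_types_aerial = 0,
                  replicates = 3, seed = 42)
sim  <- simulate_dataset(cfg)
psi  <- quantify_psi(sim$junctions, sim$events, samples = sim$samples)
psi
#> psi_matrix: 1000 events x 12 samples
#>   event types: IR=650, EX=100, ALTA=170, ALTD=80
#>   missing PSI: 0 of 12000 cells

filt  <- filter_events(psi)          # coverage + IR balance: 995 events kept
calls <- call_dse(filt, sim$samples)
head(calls[, c("event_id", "cell_type", "direction",
               "dpsi_global", "dpsi_min", "psi_range")], 3)
#>      event_id cell_type direction dpsi_global dpsi_min psi_range
#> 1 SIM_IR_0007    pATHB8        up       47.82    45.74     59.76
#> 2 SIM_IR_0014     pTMO5      down      -50.45   -48.76     53.77
#> 3 SIM_IR_0015      pPXY        up       40.68    38.43     41.80

truth_recovery(calls, sim$truth, "event")[c("recall", "precision")]
#> $recall    0.995
#> $precision 1
```

Each call row reads: the event is specific to that cell type, in the
direction of its global ΔPSI (e.g. `SIM_IR_0007` is retained ~48 PSI points
more in `pATHB8` than the average of all other root samples, at least ~46
points more than any single other cell type, and spans ~60 points between
cell-type maxima). Of the 200 planted events, 199 are recovered with no
false positives. The expression side is symmetric:

```r
expr <- expression_matrix(sim$counts, sim$mappable_positions)
deg  <- call_deg(expr, sim$samples)       # 385 calls
overlap_summary(deg, calls, sim$events)[c("n_deg", "n_dsg", "n_overlap")]
#> $n_deg 385   $n_dsg 191   $n_overlap 37
```

A shell interface with the same stages (`simulate`, `quantify`,
`call-dse`, `call-deg`, `summarize`, `enrich`, `report`) is available via
`inst/scripts/splicecall`; every stage echoes its effective configuration
into the output directory.

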