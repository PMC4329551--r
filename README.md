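# tfcr — TFBS-clustered region discovery and integrative analysis

Sequence-specific transcription factors (TFs) bind regulatory DNA in
dense clusters. `tfcr` finds these **TFBS-clustered regions**
genome-wide from per-cell-type binding-site maps and carries them
through the downstream analyses a regulatory-genomics study needs:
complexity categorisation with HOT/COLD flagging, a cross-cell-type
master list, saturation analysis, signal and nucleosome-structure
profiling, cell-lineage clustering, and conservation summaries. A
synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable offline.

## The model

Each binding site contributes an unnormalised Gaussian kernel centred on
its midpoint, so the density at position *x* from sites *s₁…sₙ* is

    ρ(x) = Σᵢ exp( −(x − sᵢ)² / (2b²) ),   b = 300 bp

Every strict local maximum *p* of ρ is a region. Sites with kernel
weight k(|p − sᵢ|) ≥ θ = 0.1 are *contributing*; their summed weights
are the **TFBS complexity** C (an effective site count), and the window
extends max contributing distance + b/2 = 150 bp on each side of *p*.
Complexities are binned into ten categories TC0–TC9 (upper bounds 6, 8,
10, 12, 14, 16, 19, 23, 30, ∞; bands low = TC0–2, median = TC3–7,
high = TC8–9). A region bound by more than 40 distinct TFs is HOT; a
TC0 region is COLD.

Downstream statistics include a Weibull saturation model
y(x) = A·(1 − exp(−(x/λ)^k)), a two-component geometric mixture for
adjacent-site gaps, FFT power at the nucleosomal repeat, central
nucleosome depletion D (background minus centre occupancy), Euclidean
presence distance Φ with single-linkage ("nearest-neighbour") lineage
clustering, Hungarian precursor placement, Baker's Γ and
Fowlkes–Mallows B_k dendrogram comparison, and nucleotide diversity π.

## Worked example

```r
library(tfcr)

# a 10-Mb synthetic landscape: 120 planted clusters, 6 cell types
ls <- gen_tfbs_landscape(landscape_config(n_cells = 6, n_clusters = 120),
                         seed = 42)
regions <- lapply(ls$cells, call_regions)
head(as.data.frame(regions$cell1)[, c("peak", "start", "end",
                                      "complexity", "category")], 3)
#>     peak  start    end complexity category
#> 1 256066 255734 256398   7.649557      TC1
#> 2 263371 263034 263708   7.445344      TC1
#> 3 412247 411940 412554   7.531607      TC1

master <- build_master_list(regions)
nrow(master); median(master$ubiquity)
#> [1] 120
#> [1] 4

sat <- saturation_curve(regions, n_samples = 500, seed = 42)
fit <- fit_weibull_saturation(sat)
fit$A
#> [1] 120.8615    # extrapolated saturation: ~120 unique elements

mix <- fit_interval_mixture(diff(sort(site_positions(ls$cells$cell1))),
                            seed = 1)
c(mix$within_mean, mix$within_q995)
#> [1]  50.04064 263.00000  # within-cluster gaps ~46-50 bp; 99.5% < ~263 bp
```

Every call above is deterministic given its seed. The region table says:
each planted cluster was found once (120 master entries), a typical
region is ~600–700 bp wide with an effective 7–8 contributing sites
(TC1), regions recur in a median of 4 of the 6 cell types, the
saturation fit extrapolates to the true 120 planted loci, and the gap
mixture separates within-cluster spacing (~50 bp) from the long
between-cluster component.

The same stages are scriptable from the command line
(`inst/exec/tfcr`): `simulate`, `call-regions`, `master-list`,
`saturate`, `annotate`, `profile`, `enrich`, `nucleosome`,
`lineage-cluster`, `lineage-bootstrap`, `lineage-sensitivity`,
`conserve`, each with `--seed` and `--config` support.

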