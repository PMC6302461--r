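# tfhic

Which transcription factors (TFs) are enriched in high-intensity,
mainly inter-chromosomal, chromatin interactions in yeast? Metazoan genomes
use CTCF to organize chromatin loops; budding yeast has no CTCF, so the
factors shaping its inter-chromosomal contacts have to be found
statistically. `tfhic` is an R package plus analysis workflow that does
this from a Hi-C contact list and a TF binding-site map:

1. **Binning & filtering** — chromosomes are tiled into 1-kb bins; contact
   records are aggregated per bin pair into interactions with read count
   *n*; intra-chromosomal pairs closer than 1 kb and interactions with
   *n* ≤ 5 are discarded; the analysis targets the inter-chromosomal subset.
2. **Overlapping ratio** — for TF *t* and threshold *T*, with
   *A* = {interactions with *n* ≥ *T*} and *B* = {interactions touching a
   binding site of *t*},

   *r_t(T)* = |A ∩ B| / |A|

   is the fraction of at-least-*T*-intensity interactions overlapping the
   TF's sites.
3. **Method 1: chi-square scan** — at every *T* in 7..45 each TF yields a
   2×2 table (*A* vs *Ā* × *B* vs *B̄*); uncorrected Pearson chi-square
   (df = 1) with Bonferroni control over all testable (TF, *T*) cells;
   a TF is significant if any threshold reaches adjusted *p* < 0.05.
4. **Method 2: bootstrapped elastic net** — response: read level *n*;
   predictors: all TFs' overlapping ratios at threshold *n*; five ranges
   (6..40 … 6..60), 500 resamples each, mixing weight 0.5, penalty by
   10-fold CV; TFs kept in >5% of fits (>25 per range or >125 of 2,500)
   are selected, with a mean-coefficient score.
5. **Trend comparison & intersection** — a Cochran–Armitage-style
   trend-in-proportions test per (TF, range) with a reported direction;
   the headline candidate set is the intersection of Methods 1 and 2,
   exported as BEDPE links for circos-style plots.

Because real accession-level inputs are not required for development, the
package ships a **synthetic study generator** (`sim_config()`,
`write_fixture()`): a yeast-like 16-chromosome genome, heavy-tailed
interaction counts (~50% of interactions at ≤10 reads), 100 TFs of which
10 are *planted* with binding probability increasing in interaction
intensity. Every stage is validated against this ground truth.

## Worked example

```r
library(tfhic)
res <- run_pipeline(list(sim = sim_config(seed = 1), seed = 1))
```

which logs the record counts at every stage:

```
simulated 49790 interactions (39872 inter-chromosomal)
binned: 49790 unique bin pairs, 638727 reads
filtered: removed 32 close intra pairs and 0 low-read pairs; 49758 remain
subset 'inter': 39872 interactions
labelled 39872 interactions x 100 factors
chi-square scan: 10 significant factor(s)
elastic net: 69 selected factor(s)
combined: 10 factor(s) significant in both methods
```

```r
res
#> <pipeline_result> 39872 interactions, 100 factors; chi-square 10, elastic net 69, both 10
res$combined$intersection
#>  [1] "TF008" "TF007" "TF006" "TF009" "TF002" "TF003" "TF005" "TF010" "TF001"
#> [10] "TF004"
```

The chi-square scan recovers exactly the ten planted factors; the
elastic-net list is broader (its >5% frequency rule is a ranking, not a
calibrated error control — see the methods vignette), and intersecting the
two methods restores a clean candidate set.

`res$combined$intersection` lists the factors called by both methods —
under the planted study all of them are true planted factors — and
`res$enet$selection` holds the per-TF bootstrap table (selection counts per
range, total, mean coefficient, sign consistency). The same pipeline runs
on real files via
`run_pipeline(list(contacts = ..., tfbs = ..., chrom_sizes = ...))`.

The step-by-step version of this analysis lives under `analysis/`
(`01_simulate_data.R` … `05_trend_combine.R`); each script narrates what it
finds and writes its tables under `results/tables/`.

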