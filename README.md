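# wormlegacy

Quantitative building blocks for transgenerational-longevity studies in
*C. elegans* — the kind of study that crosses a long-lived strain (e.g. an
intestinal lipase transgenic) back to wild type and asks whether the
descendants inherit the longevity, which chromatin marks carry it, which
genes respond, and where a maternally delivered histone ends up inside the
oocyte. The package implements four analysis layers as a tidyverse-style R
library, each testable end to end on seeded synthetic data with known ground
truth:

- **Replicated lifespan statistics.** Kaplan–Meier estimation, a log-rank
  test per biological replicate, replicate combination by Fisher's method
  (chi² = −2 Σ log pᵢ on 2k df), and the headline summary
  `extension % = 100 · (mean_treated − mean_control) / mean_control`
  computed on observed-event lifespans.
- **H3-normalized histone-mark ChIP-seq profiling.** Depth scaling, per-base
  `mark / (H3 + ε)` ratio tracks, TSS ± 1 kb signal matrices and
  metaprofiles compared with the rank-sum test, and differential-site
  calling over fixed 200-bp genome windows (Welch test on replicate window
  means, Benjamini–Hochberg FDR, fold-change floor).
- **Candidate-gene integration.** Differential windows mapped to genes
  (body + upstream promoter overlap), intersection of the two-mark
  (me2 ∩ me3) enriched sets, filtering of an expression table at
  fold change > 1.5, p < 0.01, FDR < 0.05, promoter extraction bounded by
  the nearest annotated neighbor, and position-weight-matrix motif scanning
  of both strands.
- **Radial fluorescence profiling.** For every pixel of a polygonal cell
  ROI, the normalized radius `r = d(pixel, center) / d(center, boundary
  along the same ray)` is computed by exact ray–polygon intersection; the
  signal channel is binned over `r ∈ (0, 1]`, aggregated over cells nested
  in replicates, normalized to a negative control, and compared per bin with
  a two-way ANOVA plus Bonferroni-adjusted per-bin tests.

Seeded generators (`gen_survival()`, `gen_genome_and_tracks()`,
`gen_expression()`, `gen_promoters()`, `gen_image()`) emit the exact formats
the pipeline reads together with machine-readable truth, so no external data
are needed anywhere.

## Worked example

```r
library(wormlegacy)

life <- gen_survival(n_per_replicate = 90, n_replicates = 3,
                     extension_pct = 35, seed = 11)
res <- combined_lifespan_test(life, control = "control")
res
#> Replicate-combined lifespan test (treated vs control, 3 replicates)
#>   mean lifespan: treated 27.42 d, control 19.61 d  -> extension +39.8%
#> Fisher's method: chi2 = 384.168 df = 6 p = < 2.2e-16
```

The per-replicate table behind the summary:

```r
generics::tidy(res)
#> # A tibble: 3 × 10
#>   replicate n_treated n_control events_treated events_control mean_treated
#>       <int>     <int>     <int>          <dbl>          <dbl>        <dbl>
#> 1         1        90        90             88             87         27.5
#> 2         2        90        90             84             83         27.8
#> 3         3        90        90             87             87         27
#> # ℹ 4 more variables: mean_control <dbl>, extension_pct <dbl>, ...
```

Each replicate of ~90 worms is tested by log-rank on its own; the three
p-values are combined by Fisher's method (6 df), and the +39.8% is the
pooled mean-lifespan extension of the treated arm — the simulation planted
+35%, so the estimate is within sampling error. `autoplot(kaplan_meier(...))`
draws the survival curves; `run_pipeline()` drives whole simulate-then-analyze
runs from one YAML config with a digest manifest.

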