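---
title: "Models and methods behind wormlegacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wormlegacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormlegacy)
```

wormlegacy packages the quantitative layers of a transgenerational-longevity
study — replicated lifespan assays, H3-normalized histone-mark ChIP-seq, a
ChIP × RNA × motif candidate funnel, and radial fluorescence profiling of
oocytes — as reusable, property-tested functions. This vignette records the
models, the tunable parameters and their defaults, the numerical choices,
and the design decisions that were genuinely open, so a maintainer can see
*why* the code is the way it is. Every empirical statement here is one the
test suite or `scripts/acceptance.R` computes itself.

## Replicated lifespan analysis

A lifespan experiment is a set of biological replicates, each a treated and
a control cohort of individually followed worms (day of death or censoring,
event flag). Within each replicate `combined_lifespan_test()` runs the
log-rank test: over the distinct event days, observed minus expected deaths
in one arm with hypergeometric variance, events on the same day pooled into
one risk-set update (lifespans are recorded in whole days). Replicates are
independent biological runs, so their p-values are combined with Fisher's
method, $\chi^2 = -2\sum_i \log p_i \sim \chi^2_{2k}$. A p-value of exactly
0 makes the log undefined; rather than flooring silently, `fishers_method()`
errors unless the caller passes an explicit `p_floor`
(`combined_lifespan_test()` uses 1e-300, the scale at which a double
underflows).

The headline number is the percent mean-lifespan extension,
$100\,(\bar T_\text{trt} - \bar T_\text{ctl})/\bar T_\text{ctl}$. Two open
choices were settled as follows:

- **Censoring.** Worm assays censor escapers and baggers; those animals
  carry no death time, so the mean uses observed events only. Censoring in
  the generator (and typically in practice) is unrelated to lifespan, so
  this exclusion is unbiased. A restricted-mean variant
  (`mean_type = "restricted"`) is exposed for heavier censoring.
- **Pooling.** The default extension pools animals across replicates; the
  mean of per-replicate extensions is also reported
  (`mean_extension_pct_replicates`). The two agree closely when replicate
  sizes are equal.

`gen_survival()` draws Gompertz lifespans — the accelerating-hazard model
that describes worm mortality far better than an exponential — with shape
0.35/day and the rate solved numerically (`gompertz_rate_for_mean()`) for a
20-day control mean, typical of wild type at 20 °C; this gives a lifespan
s.d. near 3.7 days. The treated arm multiplies the same draws by
`1 + extension/100`, so the planted extension holds exactly in expectation;
days are rounded to integers and 5% of animals are censored at a uniform
day before death. Under these conditions (3 replicates × 90 worms, +35%)
the combined test detects the effect with p < 0.001 and estimates the
extension within ±5 points in ≥95% of runs, and under the null its
false-positive rate sits at the nominal 5% — both recomputed by the
acceptance suite.

## H3-normalized ChIP-seq profiling

Coverage tracks are 0-based half-open interval tables (bedGraph in and out
via rtracklayer) expanded to per-base vectors internally — exact and cheap
at the simulated genome sizes (10⁵ bp; the vignette-scale choices keep the
full suite under three minutes of ChIP work).

**Depth scaling.** Tracks are rescaled to unit *background* depth: the
per-base depths are divided by the median of 1-kb-window mean depths. A
plain genome-wide mean was rejected because a mark's own enrichment inflates
it — with 10% of the genome enriched 3×, mean scaling deflates the
recovered treated/control ratio to 2.5 — whereas the windowed median sees
the background only (the same composition-bias argument behind TMM and
MAnorm scaling). Multiplying any input track by a positive constant leaves
every downstream ratio, matrix and call unchanged.

**Ratio normalization.** The mark signal is expressed per base as
$\text{mark}/(\text{H3} + \varepsilon)$ with $\varepsilon = 0.5$ on the
scaled H3 (about half the background depth), which caps the ratio where H3
coverage dips to zero while leaving well-covered bases essentially
untouched; a base with no mark signal has ratio 0 regardless.

**TSS matrices and metaprofiles.** `tss_signal_matrix()` averages the ratio
into 50-bp bins across TSS ± 1 kb (40 bins), reversing minus-strand windows
so bin 1 is always biological upstream; genes whose window leaves the
chromosome are dropped and counted. `metaprofile_compare()` reports bin-wise
mean curves, per-gene window means, their medians, and an unpaired
two-sample rank-sum test on the per-gene means. Whether such comparisons
should be paired per gene is genuinely ambiguous when the gene universes
coincide; unpaired is the default and `rank_sum_test(paired = TRUE)` is
available.

**Differential windows.** The genome is tiled into fixed 200-bp windows
(the last window of a chromosome may be shorter so the tiling is exact).
With replicates, each window's per-replicate mean ratios are compared by
Welch's t-test; a single-replicate design falls back to a conditional
binomial test on pooled window sums. BH correction runs over all tested
windows. A window is *called* when p < 0.01, q < 0.05 **and**
|log2 ratio| ≥ log2(1.5). The fold-change floor is deliberate: among several
hundred truly null windows, a handful will always reach p < 0.01 by chance,
and in the presence of many strong signals BH passes them too — no
calibrated test avoids that — but their effect sizes are tiny. Requiring a
minimal fold change, exactly as expression analyses do (and as this funnel's
own RNA filter does at FC > 1.5), removes them without costing any true
window; `lfc_min = 0` restores the purely statistical rule. Under the
simulated conditions (3+3 replicates, 3× enrichment, 30× depth) the called
set equals the planted set exactly, and with no planted effect the fraction
of q < 0.05 windows is below 10⁻³.

`gen_genome_and_tracks()` plants enrichment multiplicatively on the expected
H3 depth over the TSS ± 1 kb of a random gene subset, aligned to the window
grid, so the H3-normalized ratio *is* the planted factor by construction and
the truth window set is unambiguous. Gene placement is uniform and
non-overlapping; both marks share the enriched set so the two-mark
intersection has a planted truth.

## The candidate-gene funnel

`map_sites_to_genes()` assigns a called window to every gene whose body or
upstream 1-kb promoter interval it overlaps by ≥1 bp (a window spanning two
genes counts for both; a nearest-TSS-only mode exists for conservative
counting). Genes are flagged up/down per mark from the windows' directions;
`intersect_mark_sets()` reports the Venn regions and the both-marks-up set;
`filter_upregulated()` applies the strict thresholds FC > 1.5, p < 0.01,
q < 0.05; `select_candidates()` intersects and carries provenance. The
funnel is monotone: tightening any threshold can only shrink the candidate
set.

Promoters are defined as the upstream intergenic span — TSS back to the
nearest annotated neighbor boundary or the chromosome edge — because a
fixed-width promoter would silently overlap neighbors in a compact genome;
genes with span strictly >1 kb are eligible and the TSS-proximal 1 kb is
scanned (reverse-complemented for minus-strand genes). `scan_motif()` slides
a log-odds PWM over both strands and calls a hit at ≥80% of the maximum
attainable score by default (consensus-level thresholds are passed
explicitly where truth is exact). Windows containing N score −∞; sequences
over 50% N are skipped with a warning. The shipped example matrix
(`inst/extdata/pwm_sknlike_synthetic.tsv`) is a synthetic SKN-1-like matrix
for demonstrations — real analyses should supply their own matrix, since no
canonical SKN-1 PWM ships with the package. "Enrichment" is reported as the
count of promoters with ≥1 hit; `motif_enrichment_test()` adds an optional
binomial comparison against shuffled-promoter background.

`gen_promoters()` screens its background so that neither strand contains a
chance consensus occurrence before planting the motif in the chosen subset —
the truth (e.g. 18 planted among 36) is therefore exact, which is what lets
the tests demand exact recovery rather than approximate counts.

## Radial fluorescence profiling

The profiling algorithm maps every pixel of a polygonal cell ROI to a
normalized radius
$r = d(\text{pixel}, \text{center}) / d(\text{center}, \text{boundary
along the pixel's own ray})$, so non-circular oocytes land on $r \in (0,1]$
with the nuclear center at 0 and the membrane at 1. Parameterizing the ray
as `center + t·(pixel − center)` makes `r = 1/t` at the boundary
intersection, computed by exact segment intersection on the polygon rather
than on a rasterized mask — rasterization would introduce staircase bias in
the boundary distance. For non-convex outlines the crossing at or beyond the
pixel is used (furthest crossing as fallback), and `r` is clamped to 1. An
absolute-radius mode (optionally in microns via `calibrate()`, e.g.
10 μm / 97.5 px = 0.1026 μm/px) is provided because binning by absolute
distance is equally defensible when cells are size-matched; normalized is
the default.

The nuclear center is the intensity-weighted centroid of the
Otsu-thresholded nuclear channel inside the ROI (EBImage's Otsu;
parameter-free and standard). Pixels are binned into 20 equal-width radius
bins; empty bins are reported as missing, never zero; no background is
subtracted unless `background_percentile` is set. Three exact properties
anchor the implementation and are asserted without tolerance: conservation
(Σ bin mean × bin count = Σ in-ROI intensity), exact invariance under
90-degree rotations (the intersection arithmetic is written in cross
products, which that isometry preserves bitwise), and survival of all ROI
pixels into some bin. Scale invariance at integer upscaling holds to
discretization tolerance.

Group curves average cells, while the s.e.m. is computed over biological
replicate means (cells nested in replicates) — the cell-to-cell spread
within a replicate is not independent information about the biology.
Normalization to a negative control divides per bin and errors on a zero
control bin. Per-bin statistics delegate to `two_way_anova_bonferroni()`:
a group × bin two-way ANOVA with Type II sums of squares (per-replicate cell
counts of 7–15 guarantee imbalance, and Type II keeps main effects
interpretable there), plus within each bin a Welch comparison of each group
against the reference, multiplied by the number of bins and capped at 1,
with a significance flag at 0.05 mirroring the usual profile-plot display.
With a single bin the multiplier is 1 and the analysis reduces to the
one-way case. The ANOVA unit is the cell (nested labeling retained);
replicate-mean analysis can be had by aggregating first.

`gen_image()` builds elliptical cells with an offset Gaussian nucleus and a
signal channel that is flat, nuclear, or a Gaussian ring at normalized
radius r₀ — the ring radius is computed from the *analytic* ray–ellipse
intersection, deliberately independent of the polygon code it is used to
test — then applies Poisson shot noise and Gaussian read noise (amplitude
80 over baseline 10, read noise s.d. 2: SNR ≈ 8). Ring recovery (profile
argmax within one bin of r₀ for r₀ ∈ {0.3, 0.5, 0.8}) holds in ≥95% of
seeded cells.

## Statistical primitives

All primitives sit behind small wrappers with uniform result objects and
`tidy()`/`glance()` methods: Welch's t (`stats::t.test`; the
both-variances-zero corner returns p = 1 for equal means by documented
convention), one-way ANOVA with Tukey HSD (`aov` + `TukeyHSD`), BH
adjustment (`p.adjust`), Fisher's method (`pchisq` upper tail). The
rank-sum test is the one primitive written out in full: its exact path
enumerates all $\binom{m+n}{m}$ assignments of the observed values
(default for m + n ≤ 20), which stays exact under ties — the standard exact
implementation does not — and the large-sample path uses the tie-corrected
normal approximation. The FDR procedure is Benjamini–Hochberg, the field
default, chosen because the analyses here need a named, reproducible rule.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* each stage assumes:
Gompertz mortality with a multiplicative treatment effect, Poisson coverage
with multiplicative TSS-proximal enrichment on a uniform background,
negative-binomial counts with planted fold changes, composition-matched
promoter sequences with exactly known motif content, and Gaussian/Poisson
cell images with known radial patterns. They deliberately omit real-data
complications: mappability and GC structure in coverage, correlated
gene-level variation in expression, chromatin-state-dependent H3 occupancy,
out-of-focus light and segmentation error in imaging, and inter-replicate
batch effects beyond independent sampling. Passing the recovery tests
therefore demonstrates that the implementations are correct and calibrated
under their stated models — not that the models capture every property of a
real experiment. Determinism is absolute: every generator is a pure
function of its parameters and seed (`child_seed()` fans one run seed out
to stages), and `run_pipeline()` proves it by digest-identical reruns.
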