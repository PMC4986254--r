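# hkgselect

Identification and validation of stable housekeeping (reference) genes
from RNA-seq and qPCR data.

Relative expression measurements — qRT-PCR above all — are only as
reliable as the internal control genes they are normalized against.
Commonly used controls (GAPDH, ACTB, TUBA1A, B2M, ...) vary substantially
across cancer cell lines and tissues, which silently propagates into every
normalized measurement. `hkgselect` is for transcriptomics and molecular
biology researchers who need to *choose* their controls from evidence
rather than habit: it screens a whole count matrix for stably expressed
genes, filters out candidates whose apparent stability may reflect shared
regulation, and validates the surviving panel with qPCR stability
statistics and cohort-wide distribution summaries.

## The method

Given tag counts $C_{gs}$, CDS lengths $L_g$ and per-sample totals $N_s$:

1. **Normalize**: $x_{gs} = 10^9 C_{gs} / (N_s L_g)$, after summing
   isoform counts onto each gene's longest isoform; optionally quantile
   normalization (rank-mean assignment, ties averaged).
2. **Screen**: compute each gene's *0's proportion* (fraction of samples
   with zero expression) and coefficient of variation
   $\mathrm{CV} = 100\,\hat\sigma_{n-1}/\bar{x}$; candidate reference
   genes are the $k$ genes with 0's proportion 0 and the lowest CV.
3. **Network-filter**: drop candidates adjacent, in a protein-interaction
   network, to breast-cancer transcription factors (AP1, NFKB, GATA3,
   FOXA1, ER, Elk1, STAT3, STAT5, HIF, NOTCH, SP1, TP53, MYC; gene-symbol
   aliases configurable via YAML) or to other panel genes.
4. **Validate by qPCR**: per-gene C_T mean/SD/CV, panel-level C_T
   averages, leave-one-out Pearson correlation of each gene against the
   rest-of-panel mean, $\log_{10}$–$\log_{10}$ RNA-seq/qPCR concordance,
   and primer efficiency from dilution series
   ($E = 10^{-1/\mathrm{slope}} - 1$).
5. **Validate on cohorts**: persistence of expression in every sample and
   per-gene distribution statistics (quartiles, mean, SD, CV%), compared
   between the candidate and traditional panels.

A seeded synthetic-data generator (negative-binomial counts with planted
stable/variable/zero-inflated genes, log-linear C_T plates, TF-hub
interactomes) provides ground truth for testing every step.

## Worked example

Screen a synthetic experiment with known ground truth, then validate a
panel on the bundled five-cell-line qPCR plate:

```r
library(hkgselect)

cfg <- sim_config(seed = 42)              # 200 genes x 8 samples, 10 planted stable genes
sim <- simulate_counts(cfg)
expr <- normalize_length_depth(sim$counts, sim$cds_lengths)
candidates <- select_candidates(screen_genes(expr), k = 5)
candidates
#> Housekeeping-gene candidate set: 5 of 183 eligible genes (k = 5)
#> # A tibble: 5 × 8
#>   gene_id n_samples  mean    sd cv_percent zeros_proportion eligible
#>   <chr>       <int> <dbl> <dbl>      <dbl>            <dbl> <lgl>
#> 1 G0009           8 3539. 115.        3.25                0 TRUE
#> 2 G0006           8  328.  15.1       4.60                0 TRUE
#> 3 G0003           8 1842. 106.        5.77                0 TRUE
#> 4 G0002           8  272.  21.8       8.00                0 TRUE
#> 5 G0010           8 1173. 107.        9.10                0 TRUE
#> 195 genes excluded; see $excluded for reasons.
```

All five selected genes are among the ten planted stable genes
(G0001–G0010); the other 195 genes were excluded for zeros, undefined CV
or CV rank, each with a logged reason. `tidy()`, `glance()` and
`autoplot()` work on the candidate set.

The bundled plate holds threshold cycles for a five-gene novel panel
(CCSER2, UBXN4, SYMPK, TMEM11, ANKRD17) and five traditional controls
(GAPDH, B2M, ACTB, TUBA1A, 18S) across five breast cell lines:

```r
gene_ct_summary(example_ct_plate())
#> # A tibble: 10 × 7
#>    gene_id n_samples   min   max  mean    sd cv_percent
#>    <chr>       <int> <dbl> <dbl> <dbl> <dbl>      <dbl>
#>  1 GAPDH           5  15.7  20.5  17.9  1.89      10.6
#>  2 B2M             5  20.8  25.5  23.1  1.78       7.70
#>  3 ACTB            5  13.8  18.1  16.1  1.83      11.4
#>  4 TUBA1A          5  20.2  24.9  22.0  1.94       8.83
#>  5 18S             5  17.9  23.5  20.2  2.06      10.2
#>  6 CCSER2          5  27.5  31.0  29.2  1.44       4.94
#>  7 UBXN4           5  24.8  30.5  27.2  2.36       8.68
#>  8 SYMPK           5  27.3  30.8  28.9  1.55       5.35
#>  9 TMEM11          5  24.7  29.4  26.8  2.02       7.53
#> 10 ANKRD17         5  26.8  31.6  28.7  1.91       6.67

panel_mean_ct(example_ct_plate(precise = TRUE), hkg_panels()$nhkg_qpcr)
#> # A tibble: 1 × 6
#>   n_genes n_values mean_ct sd_gene_means sd_pooled mean_inv_ct
#>     <int>    <int>   <dbl>         <dbl>     <dbl>       <dbl>
#> 1       5       25    28.2          1.10      1.99      0.0357

loo_correlation(example_ct_plate(precise = TRUE))
#> # A tibble: 5 × 2
#>   gene_id     r
#>   <chr>   <dbl>
#> 1 CCSER2  0.977
#> 2 UBXN4   0.969
#> 3 SYMPK   0.983
#> 4 TMEM11  0.998
#> 5 ANKRD17 0.977
```

Read: the novel panel's genes have C_T CVs of 4.9–8.7% versus 7.7–11.4%
for the traditional controls, the novel panel averages 28.2 cycles, and
every novel gene tracks the mean of the other four at r > 0.96 — each
panel member is interchangeable with the panel consensus, which is exactly
what an internal control panel requires.

The full composition — normalize → screen → select → network-filter →
qPCR → cohort — is available as `run_hkg_pipeline()` with a list or YAML
configuration, per-stage TSV outputs and stage-named errors. See the
vignette in `vignettes/housekeeping-gene-selection.Rmd` for the model,
parameter choices and known limitations.

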