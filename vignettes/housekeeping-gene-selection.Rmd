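---
title: "Identifying and validating stable housekeeping genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and validating stable housekeeping genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkgselect)
library(dplyr)
```

## The problem

Quantitative RT-PCR and comparative RNA-seq analyses report expression
*relative to internal controls*: housekeeping genes (HKGs) assumed to be
expressed at a constant level across samples, tissues and conditions. If a
control gene in fact varies — and widely used controls such as GAPDH, ACTB
and TUBA1A do vary substantially across breast cancer cell lines and
tumors — every normalized measurement inherits that variation. `hkgselect`
implements a screening strategy that ranks candidate reference genes
directly by their measured expression stability, filters out candidates
whose stability is likely to be an artifact of shared regulation, and
validates the surviving panel with qPCR and cohort-scale statistics.

## The screening model

The pipeline operates on a gene-by-sample matrix of sequencing tag counts
$C_{gs}$ with known coding-sequence lengths $L_g$.

**Normalization.** Counts are made comparable across genes and libraries as

$$x_{gs} = \frac{10^9 \, C_{gs}}{N_s \, L_g},$$

where $N_s$ is the total number of mappable tags in sample $s$ (the column
total by default; externally fixed totals can be supplied when the matrix
is a gene subset of a larger experiment — subsetting otherwise changes
$N_s$). When counts were tallied per isoform, each isoform group's counts
are first summed and assigned to the longest isoform, because the screen
targets gene-level, not isoform-level, expression. Quantile normalization
can then force all samples onto one common value distribution (classic
rank-mean assignment; ties within a column receive the mean of the
rank-means they span).

**Breadth.** A gene's *0's proportion* is the fraction of samples in which
it is not expressed. "Not expressed" means a value of exactly zero; no
detection floor is assumed, but `min_expr` turns the rule into a threshold
for platforms with a known noise floor. Only genes with 0's proportion 0 —
expressed in every sample — are candidate reference genes.

**Stability.** The stability statistic is the coefficient of variation in
percent, $\mathrm{CV} = 100\,\hat\sigma/\bar x$ with the $n-1$ sample
standard deviation. The $n-1$ convention is deliberate: it is the one
consistent with the per-gene standard deviations the qPCR module reproduces.
The `k` fully expressed genes with the lowest CV (ties broken
lexicographically by gene symbol, for determinism) form the candidate set.

**Co-regulation filter.** Stably co-varying genes make poor *joint*
controls: if a transcription factor drives several panel members, a
condition affecting that TF shifts them together and the panel average
hides it. Candidates are therefore checked for 1-hop adjacency in a
protein-interaction network against (i) a breast-cancer TF panel (AP1,
NFKB, GATA3, FOXA1, ER, Elk1, STAT3, STAT5, HIF, NOTCH, SP1, TP53, MYC) and
(ii) the other candidates and the traditional reference panel. Because the
TF list mixes gene symbols with complex/family names, a configurable YAML
alias map (e.g. ER → ESR1, AP1 → JUN/FOS family) translates entries to the
symbols an interactome actually contains; the literal name always matches
too. A candidate absent from the interactome is treated as isolated and
retained — absence of evidence of co-regulation, which is logged. Only
direct edges count: indirect (2-hop) paths are too common in a
308k-edge-scale interactome to be informative at this step, and the filter
is deliberately conservative in what it removes. The final panel choice
stays with the user: database evidence beyond the supplied edge list
cannot be reproduced offline, so the module reports flags rather than
making the decision.

**qPCR validation.** Threshold cycles C_T are inversely related to log
transcript abundance, so expression comparisons use $1/C_T$ while
stability summaries work on raw C_T (the scale on which per-gene means,
SDs and CVs are tabulated). Three statistics matter:

- per-gene C_T mean, SD and CV across samples (low CV = stable);
- the leave-one-out correlation: each gene's C_T profile against the
  per-sample mean of the remaining panel genes. Pearson correlation is
  used — the validation is explicitly about *linear* interchangeability of
  panel members, and the downstream cross-platform comparison is framed as
  a linear regression;
- cross-platform concordance: the Pearson correlation between
  $\log_{10}$ mean normalized RNA-seq expression and $\log_{10}$ mean
  $1/C_T$, with the fitted line reported so results can be extrapolated
  between platforms. The correlation is invariant to the chosen log base;
  slope and intercept are reported base-10.

Correlations are computed on raw C_T rather than $1/C_T$: the tabulated
per-gene values the module reproduces are C_T-scale numbers, and Pearson r
is unaffected by the per-gene affine shifts that distinguish the two
representations only when the transform is linear, so the convention must
be fixed once and is fixed here.

Primer quality is checked with the standard dilution-series curve: the
least-squares slope of C_T against $\log_{10}$ relative input converts to
amplification efficiency $E = 10^{-1/\text{slope}} - 1$ (the standard
curve convention; a perfectly doubling reaction has slope $-3.32$ and
$E = 1$).

**Cohort validation.** A candidate panel is finally screened against a
large expression cohort: a gene qualifies only if it is expressed in
*every* sample (`expressed_in_all`, same floor option as the screen), and
per-gene distribution statistics (min, quartiles by linear interpolation
between order statistics, max, mean, SD, CV%) allow the candidate panel's
mean CV to be compared against the traditional panel's. The quantile
convention is the common default in scientific software (R type 7); the
cohort data needed to reverse-engineer any other convention are not
available, so the common default is the only defensible choice.

## Worked example: the bundled qPCR validation experiment

The package ships a qPCR plate of ten reference genes — a five-gene novel
panel (CCSER2, UBXN4, SYMPK, TMEM11, ANKRD17) and a five-gene traditional
panel (GAPDH, B2M, ACTB, TUBA1A, 18S) — measured across five breast cell
lines, plus the RNA-seq screen summary of both panels over eight cell
lines.

```{r qpcr}
plate <- example_ct_plate()
gene_ct_summary(plate)

panels <- hkg_panels()
panel_mean_ct(example_ct_plate(precise = TRUE), panels$nhkg_qpcr)
panel_mean_ct(plate, panels$thkg_qpcr)

loo_correlation(example_ct_plate(precise = TRUE))
```

The novel panel sits around 28.2 cycles with per-gene CVs of 5–9%, against
19.9 cycles and CVs of 8–11% for the traditional panel, and every novel
gene correlates at r > 0.96 with the mean of the other four — each member
is interchangeable with the panel consensus.

```{r screen-summary}
st <- example_panel_stats()
panel_summary(st, panels$nhkg_screen)
panel_summary(st, panels$thkg_screen)
```

## Synthetic data: what it emulates, and what it does not

`simulate_counts()` draws gene-wise negative-binomial counts with planted
labels: *stable* genes (overdispersion 0.005), *variable* genes (0.25) and
*zero-inflated* genes (per-sample dropout probability 0.3). The negative
binomial rather than Poisson is essential: its CV,
$\sqrt{1/\mu + \phi}$, is tunable through the overdispersion $\phi$
independently of the mean, so stability can be planted as a property of a
gene rather than of its expression level. For the same reason, per-gene
mean log2 expression is drawn uniformly on [6, 12]: below $\mu \approx
2^6$ the Poisson term $1/\mu$ dominates $\phi$ and a "stable" label would
no longer produce a stable realized CV. Defaults are fixed at 200 genes ×
8 samples (8 matching the cell-line panel the screen is designed around;
200 keeping a 100-replicate property suite inside seconds), with 5% stable
genes and 10% zero-inflated genes.

`simulate_ct()` converts expression to threshold cycles with the standard
log-linear qPCR response, $C_T = 40 - 1.6 \log_2 x + \varepsilon$,
$\varepsilon \sim N(0, 0.2^2)$ cycles. `simulate_interactome()` wires TF
hub nodes to a fixed number of partners over a sparse background, so the
co-regulation filter can be exercised end to end. One global seed derives
per-generator substreams, so counts, plates and interactomes are
independently reproducible.

The generators deliberately do *not* emulate: read-level sequencing noise
or mappability structure, between-gene expression correlation (each gene
is drawn independently), batch effects, or microarray intensity
distributions. Passing the recovery and concordance properties therefore
shows that the statistics behave correctly under the model the screen
assumes — not that real cohorts satisfy that model.

## Numerical choices and degenerate inputs

- CV is undefined for a zero-mean vector (error for a bare vector; `NA`
  plus an exclusion record inside the screen, where all-zero genes are an
  expected input).
- A zero-variance gene makes the leave-one-out correlation undefined:
  reported as `NA` with a message, never silently dropped.
- Equal maximal CDS lengths in an isoform group are resolved toward the
  lexicographically smallest isoform identifier, with a warning — the
  collapse must be deterministic.
- Quantile-normalization ties share the mean of the rank-means their
  positions span (the Bolstad-style convention). Quantile normalization is
  applied to linear (not log) expression values.
- `select_candidates()` with fewer than `k` eligible genes returns all of
  them with a warning rather than failing: a short list is a result.
- Simulated C_T values are truncated to stay positive; with the default
  intercept (40 cycles) truncation is never reached for expression below
  ~2^25.

## Known limitations

- With few genes (hundreds, as in test-scale simulations), quantile
  normalization pins any gene that occupies the same rank in every sample
  to identical values — an artificial CV of exactly 0. The planted-gene
  recovery checks therefore screen length/depth-normalized expression; at
  transcriptome scale (thousands of genes) the artifact affects at most a
  handful of extreme-rank genes.
- The screen's summary statistics reproduce published-style reference
  tables only to the precision of their inputs: statistics recomputed from
  values printed at two decimals can differ from statistics computed on
  the unrounded instrument values by about $0.01/\sqrt{n}$ in the mean and
  by a few thousandths in the SD. The bundled five-decimal plate removes
  this for the novel panel; for the traditional panel only two-decimal
  inputs exist.
- The co-regulation filter is only as good as the supplied edge list and
  alias map; it reports adjacency, not regulatory direction, and it cannot
  see co-expression without a physical interaction.
- Cohort validation treats samples as exchangeable; paired tumor/normal
  designs are summarized, not tested.
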