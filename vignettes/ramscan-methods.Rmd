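---
title: "Calling regions of altered methylation from enrichment sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling regions of altered methylation from enrichment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ramscan detects *regions of altered methylation* (RAMs) between exposure
groups from methylation-enrichment sequencing: libraries built by
methylation-dependent restriction digestion (MethylPlex/MeDIP-class
chemistry) in which the local density of aligned reads is a proxy for
methylated-CpG density. This vignette explains the statistical model, the
filters, every tunable that matters, what the synthetic-data generator
does and does not emulate, and the design choices made where the published
procedure left the details open.

## The count model

The genome is tiled into overlapping windows of `window_size` = 100 bp
every `window_shift` = 50 bp. A read contributes to the windows containing
its *anchor* — its leftmost aligned base — so each read is counted exactly
twice (once within the first 50 bp of a chromosome). Anchoring keeps the
per-read contribution constant, which makes total-count bookkeeping exact
and testable; an optional `read_extension` shifts the anchor toward the
fragment midpoint for sensitivity analysis and defaults to 0.

Windows with fewer than `min_reads` = 10 reads in at least
`min_sample_fraction` = 25% of samples (ceiling; 3 of 12) are removed:
these are regions contributing essentially no methylated-CpG signal to the
library.

For a retained window $w$, counts follow a negative binomial,
$y_{wj} \sim \mathrm{NB}(\mu_{wj}, \varphi)$ with
$\mathrm{Var} = \mu + \varphi\mu^2$ and
$\mu_{wj} = r_{w,g(j)} \, s_j$: a per-group mean rate times the sample's
effective library size. With four animals per group there is no
information for per-window dispersions, so a single genome-wide
**common dispersion** $\varphi$ is shared by all windows. Each pairwise
comparison is a likelihood-ratio test of the two-rate model against a
single shared rate, referred to $\chi^2_1$; the direction of a window is
the sign of $\log_2(r_B/r_A)$, with $B$ the exposed (or higher-dose)
group.

### Fitting details

The rate MLE given $\varphi$ solves
$\sum_j (y_j - \mu_j)/(1 + \varphi \mu_j) = 0$, whose left side is
strictly decreasing in $\log r$; we use safeguarded Newton iteration on
$\log r$ (steps clamped to $\pm 4$, tolerance $10^{-8}$, at most 50
iterations) started at the Poisson MLE, with means floored at $10^{-8}$ so
all-zero groups remain finite. At $\varphi = 0$ the fit reduces exactly to
the closed-form Poisson MLE, and the LRT to the Poisson LRT — one of the
test suite's oracles; the fit is also checked against a fine grid search
and against an independent GLM implementation at fixed dispersion.

The common dispersion maximizes the **Cox–Reid adjusted profile
likelihood** over a log-spaced grid on $[10^{-6}, 10]$ refined by
golden-section search (relative tolerance $10^{-4}$), with the per-group
means profiled out at each candidate and the adjustment
$-\tfrac12 \sum_g \log I_g$ subtracted ($I_g$ the observed information of
the group's log-rate). The unadjusted profile likelihood is available
(`adjust = FALSE`) but biased downward — with three nuisance means per
12-sample window it recovers roughly 0.145 when the truth is 0.2, while
the adjusted version recovers it nearly unbiasedly — so the adjustment is
the default. Beyond 20,000 windows the estimator subsamples evenly-spaced
rows; the dispersion is a genome-wide average and does not need more.

### What "scale invariance" means here

The test depends on library sizes only through the normalized rates:
multiplying *all* effective sizes by a constant changes nothing, and
normalized per-window means are invariant to scaling one sample's counts
together with its size. No count model can be invariant to rescaling one
sample's *counts* alone — counts are data, and $3y$ carries different
information than $y$ — so that stronger statement is not asserted or
tested.

## Library-size normalization

Raw per-sample totals are the baseline definition of the effective size.
The default, however, applies a trimmed-mean-of-log-ratios factor (30%
two-sided trim on log-ratios, 5% on average abundance, reference = the
sample with the median total) **computed on autosomal windows only**. The
reason is compositional: in a mixed-sex design, females place a visibly
larger share of their library on chrX (two copies) and none on chrY, so
raw totals deflate female autosomal rates — in the simulated 12-sample
design by about 17% — and any group with an unbalanced sex mix (the
high-dose group here is 1M/3F) acquires a systematic, direction-skewed
autosomal artifact. Restricting the factors to autosomes anchors scaling
where groups are comparable; computing them over all windows would be
dragged the wrong way by the chrX-heavy retained set. The sex-contrast QC
uses the same sizes, preserving code-path identity with the exposure
comparisons.

## From significant windows to RAMs

* **p-value gate.** Windows at raw $p < \alpha = 0.05$ are preliminary
  RAMs. No multiple-testing correction enters the calling chain (a
  Benjamini–Hochberg column is emitted for reporting): error control
  comes from the support and adjacency filters and is *audited* by the
  sex-contrast FDR bound below.
* **Per-sample support.** The published rule asks that the change be
  present in at least half the samples per group (at least two), without
  a formula. We operationalize "a sample shows the change" by the side it
  falls on relative to the midpoint of the two group medians of
  depth-normalized counts: threshold-free, robust to a single outlier,
  and equal to the intuitive reading for n = 4.
* **Adjacency.** A window keeps its call only if another preliminary RAM
  of the same comparison and direction starts within
  `adjacency_stretch − window_size` = 400 bp, so both fit inside one
  500 bp stretch; directly flanking windows (Δstart = 50 bp) are the
  tightest case. Published descriptions of this filter vary between a
  200 bp minimum span and a 500 bp stretch; the stretch is implemented
  as the operative rule and is configurable. Requiring the same direction is our
  addition: a region that is simultaneously hyper- and hypomethylated is
  not a coherent RAM.
* **Merging.** Overlapping or book-ended same-direction windows merge
  into regions (reported with window count and minimum p); window-level
  counts remain the primary unit of reporting.

## Annotation

Shores are the 0–2 kb flanks of merged CpG islands minus any island;
shelves the next 2–4 kb band minus islands and shores; both clipped to
chromosome ends, so islands, shores and shelves are pairwise disjoint by
construction. Windows are labeled by any ≥1 bp overlap at the precedence
CGI > shore > shelf (else *open sea*), mirroring the derivation hierarchy;
a per-base nearest-island classifier serves as the oracle in tests. Gene
context uses the precedence CDS exon > 5′UTR > 3′UTR > TSS-upstream 1 kb >
TSS-upstream 1–5 kb > intron > intergenic, strand-aware, with the TSS of a
minus-strand gene at its interval end; the TSS-proximity categories
(within 1 kb, and 1–5 kb, of a TSS) are taken as upstream flanks, which is
the reading this package commits to. Promoters are TSS ± 1.5 kb,
half-open, and a window keeps
every overlapping promoter assignment.

Context shares are compared with the library background as percent change
$100\,(p_{\mathrm{RAM}} - p_{\mathrm{bg}})/p_{\mathrm{bg}}$; the library
background is computed from the retained windows weighted by their total
read counts (a read-level background), and categories with zero
background are reported as undefined rather than infinite.

## Promoter dose–response classes

Promoters (unique TSS regions) are classified from the two
exposure-versus-control comparisons: response *gain* or *loss* by
direction, exposure class *UG_only*, *MG_only* or *both*; the low-dose-only
class is the non-monotonic signature. A promoter with both directions in
one comparison, or opposite directions between comparisons, is flagged
*mixed* and excluded from the six class counts (reported separately).
The third comparison (UG vs MG) does not enter the class scheme. The
heatmap view includes a promoter when one of its RAM windows has either a
group mean normalized count below the read floor scaled by the median
effective size (the pipeline's only stated read floor) or a ≥5-fold ratio
between two group means.

## The sex-contrast maximum FDR

Running the identical calling chain on a male-versus-female relabeling of
the samples yields windows that are either genuine sex differences
(chrX/chrY) or false positives (autosomes, to first order). The ratio
$100 \times \mathrm{autosomal}/(X + Y + \mathrm{autosomal})$ is therefore
an *upper bound* on the FDR of the exposure analysis run with the same
thresholds — true autosomal sex differences would only inflate it — and is
always reported as a bound, never as the FDR. A second QC asserts that no
chrY window is called hypermethylated in females, where coverage should be
background only.

## The synthetic-data generator

The generator emulates the study conditions end to end:

* **Genome**: ~6 Mb across two autosomes plus chrX (1.5 Mb) and chrY
  (0.5 Mb); CpG islands placed by a renewal process with 50 kb mean
  spacing and 300–1500 bp lengths; gene models with 2–6 exons, CDS and
  UTRs, TSSs biased toward islands.
* **Methylation landscape**: piecewise-constant on 500 bp tiles (the
  analysis works at 100 bp windows, so sub-window resolution would buy
  nothing), background level 0.25 with per-tile jitter (SD 0.015) —
  chosen so that a 3-fold planted increase stays inside $[0,1]$.
* **Planted truth**: 36 regions of 500 bp on autosomal island shores,
  cycling through hyper/hypo × monotonic/UG-only/MG-only at multiplier 3
  (the free effect-size parameter; 2–4× is the regime the power checks
  target). Monotonic effects put the low dose at the geometric midpoint.
  The truth table records the realized (tile-aligned) extent.
* **Reads**: tile sampling weight = group methylation level × CG-territory
  enrichment (2.3-fold inside islands ± 4 kb, the observed average
  CG enrichment of this library chemistry) × sex factor (chrX: female 2×;
  chrY: male-only with a 0.5% female background leak). 500,000 reads of
  80 bp per sample, with log-normal per-sample depth scatter (SD 0.1 in
  log10) to exercise normalization. Depth was set so that enriched-zone
  windows average ~17 reads per sample — above the pipeline's fixed
  10-read floor. This is a design requirement, not a free dial: at depths
  where typical windows sit below the floor, regions that *lose* coverage
  (hypomethylation, male-only chrY) can never be retained and the
  published filter would be degenerate rather than exercised, which is
  the regime the original deep-sequencing data was in.
* **Seeding**: one master seed; sample $i$ (0-based) draws from stream
  master + $i$, so any single sample can be regenerated alone.

What it does **not** emulate: fragment-length/insert-size structure,
sequencing error and base quality, mappability and repeat structure, CpG-
density variation *within* enriched territory, PCR duplicates, or
chromatin-driven coverage biases. Passing the recovery benchmarks
therefore shows the statistical chain behaves as designed under its own
assumptions — it does not certify performance on real libraries, where
normalization and dispersion are harder.

At the default conditions the pipeline recovers 100% of planted regions
with a direction-balanced false-window share of ~3–5% of final calls
(the remaining false calls are correlated-neighbor noise at the raw
p gate), the realized CG enrichment is within 15% of the configured
2.3-fold, the null type-I error at $\alpha = 0.05$ is ~0.05, and a known
dispersion of 0.2 is recovered to ~0.199 — these are exactly the
quantities the test suite and `scripts/acceptance.R` recompute.

## Numerical choices and degenerate inputs

* Means floored at $10^{-8}$; LRT clipped at 0; p-values from
  $\chi^2_1$, so $p \in (0,1]$.
* Dispersion grid $[10^{-6}, 10]$; identical constant columns drive the
  estimate to the lower bound.
* Terminal windows shorter than the shift are dropped (they duplicate the
  previous window's tail); truncated terminal windows ≥ the shift are
  kept, clipped.
* Ties in the support-filter midpoint test count for neither side.
* An empty landscape yields an empty read set with a warning; an empty
  read set writes a valid zero-line BED.
* Problem sizes in the tests (a ~2.6 Mb cached fixture at 150k reads per
  sample for module tests; the full ~6 Mb, 12 × 500k default for the
  end-to-end benchmark; 5,000-window simulations for calibration and
  dispersion recovery) were chosen as the smallest sizes at which the
  statistical properties under test are stable.

## Known limitations

Common dispersion ignores window-specific biological variability (no
tagwise/trended shrinkage, by design at n = 4); sex is not a model
covariate (matching the unbalanced published design — the autosome-anchored
normalization and the sex-contrast audit are the mitigations); the raw-p
calling chain leaves residual correlated false positives that the
adjacency filter cannot remove; and RAM counts at genome scale depend on
sequencing depth and genome size, so only depth-free summaries (shares,
percentages, calibration) are comparable across datasets.
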