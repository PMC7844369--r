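---
title: "Calling differentially methylated positions from two-channel array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated positions from two-channel array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clopidogrel resistance — high residual platelet reactivity under a standard
antiplatelet regimen — affects a substantial fraction of coronary
heart-disease patients, and known genetic variants explain only part of the
variability. One line of evidence implicates epigenetics: genome-wide DNA
methylation measured in whole blood differs between resistant and
non-resistant patients. methcall implements the complete analysis chain
such a case-control methylation study needs, from raw two-channel probe
intensities to called differentially methylated positions (DMPs),
genomic-context summaries, gene-set over-representation, and the targeted
validation statistics (pyrosequencing group comparisons, cohort
chi-squared tests, logistic odds ratios, qRT-PCR relative expression) used
to confirm individual loci.

Because raw array data for such cohorts is typically not redistributable,
the package pairs the pipeline with a first-class synthetic-data generator:
a seeded, desk-scale emulation of an 850K-style array with planted group
effects and a ground-truth table, so every stage is testable end to end.

## The model

### From intensities to beta- and M-values

Each probe on a two-channel methylation array reports an unmethylated
signal $A$ and a methylated signal $B$. The methylation fraction is

$$\beta = \frac{\max(B, 0)}{\max(A, 0) + \max(B, 0) + 100},$$

where the offset (default 100, configurable) stabilises low-intensity
probes, keeps the denominator positive, and bounds $\beta$ strictly below
1. Negative intensities occur in real data after background subtraction
and in our noise model by construction; the $\max(\cdot,0)$ guard is part
of the formula, not a data-cleaning step.

Processing follows the order: background correction (constant subtraction
truncated at zero), optional per-sample probe scaling of total intensity
(median $A+B$ to a common target; off by default because the upstream
scaling procedure in scanner software is vendor-specific), beta
computation, quantile normalization across samples, and the logit
transform to M-values,

$$M = \log_2 \frac{\beta'}{1-\beta'}, \qquad
\beta' = \mathrm{clip}(\beta,\ \varepsilon,\ 1-\varepsilon),$$

with $\varepsilon = 10^{-6}$ by default. M-values are the
variance-stabilised scale on which per-probe tests behave well; the log
base (2 or natural) is configurable and irrelevant to rank-based tests.
Quantile normalization acts on beta-values rather than per-channel
intensities: the processing order above places normalization after beta
computation, and normalizing the composite quantity is the simpler, more
common reading. Per-channel normalization is a legitimate alternative that
this package deliberately does not implement.

### Per-probe testing and calling

Each probe is tested case versus control with the two-sided Wilcoxon
rank-sum test on M-values. With $n_1 + n_2 \le 12$ and no ties the p-value
is exact (full enumeration of the rank distribution); otherwise the normal
approximation with midranks, tie-corrected variance and continuity
correction is used, and the mode is recorded. P-values are adjusted by
Benjamini–Hochberg over all tested probes. The effect size is
$\Delta\beta$ = mean case beta − mean control beta, so hypermethylation
means higher methylation in the resistant group.

The default calling rule is **raw p < 0.01 and $|\Delta\beta| \ge 0.2$**.
An "adjusted p < 0.01 and FDR < 0.05" mode is available
(`p_mode = "adjusted"`), but it cannot be the operative genome-wide rule
at the reference design of 6 vs 6 samples: the smallest attainable exact
rank-sum p is $2/\binom{12}{6} = 2/924 \approx 0.00216$, so after BH
adjustment over hundreds of thousands of probes no probe can reach 0.01
unless a large fraction of the array is differential. We therefore treat
the adjusted-p phrasing as descriptive, default to the raw rule (which
does reproduce sensible discovery behaviour), and keep both modes
implemented. Under the raw rule, the FDR cut is not additionally applied;
under the adjusted rule, both cuts act on the same BH quantity.

### Genomic context

Probes are annotated against CpG islands and gene models:

* **CpG context.** Distance is measured in bp from the probe position to
  the nearest island boundary: `island` (inside), `shore` (0–2 kb),
  `shelf` (2–4 kb), `open_sea` (further, or no island on the chromosome).
  Bins are closed on the right, so a probe exactly 2 kb away is a shore
  probe — the prose convention "0–2 and 2–4 kb" is ambiguous at the
  boundary and this package fixes one reading. Upstream and downstream
  (north/south) shores are collapsed into unsigned bins, since only the
  four classes are reported.
* **Gene regions.** Strand-aware bands in the Illumina vocabulary:
  `TSS200` (0–200 bp upstream of the TSS), `TSS1500` (201–1,500 bp),
  `1stExon`, `5UTR` (exonic between TSS and CDS start, outside the first
  exon), `3UTR` (exonic past the CDS end), `Body` (anything else inside
  the transcript). When several bands apply for one gene the precedence
  TSS200 > TSS1500 > 1stExon > 5UTR > 3UTR > Body makes the label unique
  per (probe, gene). A probe overlapping several genes keeps all its
  (gene, region) pairs, and region distributions count one contribution
  per distinct annotation — this multi-annotation counting rule is what
  makes published region percentages with denominators larger than the
  probe count internally consistent.
* **Coordinates.** BED intervals are 0-based half-open; probe positions
  are 1-based. The conversion lives in one internal routine.

### Gene-set over-representation

Differentially methylated genes (deduplicated from probe annotations) are
tested against locally supplied GMT gene sets with the one-sided
hypergeometric tail: for a set with $K$ members in a background of $N$
genes and a query of $n$ genes with $k$ hits,

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n), \qquad
\text{fold} = \frac{k/n}{K/N}.$$

FDR is BH over all sets tested. The EASE-style penalty (scoring $k-1$
hits) is available behind a flag but off by default — plain hypergeometric
is the cleaner default and published tables cannot adjudicate the choice
when the background is unknown. The background defaults to the union of
all set members unless a universe is supplied. The analysis is strictly
offline: no database queries, gene sets come from files.

### Validation statistics

* `pooled_t_test()` computes Student's t from group summary statistics
  (mean, SD, n). The pooled-variance form is the default because it
  reproduces published pyrosequencing p-values at printed precision where
  the Welch variant rounds differently; Welch is available by flag.
* `chi2_2x2()` is the Pearson chi-squared without continuity correction —
  again the form consistent with published cohort tables.
* `logistic_fit()` wraps an IRLS binomial GLM (tight tolerance, max 50
  iterations) with a divergence guard that rejects separation, and
  `tidy()` reports the Wald chi-squared $(\hat\beta/\mathrm{SE})^2$ and
  odds ratio $e^{\hat\beta}$ per term.
* `relative_expression()` implements $2^{-\Delta\Delta C_t}$ with
  replicate averaging and a housekeeping reference. The calibrator
  defaults to the mean control-group $\Delta C_t$ (no calibrator sample is
  assumed), so control samples centre on a relative expression of 1.

## The synthetic-data generator

`synth_config()` fixes the study conditions; its defaults are the
package's reference design and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 20,000 | desk-scale stand-in for an ~850K array |
| `chromosome_lengths` | 22 autosomes, human-proportional | 1/100-scale bp lengths |
| `n_samples_per_group` | 6 | the discovery design (6 resistant vs 6 control) |
| `frac_dmp` | 0.05 | fraction of probes with planted effects |
| `hyper_fraction` | 0.14 | planted share hypermethylated (hyper:hypo ≈ 0.16) |
| `effect_delta_beta` | 0.35 | target planted \|Δβ\|, middle of the 0.3–0.4 band |
| `beta_shapes1/2` | (0.5, 8), (8, 0.5) | equal-weight Beta mixture, bimodal baseline |
| `intensity_scale` | 10,000 | expected A + B |
| `noise_sd` | 300 | Gaussian channel noise (may drive intensities negative) |
| `background_level` | 200 | additive channel background |

Baseline betas come from the bimodal mixture (most probes nearly un- or
fully methylated, as on real arrays). Planted probes shift the case-group
mean by a probe-specific logit-scale offset chosen so the beta-scale
difference equals `effect_delta_beta`, clipped to [0.01, 0.99]; baselines
that cannot carry the full shift are re-drawn (at most 100 retries) so the
ground-truth table has exact planted effect sizes. The hyper/hypo split of
planted probes is deterministic (`round(hyper_fraction * n_dmp)`), which
pins the planted ratio exactly rather than binomially. Intensities are
$B = \text{total}\cdot\beta + \text{background} + \mathcal N(0,\sigma)$
and symmetrically for $A$. No published noise model exists for this
setting; this one is the package's own and is deliberately minimal.

What the generator does **not** emulate — dye bias, Infinium type I/II
probe chemistry, batch effects, SNP-affected probes, missing values,
cell-type composition. Tests that pass on this generator therefore
certify the statistical machinery (calling rules, error control, context
accounting) on clean bimodal data, not the preprocessing robustness a
real-data workflow (minfi-style QC, BMIQ/SWAN, detection p-values) would
need. Those steps are explicit non-goals.

## Numerical choices and degenerate inputs

* Exact zeros in beta (a probe with $\max(B,0)=0$) are common under the
  noise model; after clipping, M-values tie at the bounds. Tied rows use
  the midrank approximation, and a row in which every observation is
  identical is assigned p = 1 (the zero-variance normal approximation is
  undefined; identical multisets carry no evidence).
* Quantile normalization resolves ties by assigning the average of the
  reference distribution over the tied span. On tie-free data it is
  exactly idempotent and makes all per-sample sorted vectors identical;
  with ties both properties hold up to the tie-averaging, which is the
  standard behaviour of the underlying limma implementation.
* `bh_adjust(p, m_total)` supports a family size larger than the supplied
  vector, treating the supplied values as the smallest members of the
  family. This is how a printed top-k table can be re-adjusted against its
  original (unprinted) test family; a family size of 256 reproduces the
  five published pathway FDRs from their p-values simultaneously, and a
  query size of 1,167 reproduces all five published list-fraction
  percentages — both derivations are frozen into the test suite.
* The logistic guard declares divergence when the fit fails to converge
  or a slope exceeds 15 on the logit scale (odds ratios beyond $e^{15}$
  are not meaningful in cohort data and indicate separation).
* `generate_manifest()` raises a sizing error naming the chromosome when
  requested islands cannot be placed without overlap.

## Problem sizes used by the test suite

Unit and property tests run on generated fixtures of a few hundred to a
few thousand probes; the end-to-end recovery checks use the full reference
design (20,000 probes, 6 vs 6, 5% planted effects), chosen as the
package's reference conditions for recovery claims: at that size the
planted-effect sensitivity of the default rule is expected above 0.9 with
empirical FDR near 0, and a null run (no planted effects) calls nothing,
because the $|\Delta\beta| \ge 0.2$ filter dominates the raw-p rule under
the noise model.

## Known limitations

* Region-level analysis (DMRs, bump hunting), covariate-adjusted models
  and cell-type deconvolution are out of scope.
* Missing values are not modelled; matrices must be complete.
* The enrichment module reproduces over-representation arithmetic only;
  published pathway p-values and folds additionally depend on an
  unpublished background universe and cannot be reproduced exactly, so
  only the internally consistent columns (list fractions, FDR-from-p) are
  asserted.
* Published qRT-PCR group p-values are not reproducible from their
  printed summaries with any standard t-test form; the package computes
  the pooled t for such comparisons but does not assert those values.
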