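---
title: "Normalising heterogeneous common-reference two-colour microarray datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalising heterogeneous common-reference two-colour microarray datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloess)
```

## The problem

In a common-reference two-colour design every array hybridises a sample of
interest against the same reference — typically genomic DNA, whose signal is
high and roughly flat across features. Any two arrays are then comparable
through the shared channel: for per-array log-ratios
$L = \log_2(R/G)$ (signal over reference), the expression log-ratio between
two conditions is $M = L_1 - L_2$ and the mean log intensity is
$A = (L_1 + L_2)/2$.

Compendia of such data accumulated over years are *heterogeneous*: mixed
image-analysis formats (GenePix GPR, BlueFuse), several array layouts,
accidental or deliberate dye swaps, and strongly discordant spreads of
log-ratios between arrays (often tracking RNA quality). Ordinary loess
normalisation cannot be applied to a single common-reference array — with a
flat reference channel, M and A are intrinsically correlated — and
layout-bound toolchains struggle with mixtures of formats and layouts.

`cycloess` normalises such a dataset in one pass:

1. **Background correction** (GenePix): median background subtracted from
   median foreground per channel. BlueFuse output is already corrected by
   its software and passes through.
2. **Exclusions**: vendor flags (−50/−75/−100, or quality `E`), blank or
   control names (`EMPTY`, `ctrl-`…), and a statistical background filter —
   a spot is kept only when, in both channels, its raw foreground exceeds
   background by at least `k_sd` background standard deviations
   (default 3, i.e. ~99.73% confidence that signal is above background).
3. **Reference-channel detection**: the reference channel has the higher
   median intensity on every array, so comparing channel medians over the
   surviving spots assigns roles per array and makes dye swaps transparent.
4. **Block-by-block median centering**: $L$ is computed per spot and each
   block's (print-tip group's) median is set to zero, on the assumption
   that most genes are unchanging; the block structure is read from the
   files themselves, so no layout (.gal) file is needed.
5. **Duplicate averaging**: multiple spottings of a feature are averaged so
   each feature appears once per array.
6. **Cyclic loess**: for every unordered pair of arrays $(a,b)$ a loess
   trend is fitted to the MA-scatter of the shared features and subtracted:
   $N_{ab} = M_{ab} - \mathrm{loess}(A_{ab})$. The reverse orientation is
   $N_{ba} = -N_{ab}$ by definition, never refitted. $k$ arrays mean
   $k(k-1)/2$ fits.
7. **Averaging**: the value of feature $f$ on array $a$ is the mean of
   $N_{ab}(f)$ over the $n$ pairs in which $f$ was present on both arrays;
   a cell with $n = 0$ is `NA` — including a feature measured on $a$ but
   shared with no other fitted array.
8. **Final centering**: each array's median is subtracted, returning the
   majority of features to $M = 0$.

Steps 3, 6 and 8 can be disabled (`auto_reference`, `do_cyclic_loess`,
`do_final_centering`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_sd` | 3 | background-filter width, in background SDs; larger is stricter |
| `span` | 0.3 | fraction of shared features in each local loess estimate |
| `robust_iterations` | 3 | bisquare re-weighting passes of the local fit |
| `min_pair_size` | 10 | smallest feature intersection worth a loess fit |
| `empty_name_patterns` | `EMPTY`, `empty`, `ctrl-`, `Ctrl-` | blank/control name rules |

Patterns ending in `-` match as prefixes, others exactly; the choice matters
because "names like" these vary between facilities, so the list is
configurable rather than guessed. The background filter compares *raw*
foreground with background (the two directly measured quantities), fails a
spot if *either* channel fails, and is monotone in `k_sd`. Results vary
smoothly with `span` in the 0.2–0.5 range (tested); 0.3 balances trend
flexibility against variance for the few thousand shared features typical
of these arrays.

## Numerical choices

- The local regression is degree-1 with tricube weights over the
  span-fraction nearest neighbours and bisquare robustifying passes
  (`stats::lowess`, evaluated exactly at every point, `delta = 0`). Fitted
  values are mapped back to input order; tied abscissae receive a common
  fitted value, so results do not depend on input order.
- When the non-robust fit already interpolates the data to within rounding
  (residuals below `1e-10 · max(1, max|y|)`), the robustifying passes are
  skipped: with all residuals at rounding level the bisquare weights would
  be driven by numerical noise and can destabilise the fit. This guard is
  what makes the smoother exact on affine trends at any
  `robust_iterations`.
- All-equal abscissae fall back to the constant `mean(y)`.
- Pairs are always fitted in canonical orientation (lexicographically
  smaller array ID first) and per-array contributions are accumulated in
  sorted-partner order, so antisymmetry $N_{ab} + N_{ba} = 0$ holds by
  construction and the output is invariant, bit for bit, to the order in
  which files are supplied.
- Medians use the standard convention (mean of the two central order
  statistics for even counts). After centering, an odd-count median is
  exactly 0; an even-count median is 0 to within one ulp of the data
  magnitude (~1e-18 in practice), which is what the tests assert.
- Written matrices render values with `%.17g` and missing cells as the
  literal `NA`, so a write–read cycle is bit-exact.

## What the simulator emulates — and what it does not

`sim_config()`/`simulate_dataset()` generate two-colour common-reference
datasets with known truth, written as valid GenePix and/or BlueFuse files.
The default sizes follow the standard simulation design for this setting:
6 arrays, 5000 genes, 4 × 4 blocks (dealt row-major, block sizes differing
by at most one when counts do not divide evenly).

The generative model: per-feature baseline $e_f \sim N(-2, 1)$ on the
log2 signal/reference scale — the negative mean keeps the reference channel
brighter, as the design assumes; reference intensities flat around
`reference_level`; signal = reference × $2^L$ with
$L = s_a\,(e_f + \delta_f + \varepsilon)$, per-spot noise
$\varepsilon \sim N(0, 0.4)$; and DE features shifted by
$\pm$`de_log2fc` in the second group, half up and half down so the
majority-unchanged assumption stays symmetric. GenePix renderings add
rounded backgrounds to the foregrounds (so correction recovers the signal);
BlueFuse renderings carry corrected amplitudes, mirroring that software.

Three pathologies make the `"problem"` preset:

- **Scale heterogeneity**: per-array multipliers $s_a$ spread over 0.5–1.8.
- **Curvature**: a quadratic distortion
  $c_a\,(A - \bar A)^2$ added to $L$, with $c_a$ spread over
  ±`curvature_coeff`; differing $c_a$ produce the banana-shaped pairwise
  MA-trends that the loess step removes. The quadratic also skews each
  array's log-ratio distribution, which is deliberate: the preset's
  asymmetry comes from intensity-dependent *systematic bias*, the kind of
  skew a between-array method can and should remove. (`skew_coeff` instead
  injects iid asymmetric noise, which no normalisation should absorb — it
  is off in the presets.)
- **Balanced allocation**: $s_a$, $c_a$ (and any skew strengths) are
  assigned mirror-symmetrically across the array series, so under the
  default first-half/second-half group split both experimental groups see
  the same spread of technical distortions. Technical artifacts in a real
  compendium are not aligned with the biology; confounding them with the
  group split would bias any normalisation comparison.

What the simulator does *not* emulate: spatial (within-block) gradients,
print-tip-specific trends beyond block offsets, saturation, correlated
spot morphology, or channel-specific dye chemistry. Passing tests therefore
demonstrate correct behaviour under scale/curvature/skew heterogeneity with
flagged, duplicated and layout-restricted spots — not robustness to every
artifact of real slides.

## Evaluation harness

`evaluate_detection()` runs per-feature pooled-variance two-sample t-tests
with Benjamini–Hochberg control. It reports the conventional quantities
(power = TP/#DE, type-I error = FP/#null, FDR) *and*, explicitly labelled,
an alternative bookkeeping used in some normalisation benchmarks that calls
$1 - \mathrm{FDR}$ "power" and the false-negative rate "type I error".
Neither is silently converted into the other.

Operating points used by the property tests (all generated in code at test
time): the null-calibration check uses 6 arrays × 300 genes over 20 seeds;
the power-ordering check (cyclic loess versus no between-array step) uses
8 arrays (4 + 4) × 500 genes with 100 DE features at |log2FC| = 2, because
an unmoderated t-test with 3 + 3 arrays has essentially no BH-adjusted
power at α = 0.05 for *any* normalisation, which would make the comparison
uninformative. At the 4 + 4 operating point the cyclic route reaches ~0.5
power with type-I below α while the no-between-array route stays near zero
— scale discordance acts as pure noise once it cannot masquerade as signal.

## Design choices where the field leaves room

- **Background filter formula**: "foreground within `k` SDs of background"
  is read as $F < B + k_{sd}\,\mathrm{SD}(B)$ per channel, using the
  file's background-SD column; this matches the 3-SD/99.73% confidence
  reading and the data available in GPR files. The filter applies to
  GenePix only (BlueFuse files carry no background fields).
- **Order of steps**: blocks are centred before duplicates are averaged
  (step order 4 then 5); duplicate spots may sit in different blocks, and
  centering first uses each spot's own print-tip context.
- **Feature identity** is the verbatim, whitespace-trimmed, case-sensitive
  name; no further normalisation of gene names is attempted.
- **Channel order** in GPR files follows the header: channel 1 is the
  first `F<wavelength> Median` column encountered, whatever the
  wavelength naming (532/635, Cy3/Cy5, …).
- **Minimum pair size** 10: a loess fit through fewer shared features is
  meaningless; such pairs are skipped with a log entry and contribute no
  comparisons (their features can still be `NA` under the n = 0 rule).
- **Skewness estimator**: moment coefficient $g_1 = m_3 / m_2^{3/2}$
  without small-sample correction; quartiles by linear interpolation of
  order statistics (`type = 7`), documented because outlier sets depend on
  the convention.

## Known limitations

- Cyclic loess costs $k(k-1)/2$ fits; for hundreds of arrays a faster
  approximate scheme would be needed.
- A feature present on only one array of the dataset is reported `NA`
  everywhere (the n = 0 rule taken literally), even though that array
  measured it.
- The t-test harness is deliberately simple; it is an evaluation yardstick
  for the simulator, not a recommended analysis for real data (moderated
  statistics are preferable at these sample sizes).
- Missing-value imputation and downstream significance analysis are out of
  scope; the output matrix (with explicit `NA`s) is the hand-off point.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(n_arrays = 4, n_genes = 500,
                                   preset = "problem", seed = 1,
                                   formats = "mixed"),
                        dir = "simdata")
run <- run_pipeline(sim$files, output_path = "expression_matrix.tsv",
                    emit_diagnostics = TRUE, diagnostics_dir = "diag")
print(run)
distribution_stats(run$stages$block_centred)  # before the between-array step
distribution_stats(run$stages$cyclic_loess)   # after
```

The per-array standard deviations converge across the cyclic step and each
array's median is exactly zero in the final matrix; `diag/` holds the
per-stage Tukey boxplot numbers, the per-array sd/skewness table, the
pairwise fit log and the exclusion tallies as TSV.
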