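---
title: "Methods: waveform features and expression analysis of androgen-induced EOD elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waveform features and expression analysis of androgen-induced EOD elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eodkit)
```

## The measurement model

A pulse-type mormyrid electric organ discharge (EOD) is a millisecond-scale
biphasic voltage transient: a head-positive phase P1 followed by a
head-negative phase P2 that recovers exponentially toward baseline. All
waveform quantities in this package are defined on a *preprocessed* pulse:

1. per snippet, subtract the pooled mean of the first and last
   `baseline_window` (default 512) samples — with equal windows the pooled
   mean equals the mean of the two window means, so either reading of
   "average of the first and last 512 points" gives the same number;
2. divide by the peak-to-peak amplitude;
3. align at the maximum head-positive voltage (vP1), assigned time 0;
4. average the aligned snippets sample-wise and re-normalize.

Averaging before measuring is part of the protocol, not a convenience: the
default synthetic noise (0.005 normalized units) is deliberately placed *at*
the 0.5 % detection threshold, and a single raw snippet can false-trigger
the three-consecutive-samples start rule, while an average of ~10 snippets
pushes the false-trigger probability to ~1e-8.

The measured parameters, with units:

| parameter | definition | unit |
|---|---|---|
| EOD duration | `t_end − t_start` from the threshold rules | ms |
| P1 / P2 duration | split at the interpolated P1→P2 zero crossing | ms |
| P1–P2 delay | `t(vP2) − t(vP1)` | ms |
| vP2/vP1 | amplitude ratio (negative for any biphasic pulse) | — |
| sP1 | maximum central-difference slope on `[t_start, t(vP1)]` | norm./ms |
| τ | rate constant of `y = a·e^(−τ(t − t_vP2)) + b` fitted on `[t(vP2), t_end]` | 1/ms |
| vP1, vP2 | normalized extrema (`vP1 − vP2 = 1`) | — |

Detection rules (defaults in `detection_config()`): the threshold is 0.5 %
of peak-to-peak; the start is the first sample of the first three
consecutive samples exceeding the threshold *in absolute value* (the
absolute-value reading costs nothing for the canonical P1-positive pulse
and keeps pulses with a small initial negativity detectable); the end is
the first sample at or after the vP2 sample whose trailing 11-point mean
voltage exceeds the negative threshold, scanning forward from vP2 (the rule
describes the tail's return to baseline after P2, so that is where the scan
starts). The zero crossing is linearly interpolated between the bracketing
samples; sub-sample precision is free and stabilizes the P1/P2 split.

## The synthetic pulse and its closed-form truth

The generator (`simulate_eod_snippet()`) is *not* an electrocyte membrane
model. It is built so that every measured quantity has a closed form:
P1 is a raised-cosine bump `a1·cos²(π(t−t1)/(2w1))` on `[t1−w1, t1+w1]`,
the P2 falling edge is a raised-cosine on `[t2−w2, t2]`, and for `t ≥ t2`
the tail is exactly `−a2·e^(−τ(t−t2))`, continuous at the minimum. Phases
may not overlap; with adjacent supports the zero crossing is exactly
`t1 + w1`. Threshold crossings solve in closed form, including the
*windowed* end rule: the trailing mean of a recovering exponential crosses
the threshold later than the trace itself by `log(G)/τ`, where `G` is the
geometric window factor; `pulse_truth()` reports both `t_end_threshold` and
the rule-based `t_end_rule`, and defines `duration` from the latter —
truth means "what an ideal detector applying the stated rules would
measure", so noise-free detection matches truth to within one sample.

Defaults are the untreated-fish operating point: normalized amplitudes
0.41/−0.59, τ = 31.06 per ms, sampling 250 kHz with 2048-point snippets,
and phase widths calibrated so the detected duration is 0.68 ms. The
published full parameter table could not be matched in its entirety: its
P1/P2 durations (~0.03–0.09 ms) cannot sum to its EOD durations
(0.68–1.35 ms) under the stated definitions, so the generator reproduces
the self-consistent subset (duration, τ, vP1/vP2) and leaves P1/P2
duration, delay and sP1 to follow from the pulse shape. sP1 is reported in
normalized units per ms; no attempt is made to match the unstated published
unit.

## Cohorts and the elongation trajectory

`simulate_cohort()` reproduces the study structure: control n = 6 (days
0–8), T1day n = 7 (days 0–1), T8day n = 7 (days 0–8), 10 snippets per fish
per day. Androgen response is a time-axis dilation: widths and phase
spacing scale by `k`, τ by `1/k`, with `k` ramping linearly from 1.0 at day
0 to 1.96 at day 8 for T8day fish only (T1day fish are sampled before
their waveform responds, matching the observed non-response at day 1).
With the windowed end rule the deterministic T8day endpoint is ~1.31 ms —
about 3 % under the naive 0.68 × 1.96 = 1.33 because the stretched tail's
windowed crossing does not scale perfectly linearly; both are inside the
5 % band any test applies. Between-fish variability scales the whole time
axis (CV 0.19, the ratio of the published day-0 s.d. to its mean),
day-to-day jitter has CV 0.02 (inside the < 5 % acclimation criterion),
and per-fish vP1 varies with s.d. 0.03.

## Group statistics

The acclimation rule is a *trailing* window (the five most recent days),
consistent with a stopping rule applied during acclimation; CV uses the
sample standard deviation (the protocol text does not say which; the
difference is a factor `sqrt(n/(n−1))` on a 5-point window and does not
change any decision at the 5 % criterion). Between-treatment inference is
the classical two-stage protocol: one-way ANOVA at day 0 and at the last
treatment day, followed by Tukey HSD where the ANOVA is significant.
Tukey–Kramer adjusted p-values come from the studentized range distribution
(`stats::ptukey`, itself a numerical integration accurate far beyond the
1e-6 we require); the compact letter display uses the standard
insert-and-absorb algorithm, so groups sharing no letter differ at α.
Degenerate inputs are defined, not errors: zero within-group variance with
equal means gives F = 0, p = 1.

## Differential expression

The in-package DE test is an explicitly labelled stand-in, not a negative
binomial GLM: genes are TMM-normalized (Robinson–Oshlack: reference =
sample whose upper-quartile count fraction is closest to the mean; 30 %
two-sided trim on M, 5 % on A; precision-weighted mean; factors rescaled to
geometric mean 1), expression is `log2(CPM + 0.5)`, and per-gene Welch *t*
tests give p-values with Benjamini–Hochberg FDR. Externally produced
per-contrast tables (gene, log2fc, pvalue) drop into every downstream stage
unchanged. Orientation is fixed throughout: positive log2 fold change means
up with *longer* 17αMT exposure. Significance uses fold change ≥ 4
(boundary inclusive — "a minimum fold change of 4") and FDR < 0.001
(strict, as printed). The expressed-gene rule for DE is "nonzero in at
least half the contrast's samples"; the published per-contrast expressed
counts imply some per-contrast filter but not its rule, so this default is
configurable. Pattern classification maps each gene's (broad, early, late)
call triple to one of 27 deterministic labels; a conflict flag marks the
two triples where the broad direction opposes both granular directions.
Reported percentages use half-up rounding (244/20,887 → 1.17).

## Enrichment

Each contrast's full (unfiltered) DE table is reduced to a directional
score `d = sign(log2fc)·(−log10 p)` — the multi-contrast rank approach
accepts any directional statistic; this choice is documented and the
p floor is 1e-300. Per contrast, `d` is rank-transformed (ties mid-ranked)
and a set's enrichment is `s = 2·(mean member rank − (N+1)/2)/N`, which has
range `(−1, 1)` and attains `±(N−m)/N` at the top/bottom-m set; the
higher-dimensional score is `S = ||(s_broad, s_early, s_late)||₂`, so `S`
is invariant to contrast relabelling and `S ≥ max|s|`. Significance is a
two-group MANOVA of the scaled ranks (members vs background): with two
groups Pillai's trace is a monotone function of Hotelling's T², whose
F transform is exact, so the p-value is computed through T²; a singular
pooled covariance falls back to per-contrast Welch *t* with Bonferroni
min-p. Sets are intersected with the profile universe *before* the size
filter (m is the intersected size, minimum 20). Enriched sets require
FDR < 0.01 and S > 0.1. The select-set rule — the published criterion is
only "an important change in enrichment magnitude and direction before and
after day 1", with details in an external repository — is declared here as
`|s_early − s_late| ≥ delta` (default 0.1), with an optional strict
sign-change flag.

## Candidates

Candidates are `(select-set members ∩ genes significant in ≥ 1 contrast) ∪
(manual additions ∩ significant genes)`; exclusions are applied to the
*resulting* list (so a manually added early-only gene is still removed):
genes significant only in the early contrast do not track the phenotype
(duration barely changes by day 1), and blacklisted genes (e.g. an enzyme
that converts the administered androgen itself) are removed outright.
Manual picks are an input list — the published manual curation is
annotation-driven and not algorithmic — and themes attach from a
user-supplied map.

## What the generators do and do not establish

The count simulator plants early (effect in both treated groups), late
(T8day only) and broad (full effect in T8day, half in T1day — mirroring the
observation that most expression change had materialized by day 1; the
fraction is configurable) genes on a log-normal abundance background with
common NB dispersion 0.05 and 2e7-read libraries. The gene-set simulator
builds null sets uniformly and planted sets preferentially from planted
genes of the designated sign. A green test therefore establishes that the
pipeline recovers *planted, independent, homoscedastic* signal at the
stated thresholds; it says nothing about gene–gene correlation, batch
structure, dispersion heterogeneity or annotation error in real data, and
the stand-in Welch test is not an edgeR replacement (its p-values are
anti-conservative for very low counts).

## Numerical choices and known limitations

* The τ fit initializes from a log-linear regression assuming b = 0 and
  uses the `port` algorithm with τ bounded positive; non-convergence sets a
  flag rather than erroring. On noise-free synthetic decay samples the fit
  is exact to < 1e-6 relative.
* τ measured on full noisy averaged pulses is biased low (~20 % at the
  default noise): under noise the detected minimum wanders onto the flat
  cosine shoulder just before the true trough, so a few pre-exponential
  samples flatten the head of the fit window. The bias is approximately
  multiplicative and cancels in treatment comparisons (the simulated
  T8day/control τ ratio is preserved); absolute τ from single noisy
  cohorts should be read with that caveat.
* Offset and positive scaling of raw samples change no feature; the
  detector-based features are bit-stable under these transforms, τ is
  stable to the optimizer tolerance (~1e-7).
* The end-to-end treatment-separation property (no pair at day 0, T8day vs
  both at the last day, control vs T1day never) sits near its nominal
  error budget by construction: day-0 family-wise error alone spends 5 %
  of the 95 % success requirement, which is why the ANOVA-gated two-stage
  protocol (slightly conservative) is used, as in the original analysis.
* Configuration files are JSON (no YAML parser is assumed); all thresholds
  validate against documented domains with errors naming the key.
* Per-stage seeds derive from the master seed by fixed offsets, so stages
  are independently reproducible; identical seeds give byte-identical TSV
  outputs.
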