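---
title: "Quantifying sequential emotion in dream reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sequential emotion in dream reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamsent)
```

## The model

dreamsent treats a dream report as a one-dimensional signed signal: every
word carries a continuous valence rating, and the emotional course of the
dream is the trajectory of that signal in narrative order. The pipeline
has five stages, each a pure function from tabular input to tabular
output.

**Scoring.** Tokens are lowercase maximal runs of letters with internal
apostrophes; digits and punctuation are dropped, so the token count is the
report's word count. Each token is looked up in a sentiment lexicon whose
mean ratings live on a native scale (±4 for VADER-format files) and
divided by the scale maximum, giving values in [−1, 1]; absent tokens are
neutral (0). Normalizing by the scale maximum makes downstream areas
lexicon-independent. Two modes exist because word-level exports of
sentence-level sentiment tools are ambiguous about context handling:
`lexicon_only` (the default) is a pure per-token lookup — deterministic,
order-independent, and the mode all guarantees below are stated for —
while `vader_heuristics` additionally applies the published negation
scalar (−0.74) and booster increments (±0.293, damped by 0.95 and 0.9 at
distances 2 and 3) within a trailing 3-token window. Sentence-level
capitalization and punctuation emphasis are deliberately not applied in
either mode: they have no well-defined word-level meaning.

**Windowing.** The valence series is divided into windows of
`window_length = 30` tokens overlapping by `overlap = 29` (stride 1), and
each window's sum is divided by the report's window count
$W = \max(1, L - 29)$:
$$y_k = \frac{1}{W}\sum_{i=k}^{k+29} v_i .$$
This per-report normalization controls for word-count differences between
dreams and lifts the flattening effect that long neutral stretches have on
peak and trough areas. The divisor is configurable
(`n_windows`, `window_length`, `none`) because the count-based reading —
the one that actually depends on report length — is the one consistent
with that purpose; the plain moving average is retained for comparison.
Reports shorter than one window collapse to a single whole-report window,
the least surprising degenerate rule for a method whose intended inputs
are 46 words or longer.

**Segmentation.** Peaks are maximal runs of $y > 0$, troughs of $y < 0$,
each bounded by zero values. Two boundary situations the zero-bounded
definition leaves open are resolved as continuous extensions: where
consecutive points flip sign with no intervening zero, a synthetic
boundary is interpolated at the linear zero crossing (windowed sums almost
never hit zero exactly, and interpolation preserves area additivity); and
excursions truncated by the chart edges still count, since real charts
begin and end mid-emotion. Values with $|y| \le$ `eps` (default $10^{-12}$,
sized for floating-point noise in the window sums, not a smoothing
parameter) are treated as exact zeros. A single positive or negative value
is a legitimate one-point excursion.

**Indicators.** Each segment's approximated area under the curve (aAUC)
is the trapezoid rule over its points including the boundary zeros,
$\sum_i (x_{i+1}-x_i)(y_i+y_{i+1})/2$, with unit spacing between chart
positions (the chronological axis is uniform and its units cancel in
correlations). The six per-dream indicators are Total Peaks, Total
Troughs, $\mathrm{PEI} = \sum_{\text{peaks}} \mathrm{aAUC} \ge 0$,
$\mathrm{NEI} = \sum_{\text{troughs}} \mathrm{aAUC} \le 0$,
$\mathrm{OEI} = \mathrm{PEI} + |\mathrm{NEI}|$ (absolute values so trough
intensity adds rather than subtracts), and the emotion gradient below.
Both intensity sums are zero when the corresponding excursions are absent.

**Trend.** Dream charts typically oscillate, so a polynomial rather than
a straight line is fitted by least squares (QR on a centered Vandermonde
basis). The polynomial degree is a free choice; the default of 2 is the
lowest degree that can express a rise-and-fall arc, and it is
configurable. A polynomial has no single slope, so the scalar
"emotion gradient" is defined as the mean slope over the chart's domain,
$(p(x_W) - p(x_1)) / (x_W - x_1)$: it is the unique scalar that reduces to
the line's slope in the linear case and negates when the chart is negated.
The plain degree-1 slope is reported alongside for comparison.
$R^2 = 1 - SS_{res}/SS_{tot}$ is defined as 1 when $SS_{tot} = 0$. Charts
with fewer than degree + 1 points get a degenerate linear fit and
`eligible = FALSE`; beyond that, no chart is excluded automatically —
suitability judgments are left to the analyst via the configurable
`r2_floor` (default 0), since no operational exclusion rule is part of the
method.

**Validation.** Indicators are correlated with external sleep, state, and
trait variables (e.g., REM%, awakenings, overnight percentage change in
positive affect computed as $100(m - e)/e$, personality scores). The
protocol is Spearman's ρ when the pair is tie-free and Pearson's r when
ties are present; "ties present" is read as any duplicated value within
either vector of the pair (the most literal reading; a within-both policy
is available). Spearman p-values use the exact permutation distribution
where available (tie-free, moderate n) and the t approximation otherwise.
Missing values are deleted listwise per pair. p-values are uncorrected by
default, matching the exploratory pilot protocol; Holm and
Benjamini–Hochberg adjustments are available but off.

## Parameters at a glance

| parameter | unit | default | why |
|---|---|---|---|
| `scale_max` | lexicon rating | 4 | VADER convention; normalizes to [−1, 1] |
| `window_length` | tokens | 30 | the method's window |
| `overlap` | tokens | 29 | stride 1; maximal smoothing at this window |
| `normalizer` | — | `n_windows` | per-report length control (see above) |
| `eps` | chart units | 1e−12 | float noise floor around zero |
| `degree` | — | 2 | lowest degree with a rise-and-fall shape |
| `r2_floor` | — | 0 | no automatic chart exclusion |
| `alpha` | — | 0.05 | edge list threshold, uncorrected |
| `tie_policy` | — | `either` | literal tie rule |

## What the synthetic generator emulates — and what it does not

The generator plants known structure: scripts of neutral, positive, and
negative token runs with chosen amplitudes are realized from a toy lexicon
of synthetic letter-only tokens whose valences are exact (neutral fillers
are deliberately absent from the lexicon, exercising the neutral-default
path). Default cohorts emulate the scale of a small sleep-lab pilot:
14 reports with word counts uniform on 46–202, neutral stretches of 8–25
tokens alternating with emotional runs of 4–12 tokens, and eight external
variables generated as linear functions of the true indicators plus
Gaussian noise — slopes signed to mirror relationships reported in
sleep-lab validations (steeper positive gradient with more REM and fewer
awakenings, more troughs with thinner psychological boundaries, deeper
troughs with larger overnight gains in positive affect, higher overall
intensity with openness). Awakening counts are rounded to integers, which
realistically produces ties and exercises the Pearson fallback.

What passing tests on this material shows: the chain
scoring → windowing → segmentation → areas → trend → correlation computes
exactly what its definitions say, recovers planted structure, and holds
its nominal type-I error under the null. What it does not show: anything
about linguistic validity on real dreams — synthetic tokens have no
negation, irony, or narrative structure, real lexicons are noisy and
incomplete, and real dream emotion need not arrive in clean rectangular
runs. Separating dream description from dream commentary is a human
pre-processing step outside the package. Validation against human-rated
dream corpora is the natural next step, not something simulation can
replace.

## Numerical choices and degenerate inputs

- Rolling sums use cumulative-sum differences; equality with a naive
  double loop to 1e−12 is asserted in the tests.
- Interpolated crossings make signed segment areas additive: their sum
  equals the trapezoid integral of the whole chart (asserted to 1e−9
  against high-resolution numerical integration).
- A single-point chart ($W = 1$, possible only for inputs shorter than
  31 tokens) counts its excursion but has zero-width area, so OEI = 0
  there without the chart being identically zero; for every $W \ge 2$,
  OEI = 0 iff the chart is flat.
- Empty-after-tokenization reports are skipped with a warning in batch
  mode and listed in the run's skip log; a constant vector in a
  correlation pair yields an explicit NA with a warning rather than a
  silent drop.
- Polynomial fits center x before constructing the Vandermonde basis;
  recovery of noiseless degree ≤ 2 polynomials is asserted to 1e−8.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
material generated at run time: cohorts of 14 reports (word counts 46–202),
1000 random trapezoid segments, all $3^8$ sign patterns plus 1000 random
charts for segmentation, 200-series antisymmetry sweeps, 20 planted
peak/trough configurations, and 500–1000 seeded null cohorts for the
type-I error of the correlation protocol. These sizes give stable
pass/fail behavior for the properties being checked while keeping a full
run in the low minutes on a laptop.

## Known limitations

- Word-level lexicon scoring ignores syntax beyond the optional 3-token
  modifier window; sentence-level compound scoring is out of scope.
- The trapezoid rule is a deliberately simple quadrature; higher-order
  rules and spline/LOESS trends are plausible refinements, not
  implemented.
- The tie-triggered switch between Spearman and Pearson changes the
  estimand between pairs; it is implemented as specified because it is
  the protocol, not because it is statistically ideal. The adjustable
  `tie_policy` and optional p-value adjustment let an analyst do better.
- Indicator magnitudes depend on the chosen `normalizer`; comparisons
  across studies require the same setting.
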