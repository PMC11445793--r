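# dreamsent

Emotions in dream reports have traditionally been rated subjectively, by
the dreamer or by external judges. **dreamsent** implements an objective,
sequential alternative for dream scientists and affective-text researchers:
it treats a dream report as a word-for-word valence signal, standardizes
it, and quantifies its emotional dynamics as a small set of per-dream
indicators that can be validated against sleep, state, and trait variables.

## The method

1. **Word-for-word valence.** Each word *w<sub>i</sub>* of a pre-cleaned
   dream description receives a continuous valence rating
   *v<sub>i</sub>* ∈ [−1, 1] from a sentiment lexicon (VADER-format files
   are read directly; ratings on the native ±4 scale are normalized by the
   scale maximum). Negative values code negative emotion, zero neutral,
   positive values positive emotion. An optional mode additionally applies
   VADER's negation (×−0.74) and booster (±0.293, distance-damped)
   modifiers over a trailing 3-token window.
2. **Sliding-window standardization.** The series is cut into windows of
   30 words overlapping by 29; each window sum is divided by the report's
   window count *W* = max(1, *L* − 29):

   *y<sub>k</sub>* = ( Σ<sub>i=k</sub><sup>k+29</sup> v<sub>i</sub> ) / W.

   Plotted against window index, this is the **dream chart**. The division
   by *W* controls for word-count differences between dreams and
   counteracts the flattening effect of long neutral stretches.
3. **Peaks and troughs.** Maximal positive excursions of the chart bounded
   by zeros (or linearly interpolated zero crossings) are peaks; negative
   excursions are troughs. Counting them gives **Total Peaks** and
   **Total Troughs**.
4. **Emotion intensity.** Each excursion's approximated area under the
   curve (aAUC) is computed by the trapezoid rule. Summing over peaks gives
   the **Positive Emotion Intensity** (PEI ≥ 0), over troughs the
   **Negative Emotion Intensity** (NEI ≤ 0), and
   **OEI = PEI + |NEI|** the Overall Emotion Intensity.
5. **Emotion gradient.** A polynomial trendline (degree 2 by default) is
   fitted to the chart; its mean slope over the chart's domain,
   (p(x<sub>W</sub>) − p(x<sub>1</sub>)) / (x<sub>W</sub> − x<sub>1</sub>),
   is the **Emotion Gradient**, the macro direction of emotional change.
6. **Validation.** Indicators are correlated with external variables using
   Spearman's ρ when a pair is tie-free and Pearson's r as the fallback
   when ties are present, without multiple-comparison correction by
   default.

## Worked example

```r
library(dreamsent)

lex <- read_lexicon(system.file("extdata", "synthetic_lexicon.tsv",
                                package = "dreamsent"))
report <- data.frame(
  id = "dream_cliff",
  text = paste(
    "I was walking along a bright warm beach with a friend and we were",
    "happy and calm and everything felt safe and peaceful and wonderful",
    "until the sky turned dark and a storm rolled in and I was suddenly",
    "alone and lost on a cliff edge with the sea below and I felt fear",
    "and panic rising as the ground crumbled and I was falling and",
    "falling and certain I was dead until I landed softly in a gentle",
    "meadow where the light was bright again and I laughed with joy and",
    "felt completely free and safe and calm once more before I woke up"
  )
)
fit <- dream_pipeline(report, lex)
tidy(fit)
#> # A tibble: 1 × 7
#>   report_id   total_peaks total_troughs   pei    nei   oei emotion_gradient
#>   <chr>             <int>         <int> <dbl>  <dbl> <dbl>            <dbl>
#> 1 dream_cliff           2             1 0.856 -0.962  1.82        -0.000302
```

The happy–frightening–happy arc of the narrative surfaces as two peaks
separated by one trough; the trough's area slightly exceeds the combined
peak area (|NEI| = 0.962 vs PEI = 0.856), and the emotion gradient is near
zero because the dream ends roughly as positively as it began:

```r
dplyr::select(fit$segments, kind, start_x, end_x, auc)
#> # A tibble: 3 × 4
#>   kind   start_x end_x    auc
#> 1 peak       1    23.1  0.576
#> 2 trough    23.1  61.8 -0.962
#> 3 peak      61.8  76    0.280

plot_dream_chart(fit$charts, fit$segments, fit$trends)   # shaded chart + trendline
```

With an external-variables table (one row per `report_id`: REM%, N2%,
awakenings, overnight affect change, personality scores, ...) the pipeline
also returns the tie-aware correlation table:

```r
fit <- dream_pipeline(reports, lex, externals = externals)
significant_edges(fit$correlations)
```

Synthetic cohorts with planted ground truth are available for testing and
simulation, and a thin command-line front end with subcommands
`score`, `chart`, `indicators`, `correlate`, `simulate`, and `plot` lives
at `inst/cli/dreamsent.R`:

```r
g <- generate_cohort(n_reports = 14, seed = 1)   # 14 reports, 46-202 words
fit <- dream_pipeline(g$reports, toy_lexicon(), externals = g$externals)
glance(fit)
```

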