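# whiskerpad

Analysis toolkit for **rostro-caudal tactile gradients on the rodent whisker
pad**: from continuous whisker-vibration traces and first-order (trigeminal
ganglion) spike trains to edge/texture epoching, per-trial vibration and
firing-rate features, ideal-observer texture discrimination, and gradient
statistics. A synthetic-data generator with full ground truth stands in for
the original recordings, so the entire chain is testable end to end.

It is written for sensory-neuroscience analysts working with passive
texture-wheel paradigms: whiskers rest on a rotating cylinder covered with
graded sandpapers (P120–P1200, mean particle diameters 125–15 µm); surface
grains excite stick–slip micromotions, and a raised edge strikes the
whiskers once per ~3-s revolution.

## The core quantities

* **Epoching** — edge collisions are excursions beyond *mean ± 3 SD* of the
  whisker position trace (applied to a 5-ms envelope); remaining time is cut
  into non-overlapping 500-ms texture trials.
* **Features** — per-trial position SD (µm), 5–250 Hz band power (Welch),
  curvature SD (1/mm); firing rates Fr = n/T with T = 50 ms (texture
  windows) and T = 10 ms (edge windows).
* **Ideal observer** — for each texture pair, the AUC is the Mann–Whitney
  rank statistic P(coarser > finer) with ties ½; per-whisker performance is
  the unweighted mean over all pairs. Significance comes from shuffling
  trial labels across stimuli (500 shuffles) and taking the 90th percentile
  of the pooled null — ≈ 0.534 at 240 trials per condition, matching the
  closed form 0.5 + z₀.₉ · √((n₁+n₂+1)/(12 n₁ n₂)).
* **Gradients** — normalized pad maps (max = 1), grain-response regressions
  against mean particle diameter with slopes normalized to the arc-4
  whisker, edge/texture firing ratios normalized to the Greek arc, and
  one-way ANOVA over arcs with Tukey contrasts.
* **Pooling** — multi-whisker trial averaging and the linearity index
  (AUC of the average ÷ average AUC; > 1 is supralinear).

## A worked example

```r
library(whiskerpad)
report <- demo_pipeline(seed = 1, dir = "report")
report
```

```
<pad_report>
  config hash: 606a7a3c1990711628a7ac2d8e63e18b
  features: 14749 rows, 5 whiskers, 5 conditions
  pad map (position SD, normalized):
    arc 0 (gamma): 0.645
    arc 1 (C1): 0.690
    arc 2 (C2): 0.773
    arc 3 (C3): 0.867
    arc 4 (C4): 1.000
  pooled null threshold (90%): 0.5202
  arc ANOVA: F = 61.53, p = 2.32e-46
```

The demo generates a synthetic pad session (5 textures × 5 whiskers, γ and
C1–C4), runs the full pipeline and writes the report bundle. The pad map
rises monotonically from the caudal Greek column to rostral arc 4: the same
textures shake rostral whiskers harder. The per-whisker tables show the
rest of the double dissociation:

```r
report$vibration$auc       # texture discrimination from vibration
#   whisker arc  mean_auc     rostral whiskers discriminate better
#     gamma   0     0.848
#        C4   4     0.995
report$neural$units        # firing-rate readouts per unit
#   whisker arc mean_auc texture_edge_auc norm_ratio
#     gamma   0    0.529            0.914      1.000
#        C4   4    0.612            0.590      0.184
```

Caudal units separate edges from textures almost perfectly
(texture-edge AUC 0.91) but barely tell textures apart (0.53); rostral
units show the reverse. The normalized edge/texture firing ratio peaks at
the Greek arc and falls rostrally. `make_figures(report, "figs")` renders
the pad-map heat map, slope bars (single-sided error bars) and AUC bars.

A command-line wrapper with subcommands `synth`, `epoch`, `features`,
`discriminate`, `gradient`, `run` and `demo` is installed at
`inst/scripts/whiskerpad.R`.

## Layout

```
R/                     core_data, synthetic_data, epoching, features,
                       discrimination, gradient_stats, pipeline modules
tests/testthat/        unit, property and acceptance tests
vignettes/             methods vignette (model, parameters, design choices)
scripts/acceptance.R   reproduction script (see above)
inst/scripts/          command-line wrapper
```
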