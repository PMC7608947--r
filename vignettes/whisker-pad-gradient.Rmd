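---
title: "Methods: tactile-gradient analysis across the whisker pad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tactile-gradient analysis across the whisker pad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskerpad)
```

## The scientific problem

Rodent macrovibrissae are arranged in rows (A–E) and arcs (columns) on the
mystacial pad. Whisker length and compliance change systematically along the
rostro-caudal axis: the long caudal whiskers (the Greek column, treated here
as arc 0) are heavy, compliant levers, while the short rostral whiskers
(arc 4) are stiff. When these whiskers are dragged across a textured surface
mounted on a rotating wheel, surface grains excite brief stick–slip
micromotions whose magnitude grows with grain size; once per revolution the
whiskers also collide with a raised edge, producing a much larger excursion
followed by damped resonant ringing. First-order trigeminal ganglion (TG)
neurons transduce both signals.

`whiskerpad` implements the full analysis chain for asking whether the pad
forms a *gradient of tactile information transmission*: texture information
(what) transmitted preferentially through rostral whiskers, edge/collision
information (where) through caudal whiskers. The chain is: epoch separation
→ per-trial features → ideal-observer discrimination with a permutation
null → gradient statistics. Because the underlying recordings are not
publicly deposited, the package ships a synthetic generator that reproduces
the statistical structure the analysis assumes, with full ground truth, so
every stage is testable end to end.

## The synthetic pad model

`gen_texture_trace()` models whisker position (µm, at the whisker base) as

\[
x(t) = b(t) + \sum_i A_i\, k\!\left(\tfrac{t - t_i}{L_i}\right),
\]

a compound-Poisson shot-noise process on top of band-limited Gaussian
baseline noise \(b(t)\):

* **Slip events** arrive as a Poisson process at `slip_rate` (default
  1500 events/s — the grain passage rate for a wheel moving at ~39 mm/s
  across grains tens of µm wide). Each event is a biphasic excursion
  `k(u)`: a slower "stick" phase (60% of the event) followed by a faster,
  larger "slip" return scaled so the event integrates to zero. Event
  durations are uniform on 1.5–5 ms; amplitudes are
  `slip_amp_per_um × diameter × arc_gain(arc)` with mean-one lognormal
  jitter (`sdlog` 0.3). Amplitude proportional to mean particle diameter is
  the generative counterpart of the empirical finding that vibration
  variance tracks grain size.
* **Arc gains** (default 0.2, 0.35, 0.55, 0.75, 1.0 for arcs 0–4) encode
  the rostro-caudal transmission gradient: the same texture shakes a
  rostral whisker harder than a caudal one. The "constant-distance" control
  condition is modeled as an alternative gain map, not separate physics,
  because the scientific claim at stake — the gradient persists — is a
  property of the gain map.
* **Baseline noise** (SD 3 µm) is low-pass filtered at 500 Hz: photosensor
  and plant noise is band-limited, and this keeps features invariant (within
  2%) under anti-aliased decimation of the trace. The zero-phase filter is
  normalized by its theoretical white-noise variance gain rather than the
  empirical trace SD, so traces remain independent draws — resampling the
  generator many times really does produce exchangeable sessions (this
  matters for the type-I calibration of the gradient ANOVA).
* **Edge collisions** (`gen_edge_trace()`) occur once per wheel revolution
  (period 3 s): a 50-ms half-sine excursion of amplitude
  `edge_amp_sd_multiple` (default 6) times the texture SD — a 5-mm edge at
  ~39 mm/s stays in contact for on the order of 100 ms, so collisions are
  *long* events — followed by an exponentially damped sinusoid
  (`ring_decay_tau` 50 ms; ring frequency rising rostrally, 60–150 Hz, as
  shorter whiskers resonate faster). No resonance-based texture labeling is
  implemented: ring frequency varies by arc as phenomenology, not as a
  coding channel.

The closed-form SD of the texture process follows Campbell's theorem and is
exported as `texture_trace_sd()`; the test suite holds the Monte-Carlo
generator to it within 5% on 60-s traces. Curvature is generated as a
low-pass-filtered, scaled copy of position plus independent noise — the
analysis uses curvature only through its per-trial SD, so only its
statistical behavior is needed, not beam mechanics.

`gen_spike_train()` models a TG unit as an inhomogeneous Bernoulli process
on 1-ms bins with rate

\[
r(t) = r_0 + k_{tex}\,\overline{|s(t)|} + k_{edge}\,\rho(\mathrm{arc})\,e(t),
\]

where \(\overline{|s|}\) is the per-bin mean absolute slip component,
\(e(t)\) a 60-ms boxcar after each true collision onset, and
\(\rho\) a relative edge gain decreasing rostrally (defaults 1, 0.72, 0.5,
0.35, 0.25). Two gradients emerge jointly: texture-driven firing grows
rostrally (through the arc gain in the drive), while the edge/texture
response ratio peaks at the Greek arc — the double dissociation the
neural analysis is designed to detect. A hard refractory period equal to
the bin width (at most one spike per millisecond) keeps expected counts
exactly linear in rate at the rates used.

`gen_session()` generates the full factorial of whiskers × textures with a
ground-truth manifest. Defaults are the study conditions: five textures
(P120, P220, P600, P800, P1200; mean particle diameters 125, 68, 26, 22,
15 µm), whiskers γ and C1–C4 (arcs 0–4), 120 s per cell — two minutes of
wheel rotation per texture, i.e. 40 revolutions and 40 edge collisions.

## Epoch separation

The edge criterion is *mean ± k·SD* of the whole trace with `k = 3`.
Manual demarcation of edge-response margins is replaced by a deterministic
rule, all parameters exposed and reported with results:

1. compute `|x − mean|` and smooth it with a 5-ms moving average (the
   envelope step suppresses sub-5-ms noise peaks — any Gaussian-like
   process crosses 3 SD at the sample level many times per minute, while
   collisions are ≥ 50-ms events and pass unattenuated);
2. samples whose envelope exceeds `k·SD` seed edge epochs; crossings closer
   than 50 ms (spanning the ringing) merge;
3. each epoch extends forward by a fixed 20-ms margin once the envelope
   settles, and a 50-ms guard band is excised on both sides;
4. a 500-ms `pre_edge` epoch precedes each edge (duration configurable; the
   pre-edge window length is a convention, not a measured quantity);
5. everything else is `texture`.

Detection is invariant to offsets and equivariant to amplitude scaling; the
statistics can optionally be computed robustly (median/MAD) since edges
inflate the plain SD, but the plain global mean/SD is the default
criterion. A zero-variance trace yields a single texture epoch with a
warning, not an error. On synthetic sessions the suite requires 100%
collision recall and zero edge-contaminated texture trials.

Texture epochs are tiled with non-overlapping 500-ms trials
(`segment_trials()`); partial tails are dropped, so trials can never touch
an edge, guard or pre-edge sample. Non-overlap keeps trials exchangeable,
which the permutation null relies on.

## Features

Per 500-ms vibration trial: `position_sd` (sample SD, n−1 — trials are
samples from a process), `band_power` (5–250 Hz), and `curvature_sd`.
Band power uses averaged modified periodograms (Hann window, 256-ms
segments, 50% overlap) integrated over the band by the trapezoid rule; the
estimator recovers the variance of an in-band unit sinusoid (0.5) within
5%. Band power is returned in absolute units; normalization happens only
where the analysis normalizes (regression points, maps).

Firing rates are exact counts over windows: `T = 50 ms` for texture windows
tiled inside texture epochs and `T = 10 ms` at the start of each detected
edge epoch. Because detection triggers ~10 ms after physical collision
onset and the synthetic edge drive lasts 60 ms, the 10-ms window sits
inside the response and the estimate is unbiased.

The pad map (`build_pad_map()`) normalizes each whisker's mean feature by
the maximum across whiskers *per texture*, averages the normalized values
over textures, and rescales so the map maximum is exactly 1 (when
different whiskers peak under different textures, plain averaging would
leave the maximum below 1). All normalization references are the observed
maximum within the analysis group — never a fixed whisker — with one
exception: grain-response slope normalization is pinned to the arc-4
whisker of each session (below).

## Ideal-observer discrimination

`auc(a, b)` is the Mann–Whitney rank statistic (ties ½): the probability
that a random trial from the coarser texture exceeds one from the finer.
Pairs are oriented fine → coarse by mean particle diameter and AUCs are
*not* folded about 0.5 by default — under the generative model coarser
textures produce larger features, and chance is 0.5; folding is available
for real data of unknown direction. `pairwise_mean_auc()` averages all
unordered texture pairs with equal weight.

The significance threshold comes from shuffling trials across stimuli:
labels are permuted over the pooled trial list, all pairwise AUCs are
recomputed, and samples are pooled over shuffles, pairs and units (uniform
weights); the threshold is the 90th percentile of the pooled null (500
shuffles by default). With 240 trials per condition — two minutes cut into
500-ms trials — the pooled threshold is ≈ 0.534, matching the closed-form
normal approximation with null SD \(\sqrt{(n_1+n_2+1)/(12 n_1 n_2)}\).

Multi-whisker pooling (`combine_whiskers()`) averages same-index trials
across whiskers, trimming to the shortest; trial order within a texture is
arbitrary, so a seeded random pairing option exists. The
`linearity_index()` is the AUC of the average divided by the average AUC;
values above 1 are supralinear. For a duplicated channel the index is
exactly 1; independent noise across channels makes it exceed 1.
`texture_edge_auc()` compares edge-window rates against fine-grained
texture-window rates.

## Gradient statistics

`fit_grain_response()` regresses the per-texture mean response
(max-normalized per whisker, so every curve peaks at 1) on mean particle
diameter in µm — the diameter itself, not the P-number; a log-diameter
option exists but is off by default. Because responses sit on a noise
floor, low-gain (caudal) whiskers compress toward flat normalized curves
while high-gain (rostral) whiskers approach proportionality — the
normalized slope is the gradient readout. Vibration slopes are normalized
to the arc-4 slope of the same session (`normalize_slopes()`); neuronal
slopes to the steepest unit in the sample (`fit_neuronal_response()`).
Sessions are fitted per whisker and pooled after normalization, the
reading consistent with per-session referencing.

`arc_anova()` is a one-way ANOVA over arcs (or rows); Tukey's HSD runs only
when the omnibus F is significant at 0.05, with flags at both 0.05 and
0.01. The suite calibrates the test's type-I rate on flat-gain pads
(≈ 5% over 200 simulated sessions).

## Numerical choices and degenerate inputs

* Time is in seconds; sample indices are 0-based with half-open
  `[start, end)` intervals throughout.
* Sessions are stored as one directory per session (CSV manifests, one
  file per channel, 15 significant digits); spike trains validate sorted
  times and recording-span bounds on read.
* Firing rates are exact rational counts; AUC is computed by midranks and
  agrees with brute-force pair counting to 1e-12.
* Degenerate inputs: zero-variance traces epoch as all-texture with a
  warning; a zero mean texture rate flags the edge/texture ratio as `NA`
  and drops it from normalization; constant responses fit slope 0 with
  undefined r².
* Seeds: every generator accepts a seed and restores the caller's RNG
  state; a session's master seed derives per-trace seeds, so identical
  seeds give byte-identical sessions and report bundles.

## Problem sizes

Analyses in this package target the 2.5 kHz decimated representation of
the 25 kHz acquisition (Nyquist five times the 250-Hz band edge); the
generator can synthesize directly at the analysis rate, and features agree
between the two representations within 2%. The test suite exercises the
full study-condition factorial (5 textures × 5 arcs × 120 s) across 20
seeded replicate sessions for the gradient and dissociation checks, 200
flat-gain sessions for ANOVA calibration, and 60-s sessions for epoching
recall; single-trace checks against the closed-form variance run at the
full 25 kHz.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis assumes:
grain- and arc-dependent shot-noise amplitude, long edge excursions with
ringing, and rate-coded spiking with arc-dependent edge/texture drive. It
does not model beam mechanics, active whisking kinematics, 3-D contact,
slip-rate dependence on grain size, neuronal adaptation, or correlated
noise across whiskers. Recovery of the programmed gradients therefore
validates the pipeline's inference machinery — not the biological claim
itself, which only the original recordings can support. Conclusions from
real data additionally depend on the edge-margin convention (our
deterministic settle rule stands in for manual demarcation) and should
report the detection parameters alongside results.

## A worked example

```{r example, eval = FALSE}
library(whiskerpad)
report <- demo_pipeline(seed = 1, dir = "report")
report
```

The printed report shows the normalized pad map rising from the Greek arc
to arc 4, the per-arc mean AUCs with the pooled null threshold, and the
arc ANOVA; `report/` holds the CSV tables (each stamped with the config
hash), `summary.json`, and — with `figures = TRUE` — the pad-map,
slope and AUC figures.
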