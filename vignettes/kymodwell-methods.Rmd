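---
title: "Measuring microtubule end residence from kymographs: models and design choices"
author: "KymoDwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microtubule end residence from kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KymoDwell)
```

## The scientific problem

Kinesins that regulate microtubule dynamics recognise the microtubule end:
they stay at the terminal tubulin site far longer than translocating
kinesins, which walk along the lattice and leave the end within a frame or
two. The measurable signature is the **end-residence time** of single
fluorescent motors on immobilised, GMPCPP-stabilised (static) microtubules,
read off kymographs: time–position images in which rows are movie frames
and columns are positions along one microtubule. KymoDwell implements that
measurement, a stochastic simulator that generates kymographs with known
ground truth, and the statistics used to compare motor variants.

## The generative model

`simulateEvents()` draws one realisation of a minimal kinetic model:

* landings: Poisson with rate `landingRate * length` (events µm⁻¹ s⁻¹ ×
  µm), positions uniform along the lattice;
* translocation: constant speed `velocity` (nm/s) toward the plus end with
  detachment hazard `velocity / meanRunLength`, equivalent to exponential
  run lengths;
* end capture: a motor whose run carries it within `endCaptureUm` of the
  plus end parks at the centre of the terminal position bin and detaches
  after an exponential dwell of mean `meanEndDwell`;
* static binders (`fractionStatic`): exponential lattice dwells at the
  landing position, or an end dwell when the landing falls inside the end
  zone — this is how a non-translocating end-recogniser such as MCAK
  produces end events;
* events still bound at the last frame are truncated and flagged censored.

Speed is a per-variant constant: the spread of measured velocities in real
data mixes true molecular variability with measurement noise, and only the
mean enters any downstream comparison here. Only plus-end-directed motion is
generated (all simulated variants are plus-directed); `polarity` selects
which image side carries the plus end.

`renderKymograph()` samples trajectories at frame midpoints — a motor
contributes to frame *k* if bound at time (*k* − ½)Δt; there is no motion
blur within a frame, the simplest model consistent with 2.7 Hz sampling.
Each motor is a 1-D Gaussian spot (`psfSigma`, additive when events
overlap, which is what creates crossing events); both channels receive
i.i.d. Gaussian background noise. The microtubule channel is a uniform
band over the microtubule's pixel span: GMPCPP microtubules neither grow
nor shrink, so a single extent serves the whole movie.

### Defaults and what they emulate

| parameter | default | rationale |
|---|---|---|
| `frameInterval` | 1/2.7 s | the assay's 2.7 Hz acquisition |
| `pixelSize` | 160 nm | typical 100× EMCCD TIRF sampling; not stated by the assay, configurable |
| `psfSigma` | 1.1 px | ≈ 250 nm FWHM diffraction-limited spot at 160 nm/px |
| `signalAmplitude` / `backgroundSd` | 400 / 20 | spot SNR 20, comfortably above threshold, as in a well-exposed single-molecule movie |
| `landingRate` | 0.02 µm⁻¹s⁻¹ | sparse single-molecule density; see crossing losses below |
| microtubule lengths | uniform 6–10 µm | typical GMPCPP seed lengths |

The generator emulates: Poissonian landings, exponential dwells and run
lengths, diffraction-limited spots, shot-to-shot background noise, censoring
at the movie boundary, and crossing events. It does **not** emulate
photobleaching, microtubule dynamics or depolymerisation, multi-motor
crowding, stage drift, or diffusion of lattice-bound motors. Passing the
recovery tests therefore shows the measurement chain is correct under these
idealised conditions, not that it is robust to every artefact of real data.

## The measurement chain

1. **Thresholding** (`estimateThreshold`): median + *k* × robust SD
   (1.4826 × MAD) of the channel. The median/MAD pair is taken over the
   whole image, which is valid while background pixels are the majority —
   the dataset generator therefore sizes images so the microtubule occupies
   under half of the columns.
2. **End location** (`locateMicrotubule`): the time-averaged rhodamine
   profile is thresholded and the first and last columns of the longest
   above-threshold run are the end pixels.
3. **Event detection** (`detectEventPixels`): GFP pixels above threshold,
   restricted to the microtubule span.
4. **Segmentation** (`segmentEvents`): connected components under
   8-connectivity — two events are discrete when separated by at least one
   non-event pixel along time or distance, so diagonal contact joins. The
   implementation (components of the pixel adjacency graph) is checked
   exactly against a brute-force flood fill in the test suite.
5. **Classification** (`classifyEvent`): a component with ≥ 2 disjoint
   pixel runs in any frame-row is two overlapped events that cannot be
   separated and is discarded (`discarded-crossing`); otherwise an event
   spanning ≥ 3 frames whose per-frame intensity centroid moves without
   sign reversal (pauses allowed) by ≥ 2 px net is `translocating`; the
   rest are `lattice`. Every component receives exactly one class.
6. **Measurements**: end residence = frames of the maximal consecutive run
   at the end column × Δt; velocity = |OLS slope| of centroid position vs
   time, excluding end-column frames; run length = net centroid
   displacement × pixel size.

### Threshold multiplier: k = 3 vs k = 4.5

The function default is *k* = 3. On a 300 × 116 kymograph, however, a
Gaussian background leaves ≈ 0.13% of pixels above median + 3 robust SD —
dozens of isolated single-pixel "events" per movie, a fraction of which sit
on an end column and dilute dwell statistics. The pipeline default is
therefore *k* = 4.5 (expected false pixels ≪ 1 per movie), which at the
default spot SNR of 20 costs essentially no detection. With dim spots
(SNR ≈ 5), *k* = 3 keeps per-pixel recall above 0.9 and the single-pixel
specks must be tolerated.

### End attribution: peak column, not any pixel

A diffraction-limited spot two pixels short of the end already lights the
end column above threshold, so attributing end residence to *any* trace
pixel in the end column adds ≈ 0.4 s of approach time at 810 nm/s — larger
than a wild-type dwell. The default (`endAttribution = "peak"`) counts a
frame as at-the-end when the trace's *brightest* column that frame is the
end column, which coincides with the parked phase of the trajectory. The
`"any"` rule is available for data whose spots are too dim for a reliable
per-frame peak, together with `endWindow` to widen the end zone by ± *n*
columns.

### Duration convention and the dwell MLE

Per-event durations use the frame-counting convention: an event occupying
*k* frames lasts *k*·Δt (`durationConvention = "k"`; `"k_minus_1"` is
available). For an exponential dwell of mean µ sampled at frame midpoints
with uniform phase, the occupied-frame count of a *detected* event is
1 + Geometric(e^(−Δt/µ)), so the raw mean is biased:

E[*k*·Δt | detected] = Δt / (1 − e^(−Δt/µ)),

i.e. +46% at µ = 0.46 s and +20% at µ = 1 s at 2.7 Hz. Descriptive
summaries (`summarizeResidence`) keep the raw mean ± SD/√n, matching how
frame-counted residence times are conventionally reported; parameter
recovery uses the inverse of the geometric mean (`dwellMLE`):

µ̂ = Δt / log( k̄ / (k̄ − 1) ),

which is the maximum-likelihood estimate and is exact in expectation by the
memorylessness of the exponential. Fold changes between raw means are
compressed by the same bias (short dwells are inflated relatively more), so
variant comparisons on the generative scale should use the MLE ratio.

### Censoring, crossings and polarity

Events touching the first or last movie frame, and end runs touching the
last frame, are flagged censored and excluded from duration summaries;
run lengths ending at an end column are likewise censoring-flagged (the run
was cut short by the end, not by detachment), which makes the mean
*uncensored* run length an underestimate when microtubules are short
relative to the run length — visible in the worked example. Exclusion of
crossing events removes long end dwells preferentially (a long dwell is
more likely to collide with the next landing), so parameter-recovery runs
use sparse landings (0.004 µm⁻¹s⁻¹ in the validation datasets) where this
loss is negligible. The plus end is inferred per kymograph by majority vote
over the net displacement direction of translocating events; end events on
the opposite (minus) end — transient passages of motors landing in the
terminal column — are excluded from residence summaries when polarity is
inferable, and both ends are reported otherwise.

## Statistics

* **KS comparison** (`ksTwoSample`): D is the exact sup-ECDF difference
  (evaluated after ties); p comes from the asymptotic Kolmogorov series at
  √(n₁n₂/(n₁+n₂))·D. At the sample sizes of dwell datasets (~250–300) the
  asymptotic and exact p differ negligibly; the suite cross-checks both D
  and p against the reference implementation and verifies calibration
  (type-I error 0.03–0.07 at nominal 0.05 over 1000 null replicates).
  Frame-quantised durations contain ties, which make the asymptotic p
  slightly conservative.
* **Fold change** (`foldChange`): ratio of means with a seeded bootstrap
  percentile CI (defaults 10⁴ resamples, seed 12345).
* **Correlation** (`correlationReport`): Pearson r with two-sided p, used
  for velocity-vs-end-residence style reports where no relationship is
  expected when end residence is set independently of stepping speed.

The reported variant-to-wild-type end-residence ratios are estimated as
replicate-averaged fold changes over 200 simulated dataset pairs at the
compiled sample sizes: a single pair of datasets at n ≈ 280 has ≈ 8.5%
relative sampling error on the ratio, so averaging replicates estimates the
*recovered* ratio rather than one noisy draw of it.

## ATPase turnover

At 2 mM ATP over ≤ 30 min, ADP production is linear in time at the rates of
interest, so `fitTurnover` is an OLS slope of ADP (µM) against time (s)
divided by the enzyme concentration (1 µM in the assay layout), with a
guard that ADP consumption stays below 50% of starting ATP. No
Michaelis–Menten fitting is attempted — the data do not constrain it.
`simulateTimecourse` is its noiseless/noisy synthetic counterpart; the
noiseless round trip is exact.

## Validation problem sizes

The test suite validates each law-of-large-numbers property at n = 10⁴
draws (3 SE bands); segmentation against flood fill on 1000 random masks up
to 12 × 12; full-chain dwell recovery on an end-dwell grid {0.5, 1, 2} s at
810 nm/s with 300 simulated microtubules per grid point (≈ 300 uncensored
plus-end events each, giving ≈ 5–6% estimator SE against a 15% acceptance
band); and KS power/calibration at 100/1000 replicates. These sizes are
chosen so that each check's sampling error is several times smaller than
the tolerance it enforces.

## Known limitations

* No photobleaching: real dwell distributions are truncated by fluorophore
  survival; here censoring arises only at the movie boundary.
* Constant per-variant velocity; no velocity spread or pausing beyond what
  noise induces in centroids.
* MCAK is modelled as a static binder that lands directly on ends; its
  diffusive end-targeting and depolymerase activity are not simulated, so
  simulated MCAK end-event counts are lower than experimental ones.
* Merged same-column events (one motor landing on another's end dwell
  without a separating gap) are not detectable by the crossing rule and
  lengthen a small fraction of end runs at high density.
* The microtubule extent is a single time-averaged estimate; dynamic ends
  are out of scope.
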