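# KymoDwell

Single-molecule TIRF kymograph analysis for kinesin motor proteins, centred
on the question of how long a motor resides at the microtubule end before
detaching. Translocating kinesins (such as Kinesin-1) walk along the
microtubule lattice and leave the end almost immediately; regulating
kinesins (such as the depolymerase MCAK, a Kinesin-13) recognise the end and
dwell there. KymoDwell measures, from two-channel kymographs (a rhodamine
microtubule channel and a GFP motor channel), the three readouts that
distinguish these behaviours — **end-residence time**, **translocation
velocity** and **run length** — and compares residence-time distributions
between variants with two-sample Kolmogorov–Smirnov tests. A basal ATPase
module fits ATP turnover rates from ADP-production timecourses.

Because raw single-molecule movies are rarely shareable, the package ships a
stochastic simulator of single kinesin–microtubule interaction events with a
TIFF kymograph renderer, so that every stage of the measurement chain can be
validated against known ground truth.

## The model and the measurements

The simulator realises a simple kinetic model on a static (GMPCPP-stabilised)
microtubule of length *L*:

- landings are a Poisson process of rate *k*<sub>on</sub>·*L*
  (events·µm⁻¹·s⁻¹ × µm), uniform in position;
- a translocating motor moves plus-ward at constant speed *v* (nm/s) with
  detachment hazard *v*/*ℓ*, i.e. exponential run lengths of mean *ℓ* (µm);
- a motor reaching the terminal pixel switches to an exponential end dwell
  of mean *τ*<sub>end</sub>, then detaches;
- static binders dwell exponentially on the lattice
  (*τ*<sub>lattice</sub>), or at the end if they land there.

Rendering samples each trajectory at frame midpoints (2.7 Hz by default),
draws each motor as a 1-D Gaussian spot (σ ≈ 1.1 px at 160 nm/px) and adds
Gaussian background noise in both channels.

The measurement procedure mirrors manual kymograph analysis: intensities are
thresholded at median + *k*·(1.4826·MAD); the microtubule end is the final
above-threshold column of the time-averaged rhodamine profile; an event is a
connected set (8-connectivity) of above-threshold GFP pixels; events moving
unidirectionally for ≥ 3 frames are translocating; overlapping events that
cannot be separated are discarded; and an event's end residence is the
maximal run of frames its trace spends at the end column, times the frame
interval. Because frame-quantised exponential dwells are biased upward
(E[k·Δt | detected] = Δt/(1 − e^(−Δt/µ))), the summary layer also reports a
geometric frame-count MLE, µ̂ = Δt / log(k̄/(k̄ − 1)), which recovers the
generative dwell; see the methods vignette.

## Worked example

Simulate a wild-type/S266R-like panel, analyse the kymographs, and compare
end-residence distributions:

```r
library(KymoDwell)

cfg <- pipelineConfig(
  variants = list(
    WT    = MotorParams("WT",    velocity = 810, meanRunLength = 3.06,
                        meanEndDwell = 0.46, landingRate = 0.01),
    S266R = MotorParams("S266R", velocity = 676, meanRunLength = 1.54,
                        meanEndDwell = 1.41, landingRate = 0.01)),
  imaging = ImagingParams(),   # 2.7 Hz, 160 nm/px, 300 frames
  nMicrotubules = 40, seed = 1)
report <- runPipeline(cfg, verbose = FALSE)
```

which prints (via the report):

```
WT     end events n =  89  mean = 0.72 s  dwell MLE = 0.52 s  velocity = 810 nm/s
S266R  end events n =  66  mean = 1.75 s  dwell MLE = 1.56 s  velocity = 673 nm/s
S266R vs WT: fold change = 2.42, KS D = 0.43, p = 1.7e-06
```

Reading this: the raw means (0.72 s, 1.75 s) carry the upward
frame-quantisation bias, while the dwell MLE recovers the generative means
(0.46 s and 1.41 s) within sampling error; their ratio (≈ 3.0) matches the
generative three-fold difference, and the KS test separates the two
distributions decisively. Velocities are recovered to within a few nm/s.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/kymodwell.R run --config inst/extdata/panel.yaml \
    --out results/ --seed 1
Rscript inst/scripts/kymodwell.R atpase --in inst/extdata/atpase_wt_synthetic.csv
```

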