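---
title: "Detecting sleep spindles and K-complexes by oscillatory/transient decomposition"
author: "sleepwave developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep spindles and K-complexes by oscillatory/transient decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleepwave)
```

## The problem

Stage-2 sleep EEG mixes two diagnostic micro-events with opposite
morphology: **spindles** — trains of 11–16 Hz waves lasting at least
0.5 s — and **K-complexes** — a well delineated negative sharp wave
immediately followed by a positive component, total duration at least
0.5 s. A detector that band-pass filters the raw trace sees both events
through the same linear lens and confuses each with background activity
of the other's type. `sleepwave` instead separates the signal *by
morphology first*: a sparse decomposition splits each segment into an
oscillatory component (where spindles live) and a transient component
(where K-complexes live), and each detector then works on a far cleaner
signal.

## The tunable Q-factor wavelet transform

The decomposition rests on the TQWT, an oversampled two-channel filter
bank iterated on its low-pass branch. Its two free parameters are
directly interpretable:

* **Q-factor** `Q = (2 − β)/β` — the ratio of a wavelet's centre
  frequency to its bandwidth, i.e. roughly the number of oscillation
  cycles. `Q = 5.5` matches the minimum cycle count of an 11 Hz burst
  lasting 0.5 s; `Q = 1` gives one-cycle, transient-shaped wavelets.
* **redundancy** `r = β/(1 − α)` — the oversampling rate; `r = 3` is
  the customary choice for biomedical signals. Larger r localizes the
  wavelet in time without changing its shape.

The filters are specified in the DFT domain through the scaling factors
`β = 2/(Q+1)` and `α = 1 − β/r`, with the Daubechies-type transition
function `θ(ω) = ½(1+cos ω)√(2−cos ω)`, which satisfies
`θ(ω)² + θ(π−ω)² = 1`. With unitary per-subband DFT normalization the
transform is a **Parseval frame**: the inverse is the adjoint and
reconstruction is exact to round-off (the suite asserts 1e−8 relative;
measured ~1e−15). The maximal depth is
`J_max = ⌊log(βN/8)/log(1/α)⌋`; the package defaults to `J = J_max`
because no working depth below that is canonical, and the deepest
subbands then hold the slowest resolvable scales.

Subband lengths are rounded to even integers per level and the input is
zero-padded to the smallest even length for which every stage is
realizable; the original length is recorded and restored on inversion.
The cascade is implemented twice: a pure-R reference and a compiled
(RcppArmadillo) path used everywhere; a property test pins them to each
other at machine precision, so the fast path is continuously validated
against the readable one.

## Morphological component analysis

Each 30-s segment `x` is decomposed by dual basis-pursuit denoising:

    argmin_{w1,w2} ‖x − Φ₁ᵀw₁ − Φ₂ᵀw₂‖₂² + Σⱼ λ₁ⱼ‖w₁ⱼ‖₁ + Σⱼ λ₂ⱼ‖w₂ⱼ‖₁

with `Φ₁` the Q = 5.5 dictionary and `Φ₂` the Q = 1 dictionary. The
components are `x₁ = Φ₁ᵀw₁` (oscillatory) and `x₂ = Φ₂ᵀw₂` (transient);
the residual `x − x₁ − x₂` absorbs what neither dictionary represents
sparsely — in practice mostly broadband noise, which is why the
decomposition also acts as a denoiser.

**Solver.** The canonical solver for this problem family is SALSA
(split augmented Lagrangian shrinkage). We implemented it and found its
objective trace oscillates at the ~1e−6 relative level — harmless for
convergence, but this package's contract requires a per-iteration
non-increasing objective (it is the cheapest property a user can check
to trust a fixed-iteration solver). The default is therefore **monotone
FISTA**: an accelerated proximal gradient whose objective is
non-increasing *by construction*, with step `1/L = 0.25` (the
concatenated Parseval dictionaries give the data term a gradient
Lipschitz constant of exactly 4). Tracking the synthesis images of all
iterates through the linear recursions keeps the cost at two forward
and two inverse transforms per iteration — the same as SALSA. At the
default 500 iterations both solvers agree to three decimals on the
separation benchmarks; `solver = "salsa"` and `"ista"` remain
available.

**Regularization.** The study this design follows reports no λ values.
We set `λ_{i,j} = θᵢ · ‖ψ_{i,j}‖₂ · scale`, where `‖ψ_{i,j}‖₂` is the
norm of the level-j synthesis wavelet (computed by inverting a unit
coefficient — this equalizes the penalty across subbands of an
overcomplete transform), `scale` is the segment's standard deviation,
and `θ₁ = θ₂ = 0.1`. The θ values were fixed once so that a clean tone
and a clean biphasic transient each land ≥ 99% in their own component;
they are exposed in `mca_problem()` but the defaults are not tuned per
data set. Iterations default to 500; an early-stop is deliberately
absent so that identical inputs always do identical work.

**Numerical notes.** Soft-thresholded coefficients cluster around zero
and feed back into FFTs; denormalized floats slowed the solver about
seven-fold on x86, so the solvers run with flush-to-zero enabled and
restore the FPU mode on exit. All reductions in the objective use
Armadillo's single-threaded accumulators rather than BLAS dot products,
which makes runs bit-reproducible regardless of the BLAS thread count.

## Spindle detection

The oscillatory component is mapped to the spindle band by a CWT with
complex frequency-B-spline wavelets
`ψ(t) = fb·sincᵐ(t·fb/m)·e^{i2πfc t}` with `m = 25`, `fb = fc = 1` —
the fbsp family correlates best with spindle waveforms among the
candidates ranked by `waveform_crosscorr()`. Scales map to frequency by
the pseudo-frequency relation `f = fc·fs/scale`; the grid is 11–16 Hz
in 0.25 Hz steps (≥ 20 rows, so 8-neighbourhoods are meaningful).
Kernels are L1-normalized, so a tone of amplitude A reads ≈ A²/4 µV² on
the squared-magnitude map; this puts map values and thresholds in an
interpretable microvolt² range, but they remain normalization- and
fs-dependent and are always learned, never transplanted.

Candidate events are built *threshold-independently*: every strict
8-neighbour local maximum above a structural floor (5% of the map's
global maximum) claims the contiguous time span over which the
per-column map maximum stays above 25% of its value (a −6 dB amplitude
drop); overlapping spans, or spans closer than 0.25 s, merge.
Thresholding then merely filters candidates by their peak value, which
makes the detected count non-increasing in the threshold by
construction — the property the training sweep relies on. The
structural floor exists because a noise-level maximum's −6 dB span is
meaninglessly wide; without the floor such spans glue real events
together.

**Duration floor.** The m = 25 wavelet's envelope has width
`σ_w = √(3m)/(πf)` ≈ 0.21 s at 13 Hz, so *any* blip smears to a
≈ 0.5 s map extent — the raw extent cannot discriminate the AASM 0.5-s
floor. Treating burst and wavelet envelopes as Gaussians whose widths
add in quadrature, the package deconvolves the wavelet width from the
half-amplitude extent and estimates the visible burst duration as
`dur = 6·√((extent/2.355)² − σ_w²)` (a Gaussian burst whose visible
duration is `6σ` has −6 dB extent `2.355·√(σ² + σ_w²)`). A 0.3-s blob
is then rejected at any band frequency while a genuine 0.5-s spindle
passes. The factor 6 encodes "visible duration = ±3σ of the envelope";
for strongly non-Gaussian envelopes the estimate is approximate.

**Band-edge limitation.** With the strict "all eight neighbours" rule
and the analysis grid confined to 11–16 Hz, a spindle at exactly 11 or
16 Hz puts its ridge on a border row, where maxima are excluded by
policy; only spectral smearing lets a neighbouring row catch it. In the
synthetic end-to-end experiment (frequencies uniform over 11–16 Hz)
this accounts for essentially all residual misses (~5%). Real spindle
frequencies cluster away from the band edges, so the practical impact
is smaller, but detection near the edges is structurally weaker.

## K-complex detection

The transient component is filtered to 0.5–5 Hz with a Hamming
windowed-sinc FIR applied as a single centred convolution — the kernel
is symmetric (linear-phase type I), so this is exactly zero-phase and
preserves trough timing; edges are mirror-extended to avoid step
transients. Each low-pass prototype is normalized to unit DC gain
before differencing, making the band-pass DC gain exactly zero. Kernel
length defaults to `3.3·fs/min(low, (high−low)/2)` taps: the narrower
of the lower transition and half the bandwidth governs the length, so
the same rule serves the wide 0.5–5 Hz band and the narrow 12–15 Hz
RMS-baseline band.

Strict local minima at or below the (negative) trained threshold are
candidate troughs; when two fall within 2 s, the more negative wins
(the constraint is stated in the field as "successive detections at
least 2 s apart"; the resolution rule is ours). The event extent runs
from the last zero-crossing before the trough to the first
zero-crossing after the following positive peak — mirroring the
"negative sharp wave immediately followed by a positive component"
definition — with a ±0.75 s fallback and a symmetric widening to the
0.5-s floor. A final pass drops the shallower of any pair whose
*onsets* ended up closer than 2 s, so the separation contract holds for
the reported intervals, not just the troughs. Note the band-pass
attenuates a biphasic wave's trough by roughly 15% at typical K-complex
durations, so thresholds trained on the filtered trace sit shallower
than raw trough amplitudes.

## Training and evaluation

Detected and annotated events are matched one-to-one, greedily by
largest temporal overlap, any positive overlap qualifying (the most
permissive defensible reading of window-based scoring; the criterion is
a parameter). Sensitivity `TP/(TP+FN)` and FDR `FP/(FP+TP)` return `NA`
when undefined — never a silent 0. Training sweeps the spindle
threshold from 0 to twice the largest map value in 10 µV² steps and the
K-complex threshold from −2 to −200 µV in −2 µV steps, pooling all
training segments, and picks `argmax(Sen − FDR)` (first index on ties).
Inter-annotator agreement uses per-30-s-segment presence/absence per
event type (event-level kappa would need a negative-event count that
has no natural definition); Cohen's
`κ = (p_o − p_e)/(1 − p_e)` is `NA` when `p_e = 1`.

The RMS baseline detector (12–15 Hz band-pass, RMS of consecutive
100-ms windows, threshold runs of 0.5–3 s) is included as the
comparison standard; its analytic behaviour (a tone of amplitude A has
RMS `A/√2`) anchors its tests.

## The synthetic world

`generate_recording()` emulates what the detectors need and nothing
more: a `1/f^γ` Gaussian background (γ = 1, 10 µV RMS — typical of a
central derivation in stage 2), spindles as Gaussian-windowed tones
(11–16 Hz, 0.5–2 s, envelope peak 15–40 µV, envelope σ = dur/6),
K-complexes as C¹ biphasic half-sine-squared waves (troughs −75 to
−150 µV, positive lobe at half the trough, 0.5–1.5 s), Poisson
placement (1.5 spindles and 1 K-complex per segment) with a 0.25-s
mutual guard and a 2-s guard between K-complexes. Everything is
deterministic per seed, and the truth list is exact.

What the generator does **not** contain: sleep-stage architecture,
EOG/EMG leakage, movement or electrode artifacts, alpha intrusions,
vertex waves (the classic K-complex confound), or amplitude
non-stationarity. A green end-to-end test therefore establishes that
the pipeline recovers its own event model under realistic SNR — not
that it reaches any particular performance on clinical recordings. At
the acceptance operating point (spindle amplitude 5× background RMS,
K-complex troughs 3× background RMS, 20 training + 20 test segments)
the trained pipeline reaches Sen ≥ 0.9 / FDR ≤ 0.2 for both event
types; at that SNR the spindle side of the no-decomposition ablation
can tie the full pipeline (the acceptance direction admits equality),
while the K-complex side degrades clearly because background
delta-band minima survive on the raw trace.

## Degenerate inputs and numerical choices

* Zero or constant segments: the decomposition returns zero components
  and an all-zero objective trace without running the solver.
* Reconstruction tolerance 1e−8 relative (double-precision FFT
  headroom; measured ~1e−15).
* Objective monotonicity tolerance 1e−9 per step after a 5-iteration
  burn-in (FISTA satisfies 0 by construction).
* Plateaus are never extrema (strict inequalities throughout), so
  constant maps and flat traces yield no events.
* Undefined metrics (empty annotation or detection sets) are `NA`, and
  `threshold_sweep` treats an `NA` FDR as 0 false discoveries when
  ranking operating points.
* EDF export quantizes to 16 bits over a symmetric range covering the
  data; round-trip error is bounded by range/2¹⁵.

## Known limitations

* Thresholds are coupled to the CWT normalization and sampling rate;
  retrain when either changes.
* Spindles at the exact 11/16 Hz band edges are structurally
  under-detected (border policy, above).
* The duration deconvolution assumes an approximately Gaussian burst
  envelope.
* Per-segment processing (exact segment independence) means events
  spanning a 30-s boundary are truncated or split.
* The K-complex/vertex-wave distinction is out of scope; on real data
  vertex waves will inflate the K-complex FDR.
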