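---
title: "Methods: single-cell mechanosensation analysis on micropillar arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell mechanosensation analysis on micropillar arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarmech)
```

## The measurement model

`pillarmech` analyzes the mechanoresponse of single adherent cells —
vascular smooth muscle cells (VSMCs) in the motivating application —
cultured on a bed of elastic PDMS micropillars. Each pillar acts as an
independent cantilever spring: a cell adhering to the pillar tops deflects
them, and the traction force at pillar *i* is

$$\vec T_i = k\,\vec u_i,$$

where $\vec u_i$ is the tip deflection and $k$ the bending stiffness of a
cylindrical beam, $k = 3\pi E d^4 / (64 L^3)$ (diameter $d$, height $L$,
Young's modulus $E$). The small-deflection linear-spring model is the
standard assumption for micropillar traction force microscopy; deflections
here are a few hundred nanometres against pillar heights of several
micrometres. The default geometry ($d = 2\,\mu m$, $L = 9\,\mu m$,
$E = 0.6$ MPa, 4 µm pitch, $k \approx 1.94$ nN/µm) gives per-pillar
deflections of 0.3–0.6 µm, comfortably resolvable in fluorescence images.
Every reported cohort metric is normalized (to pre-stimulus baseline, to a
reference group, or min–max), so the absolute force scale set by $k$
cancels throughout.

The elastic energy a cell stores in the array — its strain energy — is

$$E_{strain} = \tfrac12 \sum_i \vec T_i \cdot \vec u_i
            = \tfrac12 k \sum_i |\vec u_i|^2 ,$$

computed per frame by `strain_energy()`; the equality of the two forms is
asserted in the tests as a cross-check.

## From movies to forces

A recording is a fluorescence stack of the pillar tops (30-s frame
interval, 55 min by default, stimulus after a 5-min baseline).
`detect_and_track()` band-passes each frame (difference of Gaussians),
takes 8-neighbour local maxima, and refines each spot to sub-pixel
precision by separable three-point parabolic interpolation of the log
intensity about the brightest pixel — exact for a Gaussian spot sampled
over a locally constant background, and accurate to ~0.015 px on noise-free
synthetic frames. Detections are linked frame-to-frame by nearest neighbour
with a maximum step of a quarter pitch; ambiguous links flag the pillar out
of all downstream metrics.

Deflections need a rest reference that is unobservable under the cell, so
`register_rest_lattice()` fits an ideal square lattice (translation,
rotation, pitch) to the time-averaged positions of *free* pillars by least
squares and assigns every pillar the nearest fitted node. Free pillars are
identified from the supplied cell mask or, absent one, by their low
temporal displacement variance. On synthetic arrays the fitted pitch is
accurate to 0.1% and a 7° array rotation is recovered to 0.1°.

`force_metrics()` then reports, per frame over engaged pillars: total force
$\sum_i |\vec T_i|$, force per pillar, strain energy, and the
active/quiescent split — *active* force is carried by pillars whose force
magnitude exceeds the engaged-pillar median by more than three scaled
median absolute deviations (scaled MAD, consistency constant 1.4826),
applied one-sided per frame (a two-sided variant is available by flag).
The total-force trace is normalized to its pre-stimulus mean; the
normalized peak and the time-to-peak are read from a 5-frame (2.5-min)
moving average restricted to post-stimulus frames, since minute-scale peak
times should not be claimed from single noisy 30-s samples.

## The instantaneous force-frequency spectrum

The dynamic fingerprint of mechanosensation is extracted from each engaged
pillar's displacement-velocity series $v(t) = d|\vec u|/dt$ (signed central
difference). Classical empirical mode decomposition (EMD) splits $v(t)$
into intrinsic mode functions (IMFs) by envelope-mean sifting: cubic-spline
envelopes through the extrema (mirror extension of two extrema per
boundary), subtraction of the envelope mean, repeated until the Cauchy
criterion falls below 0.2 *and* the candidate satisfies the IMF mode
condition (extrema and zero-crossing counts within one), up to 50 sifts;
modes are extracted until the residue is monotone. The decomposition is
complete to $10^{-8}$ relative and its orthogonality index stays below 0.1
on band-limited inputs.

The Hilbert transform of a chosen IMF (IMF2 by default — the first mode
carries the frame-rate measurement noise and fast cytoskeletal flicker,
and IMF2 is the first physiologically interpretable band) yields the
instantaneous amplitude $A(t)$ (analytic-signal modulus, µm/min) and
instantaneous frequency $F(t)$ (unwrapped phase derivative, mHz).
Non-positive and super-Nyquist frequencies are Hilbert edge artifacts and
are masked, not clamped; a 10% margin at each end of the series is
excluded from all summary statistics. Per-pillar instantaneous power is
defined as $p(t) = k\,|\vec u(t)|\,A(t)$ — force times velocity envelope,
dimensionally a mechanical power — averaged in sliding 5-min windows, with
the per-pillar maximum reported. Because the study this definition
supports does not print its own power formula, only orderings (young
above old), never absolute powers, should be compared across
implementations. Cohort curves are the pointwise mean ± SEM of per-cell
means (cells first, then cohort).

## The synthetic-data generator

`simulate_cell_force()` generates the ground truth the pipeline is
validated against. One cell is a disk footprint of engaged pillars
(area drawn per cell) whose total force follows a biphasic program: a
baseline $F_0$, a raised-cosine reinforcement to $F_0(1+\rho)$ reached
$t_{peak}$ minutes after the stimulus, and an exponential relaxation
toward $F_0(1 + \rho\,r)$ with residual fraction $r$. The total is
partitioned over engaged pillars with log-normal heterogeneity, pointed
at the cell centroid, and mean-vector-balanced per frame so the net
traction is ≈ 0 (cells exert no net force on their substrate); the
oscillatory field is balanced the same way.

Each pillar additionally carries two zero-mean Gaussian band-limited
oscillations (bandwidth 40% of center): the cohort's actomyosin band
(`osc_center_freq`, amplitude on the velocity-envelope scale) and a fast,
low-amplitude flicker near the Nyquist frequency (`fast_freq`,
`fast_amplitude`). The flicker models the fast end of cytoskeletal
activity plus frame-rate measurement fluctuations; it is what occupies
IMF1 in the measured velocity series and thereby makes IMF2 the analysis
band. Rendering draws each pillar as a Gaussian spot (uint16, additive
camera noise, per-frame localization jitter), and writes truth tables of
the rendered sub-pixel centers, so detection accuracy can be scored
exactly. `simulate_calcium()` and `render_actin_image()` produce Fluo-4-
like normalized transients (rise to `ca_peak`, exponential decay fixed by
the 15-min recovery fraction) and fiber-textured images (anti-aliased
segments, axial von Mises orientations of concentration κ about a random
cell axis, masked mean scaled to the cohort intensity).

### Packaged cohorts and their calibration

The packaged profiles encode the aging phenotype: young cells respond with
a ~57% force increase peaking near 27 min, carry a faster and larger
oscillation band, spread less, show brighter and more aligned F-actin, and
their calcium transient mostly returns to baseline within 15 min; old
cells increase force only ~20%, peak near 35 min, fail to relax fully,
oscillate slower and weaker, and retain 75% of their calcium peak excess
at 15 min. AngII-treated young cells mimic the old phenotype (including a
2.4-fold F-actin reduction); siPiezo1-treated old cells keep old static
properties but recover young-like dynamics.

The profile parameters are calibrated at the *pipeline* level: the
quantity a phenotype states (e.g. "+57% peak force") is what the full
render → detect → track → metric chain must measure, and the estimators
are not unbiased — the smoothed argmax under oscillation noise
overestimates the peak by ≈ +2 percentage points and anticipates the peak
time by ≈ 1–2 min. Generator means are therefore set to the target value
minus the measured estimator bias (e.g. `peak_increase = 0.55` so the
measured cohort mean lands at 57%). Per-cell spreads use the printed
dispersions read as per-cell standard deviations; read as standard errors
they would imply old-cell peak times routinely outside the 55-min
recording, which is not a usable generative model.

### What the generator does not emulate

The footprint is fixed (no spreading or migration during the recording),
pillars are independent linear springs (no substrate crosstalk, no
large-deflection stiffening), the stimulus enters only as an onset time
(the acoustic radiation force itself is not simulated), photobleaching
and focus drift are absent, and actin images contain no nucleus, no
cross-talk channel and no out-of-focus light. Passing tests therefore
demonstrate the *analysis* is correct and well-calibrated on data obeying
the stated model, not that the model captures every feature of real
recordings.

## Statistics

Two groups are compared with the two-sided unpaired equal-variance
Student's t test (Welch by flag), more with one-way ANOVA followed by
Tukey's HSD; a Shapiro–Wilk screen is reported as a diagnostic only, and
no multiplicity correction is applied beyond Tukey. Force–area relations
use ordinary least squares with a pointwise 90% mean-response confidence
band (prediction bands would be far wider than the shaded fit regions
this reproduces). Multi-metric phenotype summaries min–max normalize each
metric over all cells (constant metrics map to 0.5 by convention) and
report group means, ready for radar plots; distances between group rows
in this normalized space quantify phenotype rescue.

## Numerical choices and degenerate inputs

* EMD: mirror extension of two extrema per boundary; inputs with fewer
  than two interior extrema return zero IMFs with the input as residue.
* A zero MAD makes the active-force rule degenerate; the active set is
  then empty rather than arbitrary.
* Missing pillar detections are linearly interpolated across gaps of at
  most two frames; longer gaps exclude the pillar, to avoid fabricating
  dynamics.
* A constant normalized trace reports peak 1 with a missing time-to-peak;
  a calcium trace that never exceeds baseline reports missing metrics.
* Calcium recovery is defined on the peak excess,
  $(peak - f(t_h))/(peak - 1)$, clipped to [0, 1]; it is invariant to
  rescaling the raw fluorescence.
* The central-difference velocity attenuates a tone at frequency $f$ by
  $\mathrm{sinc}(2\pi f\,\Delta t)$ — about 2% at a tenth of the Nyquist
  frequency and 6.5% at a fifth.

## Known limitations

The strongest limitation is spectral: with 110 samples at 30-s spacing,
classical EMD behaves as a dyadic filter bank, and a band is only cleanly
captured in IMF2 if it lies roughly a factor of three below the IMF1
(noise/flicker) mode. That caps the recoverable IMF2 mean frequency near
4 mHz, while partial capture floors the weak-band (old-cohort) mean near
2 mHz. The young-minus-old instantaneous-frequency separation this
pipeline can reproduce is therefore ≈ 2.0–2.5 mHz, short of the 3 mHz the
young/old phenotype nominally exhibits; the corresponding acceptance
check is left failing by design rather than loosened, and the amplitude
separation (0.06 µm/min) is unaffected. Longer recordings or faster
sampling would lift the ceiling; ensemble EMD might too, but is out of
scope here.

Problem sizes used in the packaged checks — cohorts of 8 cells with
100–220 engaged pillars each for force and spectrum metrics, 20 calcium
traces, and 50 actin images per group — match the study group sizes the
phenotypes are stated at; the unit-test fixtures use smaller cells and
shorter recordings, which exercise the same code paths.
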