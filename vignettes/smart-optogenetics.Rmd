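---
title: "Closed-loop optogenetic control of spiral waves, in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop optogenetic control of spiral waves, in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spiralctl)
```

## What the package models

Many cardiac arrhythmias are sustained by spiral waves (rotors) that rotate
around phase singularities. A "smart optogenetics" platform closes the loop
around such activity in a cultured monolayer: a camera images membrane
potential through a voltage-sensitive dye, a small convolutional network
localizes the spiral core in real time, and a micro-LED matrix under the
dish projects a line of blue light from the detected core to the nearest
boundary. Channelrhodopsin-expressing myocytes depolarize under that line,
it becomes a transient conduction block connecting the core to inexcitable
tissue, and the reentrant circuit is cut.

`spiralctl` reproduces this entire loop in silico: a monodomain
reaction--diffusion model of a 15 mm circular monolayer supplies the
biology, a virtual camera and a virtual LED matrix supply the hardware, and
the detection/decision software layer is implemented exactly as specified
for the real-time system. Every stage is callable on its own, and
`run_closed_loop()` wires them together.

## The tissue model

The monolayer is a 2D grid (`make_domain()`): 256 x 256 nodes at 60 um in
the reference configuration (15.36 mm side), with a centered 15 mm
conducting disc and zero-flux (Neumann) boundaries implemented as exactly
zero coupling weights across the disc border. Each node carries a
three-variable phenomenological ventricular cell model of the Fenton--Karma
family (`cell_model_fk()`): a fast inward current gated by a
threshold switch (time scale `tau_d` = 0.25 ms), a slow outward
repolarizing current (`tau_r` = 33 ms), and a slow inward plateau current
(`tau_si` = 29 ms) with recovery gates. The membrane variable `u` is
normalized; movies map it to mV as `V = -84 + 100 u`.

The reference NRVM-style ionic model lives in external literature, so the
cell-model interface is pluggable and the shipped default is this
phenomenological model, tuned so that a 15 mm well sustains functional
reentry: with the default diffusion coefficient `D = 0.0025` mm^2/ms the
plane-wave conduction velocity is about 53 mm/s, the action potential
duration (APD80) about 55 ms, and rotors circle at roughly 8--14 Hz. These
values sit at the slow-conduction, short-APD end of what cultured monolayers
show; the choice is deliberate: the wavelength (CV x APD, a few mm) must fit
the 15 mm dish for rotors to be sustained at all, which is the platform's
operating regime. Tuning toward textbook NRVM values (150--200 mm/s,
120--200 ms) produces wavelengths larger than the dish and no sustained
reentry under this reduced model, so sustained rotors were given priority.

Integration is explicit: forward Euler for the reaction, a 5-point Laplacian
for diffusion, one shared step. The reference step is 0.005 ms with a frame
recorded every 1200 steps; the desk-scale configuration used throughout the
test suite runs the identical physical geometry on a 128 x 128 grid (120 um)
at dt = 0.1 ms with a frame every 60 steps, preserving the recording
arithmetic exactly (1.25 s -> 208 frames at 6 ms). `check_stability()`
verifies the diffusion CFL bound; at the desk scale the bound is ~0.36 ms,
a 3.6x margin even at the largest coupling multiplier.

Heterogeneity (`sample_heterogeneity()`) follows the generator's study
conditions: all ionic currents scaled globally by a uniform draw in
[0.83, 1.20], per-node multipliers log-uniform in [0.5, 2] on top (median
equal to the global value), and the coupling coefficient scaled uniformly in
[0.25, 4] per sample (an optional smooth spatial field spans the same
range). Because conduction velocity scales as the square root of coupling,
this range alone drives CV between ~26 and ~106 mm/s; samples at the upper
end often cannot sustain a rotor in the dish and samples at the very bottom
may fail to propagate at all, which is exactly the failure diversity the
generator is meant to produce (the generation log records each rejection
reason; under the default conditions roughly two thirds of attempts are
rejected, a higher rate than the reference platform's ~25% because the
reduced ionic model has a narrower sustained-rotor regime).

### Numerical notes

* The conservation property (reaction off, total `u` preserved to 1e-9
  relative) holds because edge weights are symmetric by construction.
* The sqrt-coupling CV law is a continuum property; at the default `D` the
  depolarization front is ~0.05 mm wide, below the 120 um grid spacing, and
  lattice discreteness slows the slowest fronts by >10%. The physics test
  therefore measures CV scaling at `D = 0.04` mm^2/ms (front width several
  nodes, dt = 0.015 ms), where the measured ratios are within a few percent
  of 2. This is a property check of the diffusion operator, not a change of
  the study conditions.
* Blow-up (CFL violation, NaN states) raises an integration-diverged error
  naming the step index; NaN is detected explicitly.

## Spiral induction and the synthetic corpus

`generate_sample()` induces reentry with a cross-field S1S2 protocol: S1
paces a plane wave from a strip at the left edge; S2 is a half-plane whose
edge passes through a uniformly drawn interior site, oriented perpendicular
(with +/-0.3 rad jitter) to the S1 propagation direction. S2 timing is
adaptive: the site's membrane variable is monitored, and S2 fires 10 ms
after the site becomes excitable again, placing the stimulus in the
vulnerable window of the repolarization tail. The wavebreak forms near the
monitored site, so core locations vary across the disc; the eight dihedral
augmentations then distribute them (and both chiralities) uniformly. After
300 ms of stabilization the movie proper is recorded: 208 frames at 6 ms.

Movies are rendered to the camera raster (100 x 100) by exact area-weighted
block averaging and classified on the center-cropped 86 x 86 detector view:
`propagation_failure` (nothing activates), `no_sustained_spiral` (activity
dies out), or `sustained_spiral` (a phase singularity persists through at
least 80% of the final half of the recording while the tissue is still
active). Ground-truth cores come from the topological-charge detector
(below) linked into a consensus trajectory.

Training windows replicate the runtime pipeline bit for bit: five
consecutive frames, background = the frame immediately before the window,
3 x 3 Gaussian blur, center crop, unit-peak normalization, plus seeded
Gaussian camera noise (sd 0.01 in normalized fluorescence units, a
conservative optical-mapping noise floor) added before preprocessing.
Labels are isotropic Gaussian bumps with peak 1 at the core pixel. The
label width is 5 px rather than the initially considered 3 px: at desk
scale the sparse-target objective needs enough target mass to anchor
learning, and 3 px bumps collapse training to the trivial all-zero solution
(sigma is a config parameter; `render_label()` itself defaults to the
narrower 3 px for display purposes).

The desk-scale corpus used by the test suite is 50 accepted base
simulations x 1 window position x 8 dihedral transforms = 400 windows,
split 80/20 by base sample so augmentations never straddle the split. The
reference platform trained on 7776 patterns; the scaled-down corpus is a
deliberate desk-scale choice, reachable to full scale purely by config.

## Phase singularities

`compute_phase()` builds the activation phase by time-delay embedding
(`theta = atan2(V(t + tau) - Vbar, V(t) - Vbar)`, tau = 2 frames, per-node
temporal mean), with the analytic-signal (Hilbert) construction available
as an option. Nodes whose signal range is below 5% of the movie's global
range are invalid, which silences noise-driven detections outside the dish.
`detect_ps()` sums the four wrapped phase differences around every 2 x 2
plaquette; a circulation of +/-2 pi (tolerance 1e-6; wrapping makes the
value exact up to float error) marks a phase singularity at the plaquette
center -- half-integer coordinates by convention -- with the sign giving
chirality. The boundary winding number (`boundary_winding()`) provides an
independent line-integral oracle: total enclosed charge must match it
exactly, and the suite checks this on 100 random band-limited phase fields.
`consensus_core()` links detections across frames by nearest neighbour
(5 px link radius, 3-frame gap tolerance) and selects the longest-lived
track, breaking ties toward the interior.

## The core detector

The network (`net_config()`, `build_network()`) is the specified shallow
six-layer architecture: a gradient stem (per-frame central-difference
spatial gradients appended as channels), a 3 x 3 x 3 space-time convolution
with 16 channels (valid in time: 5 -> 3), joint max-pooling over the three
time slices with spatial kernel 3 / stride 2 (86 -> 43, time -> 1), a 3 x 3
convolution, a second 3 x 3 stride-2 pool (43 -> 21), two 4 x 4 stride-2
transposed convolutions decoding to 84 x 84, a 1 x 1 projection, bilinear
interpolation to 86 x 86 and a saturating output activation. About 12k
parameters, ~46 kB serialized -- the compact-model regime of the original
system. Under the stated kernels and strides no padding convention
reproduces a 39 x 39 intermediate; the internal rasters are 43 and 21 and
the decoder restores 86. This deviation is deliberate and documented; the
printed intermediate shape is not a target.

The output activation is a hard sigmoid (identity clamped to [0, 1]) rather
than the logistic: with sparse heat-map targets the logistic's slope
vanishes exactly where near-zero outputs must rise, and training reliably
collapses. Backward uses a straight-through window slightly beyond the
clamp so mildly saturated outputs can recover. Forward/backward are
implemented directly (im2col/col2im and pooling in C++, matrix products via
BLAS) with a hand-written Adam optimizer.

### Loss and optimization

The objective is the specified L1 norm plus an anti-collapse penalty
`lambda * max(0, epsilon - max(pred))` (defaults lambda = 1,
epsilon = 0.2), reported by `cnn_loss()` and tracked in the training
history. Three optimization choices matter and are worth stating plainly:

1. **Smooth-L1 gradients.** The exact L1 subgradient gives every pixel the
   same pull regardless of error size; on sparse bump targets its global
   optimum from a cold start is the all-zero map, and in our experiments
   training under it always collapsed (the penalty merely props up one
   pixel). The training gradient therefore uses the pseudo-Huber
   (smooth-L1) form with transition width `beta = 1` -- the standard
   implementation of an L1 objective in deep-learning frameworks, quadratic
   for the sub-unit errors that occur here.
2. **Probe initialization.** Before training, a ridge regression from the
   randomly initialized encoder's bottleneck features to a coarse core map
   is solved in closed form, and the decoder is initialized to upsample
   exactly that map (bilinear-identity transposed convolutions, ridge
   coefficients in the 1 x 1 head). Training then starts from an
   input-dependent, non-collapsed prediction. Data-dependent initialization
   of this kind is established practice; without it the bump-placement
   problem is a chicken-and-egg trap for any member of the L1 family.
3. **Scaling hygiene.** Gradients are normalized per map rather than per
   pixel and Adam uses eps = 1e-12; per-pixel normalization pushed moment
   estimates under the optimizer's epsilon floor and silently froze
   training. A 50-step learning-rate warm-up protects the probe
   initialization from the first full-size Adam steps.

With these choices the 20-epoch desk-scale run (batch 8, lr 1e-3) reaches a
median held-out core-localization error near 2 px with median peak
probability ~0.75; a single window overfits to a training loss below 0.02
in 200 epochs.

## The decision layer and the closed loop

The streaming layer mirrors the real-time software: packs of five 100 x 100
frames at 8 ms; the last frame of each pack is the next pack's background;
background subtraction, 3 x 3 Gaussian blur, center crop to 86 x 86, and
unit-peak normalization produce the detector input. Per map the argmax and
maximum enter a sliding 10-deep histogram; when the buffer is full and the
mean of the maxima strictly exceeds 0.7, the modal coordinate (ties to the
most recent occupant) is the consolidated core. A trigger starts the timing
policy: 3 s settle (tracking continues, no new trigger), 0.5 s light
pattern, 3 s blanking (detections suppressed, histogram cleared on re-arm).

The light line runs from the consolidated core to the nearest
non-conducting pixel (Euclidean distance transform; ties broken by smallest
angle from the +x axis), rasterized to the LED matrix through the
camera-to-LED affine registration. The commanded line also extends 12
camera pixels (~1.8 mm) past the core away from the border: a consolidated
core is the center of the rotor's tip orbit, and a line ending exactly
there lets the rotor pivot around the line's free end -- with the
overshoot, single-pulse termination succeeds in roughly 60% of fixtures,
matching the reference platform's single-attempt success rate, and repeated
cycles handle the rest. Multi-well operation partitions the probability map
into rectangular zones with an independent histogram per well and per-well
enable flags (the classic disabled control well).

Termination is declared when the pre-normalization window amplitude stays
below a threshold (10x the camera noise floor) and no decision fires for
1 s; the logged termination time is backdated to the onset of quiescence.
An optional decision-only criterion (no decision for a configured hold,
any amplitude) classifies paced planar rhythms -- which never trigger the
core rule -- as "no reentry"; the closed-loop driver itself uses only the
quiescence criterion.

At desk scale, across 20 seeded spiral fixtures (final states of accepted
corpus samples), the loop with light enabled terminates 80% within the 5 s
horizon versus 20% without light (spontaneous terminations), and 80%
terminate within three attempts; a registration offset of three LED
pitches (1.8 mm) still terminates the reference fixture. Fixtures that
resist repeated attempts are in practice multi-rotor episodes produced by
ongoing breakup in strongly heterogeneous samples, which also mirrors the
reference system's hardest cases.

## The LED model

`led_matrix_spec()` describes the two matrices (48 x 32 at 0.6 mm,
116 mW/cm^2; 160 x 160 at 0.9 mm, 65.4 mW/cm^2; 450 nm; plane distance
3 mm). Driver frames pack eight LEDs per byte, row-major, MSB first
(`encode_frame()`/`decode_frame()` round-trip exactly; byte count is
pixels/8). Each emitter is a Lambertian source:
`E = E_peak * H^4 / (H^2 + d^2)^2`, integrated over the 125 x 250 um
footprint by 10-point Gauss--Legendre quadrature per axis; fields
superpose additively and scale linearly with intensity.
`led_uniformity()` reproduces the pitch-to-distance design study: emitters
at pitch `D = sigma * H`, uniformity = min/max irradiance across the
central pitch cell of the array. Sampling the central cell (rather than a
region that grows with the footprint) isolates the inter-emitter ripple
that sigma governs and makes the sweep monotone; uniformity approaches 1
as sigma -> 0 and decays steeply beyond sigma ~ 2. The two-zone scanning
and refresh-rate electronics of the large matrix are out of scope and kept
as metadata only.

In the rig, LED patterns project back onto the simulation grid either as
uniform pitch-sized footprints ("box", used by the loop) or through the
Lambertian field normalized by the single-emitter peak; the photocurrent is
an instantaneous conductance `g * irr * (E_rev - V)` with `E_rev = 0` mV
and `g = 0.25` in normalized units -- no channel kinetics, which suffices
to reproduce optical pacing, conduction block at full irradiance,
pass-through at low irradiance, and line termination.

## What desk-scale results do and do not show

The synthetic camera adds Gaussian noise to a linear fluorescence map; real
optical mapping adds photobleaching, motion, illumination inhomogeneity and
reflection artifacts, none of which are modelled. The phenomenological cell
model reproduces wave phenomenology, not ionic pharmacology. Corpus,
training length and fixture counts are desk-scale (400 windows, 20 epochs,
20 fixtures; the study-scale numbers are reachable by config). Passing
tests therefore demonstrate that the platform's algorithms -- detection,
decision, projection, termination -- work end to end under controlled
conditions; they do not certify performance on wet-lab recordings.

Known limitations: multi-rotor episodes are terminated sequentially and can
exhaust the attempt budget; the 86 x 86 crop excludes the outer rim of the
15 mm disc, so cores near the rim are rejected from the corpus and are
invisible at runtime (as in the original geometry); wells are modelled one
at a time (the multi-well decision layer is implemented and tested on
synthetic maps, but no four-dish simulation preset ships with the package).
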