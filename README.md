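# spiralctl

Closed-loop optogenetic detection and termination of cardiac spiral waves,
entirely in silico.

Reentrant arrhythmias are sustained by spiral waves (rotors) that circle a
phase singularity. A "smart optogenetics" platform closes a control loop
around them in a cultured monolayer: optical voltage mapping images the
activity, a shallow convolutional network localizes the spiral core in real
time, and a micro-LED matrix projects a blue-light line from the core to
the nearest boundary; channelrhodopsin-mediated depolarization turns the
line into a conduction block that cuts the reentrant circuit. `spiralctl`
reimplements the whole platform as a virtual experiment:

* **Tissue** — a monodomain reaction–diffusion model of a 15 mm circular
  monolayer (zero-flux disc boundary, 256² at 60 µm reference geometry)
  with a pluggable three-variable cell model and per-sample ionic (83–120 %
  global, 50–200 % per cell) and coupling (¼×–4×) heterogeneity.
* **Phase singularities** — Bray–Wikswo-style topological-charge detection:
  phase by time-delay embedding (Hilbert optional), ±2π plaquette
  circulation, consensus-core tracking; verified exactly against a boundary
  winding-number oracle.
* **Synthetic corpus** — adaptive S1S2 induction at random sites, 208-frame
  movies at 6 ms, camera-raster rendering, rejection of failed samples, all
  eight dihedral augmentations, leakage-safe 80/20 split.
* **Detector** — the six-layer space–time CNN (gradient stem, 3×3×3
  convolution, joint time/space pooling, two deconvolutions, ~12k
  parameters ≈ 46 kB) mapping a five-frame 86×86 window to a core
  probability map in [0, 1]; L1 + anti-collapse objective; forward,
  backward and Adam implemented natively (Rcpp + BLAS).
* **Decision layer** — frame packs at 8 ms, background-subtraction
  preprocessing, the 0.7/10-frame histogram trigger, nearest-border light
  line, 3 s / 0.5 s / 3 s timing policy, quadrant multi-well partition,
  quiescence-based termination detection.
* **LED layer** — matrix specs of the two built devices, pixels/8 driver
  byte packing, Lambertian irradiance fields with footprint quadrature, and
  the pitch-to-distance (σ = D/H) uniformity study.

## Worked example

```r
library(spiralctl)

## one virtual monolayer: induce, record, characterize
cfg <- generator_config("desk")          # 128^2 @ 120 um, dt 0.1 ms
s <- generate_sample(seed = 11003, config = cfg)
s
#> <spiral_sample> seed 11003: sustained spiral, core tracked over 103 frames
dim(s$movie$frames)
#> [1] 100 100 208                        # 208 frames, 6 ms apart
measure_spiral_frequency(s$movie86)
#> [1] 12.82051                           # rotor frequency, Hz

## detect the phase singularity directly
ps <- detect_ps(compute_phase(s$movie86))
tail(ps, 1)
#>     frame  row  col charge
#> 206   206 55.5 70.5     -1

## train the core detector on a labelled corpus
corpus <- build_corpus(n_base = 50, seed = 11, config = cfg)
corpus
#> <spiral_corpus> 400 windows (50 base samples x 8 aug), 320 train / 80 val
fit <- core_cnn(corpus, train = train_config(epochs = 20))
fit
#> <core_cnn> 11873 parameters, 20 epochs (best val loss 0.0120)
#>   validation: median core error 2.34 px, median peak 0.73 (n = 80)

## close the loop: light ON terminates, light OFF does not
rig <- virtual_rig(cfg$domain, s$het, cfg$model, s$final_state,
                   dt_ms = cfg$dt_ms)
run_closed_loop(rig, fit, seed = 11003, control = TRUE, horizon_s = 20)
#> <loop_log> 69 events over 5.0 s (control ON): TERMINATED at 4.04 s after 1 attempt(s)
run_closed_loop(rig, fit, seed = 11003, control = FALSE, horizon_s = 5)
#> <loop_log> 68 events over 3.9 s (control OFF): reentry persisted
```

The numbers read as follows: the generator accepted seed 11003 as a
sustained spiral whose core the topological-charge detector tracked through
the tail of the recording; the trained network localizes held-out cores to
a median 2.34 px on the 86×86 raster (≈ 0.36 mm); and with the LED output
enabled the loop triggered on the rotor, waited out the 3 s settle window,
projected one core-to-border line and extinguished the reentry at 4.04 s,
while the paired no-light control still showed reentry at the 5 s horizon.

A thin command-line front end wraps the same functions
(`inst/scripts/spiralctl`): `simulate`, `make-dataset`, `train`,
`run-loop`, `led-uniformity`.

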