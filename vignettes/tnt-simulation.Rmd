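---
title: "Simulating tissue nanotransfection fields and quantifying nerve-repair outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tissue nanotransfection fields and quantifying nerve-repair outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntsim)
```

## Scope

`tntsim` bundles two things that belong to the same study design:

1. a desk-scale, quasi-static simulator of the electric field a
   nanochannel tissue-nanotransfection (TNT) chip imposes on a sciatic
   nerve cross-section, with downstream nanoporation and stochastic
   transfection maps; and
2. the outcome computations used to evaluate peripheral-nerve repair:
   motor unit number estimation (MUNE) from incremental stimulation,
   compound muscle action potential (CMAP) amplitudes, twitch/tetanic
   torque, grip strength, recovery normalization, and fluorescence
   quantification of myelinated axons, axon density, capillary density
   and lineage-marker coassociation.

Because the animal recordings and micrographs themselves are not
reproducible at desk scale, every input is generated by seeded synthetic
generators with embedded ground truth, and the test suite checks
parameter recovery against that truth.

## The chip field model

### Geometry

The cross-section is rasterized onto a 100 x 100 grid (the simulation
resolution used for the field model) spanning 160 x 160 um by default.
Row 1 is the plasmid reservoir (cathode side); the last row is deep
tissue (anode side): the positive electrode sits underneath the nerve,
so anionic plasmid DNA migrates downward into the tissue. Between the
two sit an insulating silicon slab of the nanochannel depth (11 um),
pierced by 20 nanochannels (0.9 um wide, 8 um pitch), and a staircase
rasterization of the conical nanostructures (4-um base, 4.5-um height).
A stated fraction of nanochannels (65% by default) is open, selected by
a seeded uniform draw without replacement; the open count is exactly
`round(open_fraction * n_nanochannels)`.

The 160-um extent is deliberate: at 100 cells it gives 1.6-um cells, the
coarsest isotropic resolution at which a 0.9-um channel still rounds to
one column. A channel that would round to zero columns raises an
explicit resolution error rather than silently vanishing.

The nerve domain is represented as the lower-triangular region of the
grid (`tissue_mask()`, `n(n+1)/2` cells of an `n x n` grid), a wedge of
nerve under the chip edge. The orientation of the triangle is
configurable and a rectangular slab is available as an alternative,
since nothing in the physics forces the triangular shape.

### Potential solve

The potential obeys the quasi-static continuity equation
`div(sigma grad phi) = 0` with Dirichlet electrode rows (cathode 0 V,
anode at the pulse voltage, 200 V default) and insulating side walls.
We discretize with a flux-conservative finite-difference scheme:
inter-cell link conductances are harmonic means of the two cell
conductivities, which is exact for piecewise-constant conductivity in
series. Dirichlet rows are eliminated so the reduced system is symmetric
positive definite, and it is solved directly with the sparse solvers in
the Matrix package. A direct solve was chosen over relaxation or
conjugate-gradient iteration because the insulator-to-saline
conductivity contrast (~1e12) makes unpreconditioned iteration
impractical; the residual of the full system is still checked against
`tol` (default 1e-8) after the solve, and `max_iter` is retained in the
interface for drop-in iterative implementations.

Default conductivities are saline lumen/reservoir 1.4 S/m, nerve tissue
0.5 S/m, and 1e-12 S/m for silicon/silicon-nitride and blocked lumen.
These are implementation defaults in the physiological range, exposed in
the configuration, not measured device values.

The pulse is treated quasi-statically: one solve per protocol, no
membrane charging transient. This is consistent with treating membrane
impedance as effectively infinite for a myelinated peripheral nerve, and
means pulse duration and count do not alter the field map, only the
action-potential bookkeeping below.

### Field magnitude and smoothing

`field_magnitude()` is the central-difference gradient magnitude
(one-sided at edges), in V/m. `smooth_field()` applies a separable
Gaussian (default sigma = 1 cell, truncated at 4 sigma, renormalized)
with reflective boundaries; sigma is configurable because only the fact
of smoothing, not its width, is fixed by the study design.

### A numerical boundary caveat

Two artefacts contaminate tissue cells within a few cells of the chip:
the central difference at a material boundary mixes in the
insulator-interior potential (where essentially the whole applied
voltage drops over ~11 um, |E| ~ 2e7 V/m), and the Gaussian filter
spreads that insulator field a few cells outward. Neither value is a
physiological tissue field. The pipeline therefore evaluates poration on
a guarded tissue domain (`tissue_domain()`): TISSUE-labelled cells
eroded by `ceiling(4 * sigma_smooth) + 1` cells before intersecting the
triangular mask. Without the guard, a fully blocked chip would still
"porate" a rim of boundary cells, which contradicts the physical
expectation (and the tested property) that zero open channels deliver no
field to the tissue.

## Poration, action potentials, transfection

The field couples to the membrane through the steady-state (Schwan)
form with the angular factor at its maximum: `|dVm| = 1.5 |E| r`, with
`r` the coupling radius (default 5 um, configurable — the coupling law
itself is a modelling choice, since only the thresholds are fixed by
the study parameters). The reported magnitude is
`|Vm| = |v_rest| + |dVm|`; membrane orientation is not tracked in 2-D,
so the -200 mV poration threshold is applied as a magnitude, and all
thresholds are inclusive (`>=`). At the defaults, poration therefore
occurs exactly where `|E| >= 130 mV / 7.5 um ~ 1.733e4 V/m`.

Action potentials are a bookkeeping cap, not a conductance model: a
cell whose depolarization exceeds `|v_rest| - |v_ap_threshold|`
(15 mV) fires at most `floor(pulse_duration / refractory)` times per
pulse (10 at the 10-ms/1-ms defaults). Conduction velocity (120 m/s)
and sodium-channel density (600 channels/um^2) are stored and reported
with the membrane parameters but drive no dynamics, because no equation
connects them to the 2-D field map in this model class.

Transfection: per porated cell an efficiency `p ~ N(mean_eff, sd_eff)`
clipped to [0, 1] (defaults 0.6 / 0.15, configurable; the Gaussian
variability is part of the study design, its parameters are not), then
a Bernoulli draw. Everything is reproducible under fixed seeds, and the
realized set is a subset of the porated set by construction.

At the default 200 V the field in the guarded tissue domain exceeds the
1.7e4 V/m poration level everywhere (a parallel-plate estimate alone
gives ~1.25e6 V/m), so the porated fraction saturates at 1 and the
interesting structure is in the field map and the transfection
realization, not the threshold contour. Lower voltages or a higher
poration threshold move the contour into the domain.

## Electrophysiology outcomes

* `cmap_amplitude()` — baseline is the mean of a 5-ms pre-stimulus
  window; baseline-to-peak is the largest absolute deviation within a
  50-ms response window, peak-to-peak is max minus min. Window lengths
  are configurable defaults, chosen as ordinary EMG practice.
* `smup_average()` — the mean of successive differences between
  consecutive incremental submaximal response levels, the standard
  incremental-MUNE convention (10 increments). The series includes the
  subthreshold zero level, so the first recruitment step is one of the
  10 differences; the telescoped form `(last - first)/n` is available
  and identical when no flooring occurs. Negative differences
  (alternation noise) are floored at zero with a warning rather than
  dropped, keeping the increment count fixed.
* `mune()` — maximum CMAP peak-to-peak over average SMUP, reported
  real-valued (the rounded integer rides along as an attribute).
* `peak_torque()` — twitch: max of the baseline-corrected
  single-stimulus response; tetanic: max over the 150 Hz x 1 s train,
  with the mean of the final 200 ms attached as the fused-plateau
  summary.
* `grip_strength()` — mean of three trials (other counts warn).
* `recovery_percent()` — `100 * treated / healthy`, values above 100%
  reported as-is; scale-invariant by construction.

For a pool of N identical units the chain
pool -> increment series -> CMAP trace -> MUNE returns exactly N (tested
for N = 1..50). Under lognormal amplitude heterogeneity (CV 0.3) the
estimator is mildly biased upward (~2% at N = 30 over 100 replicates):
the maximal CMAP sums all units while the average SMUP estimates the
mean from 10 early-recruited units, and the ratio of a sum to a noisy
mean is convex in the denominator (Jensen). The dispersion across
replicates is reported alongside the mean by the acceptance script.

## Image quantification

Channels are max-intensity projected, thresholded (manual value,
negative-control mean + 3 SD, or Otsu when nothing else is available —
the original analyses used manual thresholds that are not published),
and segmented into 8-connected components with a 4-px minimum object
size to suppress speckle. An axon (NF component) "has" myelin when its
overlap with the MBP mask reaches 1 px (an overlap-fraction rule is
selectable); the having/not-having pair partitions the axon population,
so the two percentages sum to 100 whenever any axon is present, and a
zero-axon image returns flagged nulls rather than dividing by zero.
Densities count components whose centroid falls inside the ROI polygon
(centroid-in-ROI prevents double counting across fascicle ROIs) divided
by the polygon area in mm^2; capillaries additionally require >= 1 px
overlap between the CD31 component and the DAPI mask. Coassociation
reports double-positive (A and B, DAPI-confirmed) components as a
percentage of a stated denominator; the default denominator is the
lineage-marker (A) component count and is recorded in the output,
because the percentage is meaningless without it.

## Synthetic data generators

`gen_motor_pool()` draws lognormal unit amplitudes (physiological right
skew; CV exposed, CV = 0 degenerates to identical units) and sorted
uniform recruitment thresholds over the 1-10 mA stimulation range.
`gen_increment_series()` returns cumulative sums of the recruited units
(preceded by the zero level) plus Gaussian measurement noise;
`gen_cmap_trace()` scales a biphasic template so its peak-to-peak equals
the pool's summed amplitude; `gen_torque_trace()` produces a rise-decay
twitch with exact peak or a saturating tetanic envelope whose final
200-ms plateau sits within 1% of the stated peak.

`gen_nerve_image()` paints NF discs (3-5 px radius), MBP annuli from one
pixel inside the axon rim to two outside (so the >= 1 px having rule is
satisfiable by construction), CD31 rings with a DAPI nucleus placed on
the ring, optional GFP co-labelling of a stated vessel fraction plus
GFP-only cells, and scattered extra nuclei, over Poisson background
noise (lambda = 8 against foreground 200). Object centres are placed by
seeded rejection sampling with a minimum separation large enough that no
two objects touch, capped at 10,000 attempts per object (a packing
failure is an explicit generation error). For thresholding generated
channels the tests use the foreground midpoint (100), standing in for
the manual negative-control threshold; the Otsu fallback is exercised
separately on bimodal images, because Otsu on a channel with no true
foreground (e.g. an MBP channel of a fully unmyelinated field) happily
splits the noise.

What the generator does *not* emulate: motor-unit firing statistics and
alternation, realistic EMG shapes, histology textures, uneven
illumination, out-of-focus light, or touching/overlapping objects.
Passing the round-trip tests therefore shows the quantification logic is
correct, not that it is robust to real-microscopy segmentation
ambiguity.

## Problem sizes and determinism

The test suite and acceptance script use the 100 x 100 simulation grid,
100-replicate MUNE ensembles, a 320 x 320 px reference micrograph with
50 axons / 20 myelinated / 12 vessels, and 50 randomized small
micrographs for the partition property; the whole suite runs in well
under a minute. Every stochastic stage takes an explicit integer seed
and restores the caller's RNG state, so identical configurations
reproduce bit-identical maps, summaries and output files (the pipeline
writes the configuration hash and seeds next to every run for exactly
this purpose).

## Worked example

```{r example}
rec <- run_pipeline(default_config())
rec

pool <- gen_motor_pool(30, mean_amp = 0.2, cv = 0, seed = 1)
ser  <- gen_increment_series(pool, n_increments = 10, noise_sd = 0, seed = 1)
cmap <- gen_cmap_trace(pool, noise_sd = 0, seed = 1)
mune(cmap_amplitude(cmap, "peak_to_peak"), smup_average(ser))

img <- gen_nerve_image(n_axons = 50, n_myelinated = 20, n_vessels = 12,
                       seed = 1)
masks <- lapply(img$channels, function(ch) binarize(ch, value = 100))
myelination_fraction(masks$NF, masks$MBP)[c("pct_myelinated",
                                            "pct_unmyelinated")]
```

## Known limitations

* The field model is 2-D and quasi-static: no Joule heating, no pore
  dynamics or resealing, no electrophoretic DNA trajectories, no
  transient membrane charging.
* The coupling radius, material conductivities, smoothing sigma and
  transfection mean/SD are configurable stand-ins where the study
  design fixes only thresholds and protocol.
* At the default protocol the poration map saturates over the guarded
  tissue domain; threshold-contour structure appears only at reduced
  voltage or raised thresholds.
* Image analysis assumes well-separated objects; it does not split
  touching axons and does not measure morphometry (diameters, g-ratio).
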