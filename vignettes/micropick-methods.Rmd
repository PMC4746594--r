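---
title: "micropick: models and methods of the in-silico micropipette cell sorter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{micropick: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropick)
```

# The system being modelled

A computer-vision-controlled micropipette robot isolates single live cells
from a thin (~100 µm) layer of cell suspension kept under oil inside
miniature wells printed into a Petri dish. The robot scans the well as a
mosaic of fluorescent frames, detects labeled cells, visits them with a
30 µm inner-diameter glass micropipette, aspirates each in ~1.4 nl with a
brief vacuum pulse, and ejects it at a destination (another miniature well,
a deposition grid, or a PCR tube) with an overpressure pulse. Because the
suspension is not perfectly still, the robot re-detects every target from a
single fresh image immediately before picking it (*adaptive cell
targeting*) rather than trusting the stale scan coordinates.

`micropick` implements this whole computational stack — synthetic imaging,
detection, targeting, scheduling, and a stochastic digital twin of the
suspension — so the three headline experiments (sparse isolation,
successive enrichment from a 1,000:1 dense culture, and the
microwell-entrapment comparison) can be executed and tested entirely in
silico, with ground truth known exactly.

# Coordinate and unit conventions

All stage coordinates are micrometres, x rightwards along image columns and
y downwards along rows. Pixels are indexed 0-based and a pixel coordinate
refers to its centre, so `stage = pixel * pixel_size + offset` with no
half-pixel terms; `stageFromPixel()`/`pixelFromStage()` are exact inverses.
Volumes are nanolitres (1 nl = 10^6 µm^3), times seconds, speeds µm/min
(the unit the floating-speed measurements are reported in).

# Synthetic imaging

`makePopulation()` draws uniform positions in the arena polygon, with an
optional hard-core minimum separation enforced by dart throwing (retry cap
100 attempts per cell, so generation time is bounded; a grid hash keeps the
neighbour test O(1)). For dense inocula (50,050 cells at ~2,000 cells/mm²
the mean neighbour spacing is ~11 µm, below a cell diameter) the hard core
is disabled by default: overlapping projections are what a settled dense
suspension looks like from above.

`renderFrame()` draws each labeled cell as an isotropic Gaussian spot on a
constant background with i.i.d. Gaussian read noise, clipped to the 8- or
16-bit range. The spot sigma defaults to cell size / 4, chosen so the
detected blob diameter approximates the nominal cell diameter. Unlabeled
cells are invisible in the fluorescent channel (that is what the dye label
means) and appear only as faint rings in phase renders. Rendering is
translation-equivariant and bit-identical under a fixed seed, which the
tests exploit. The generator deliberately omits optical realism — no
vignetting, shading or bleaching kinetics (only an optional per-exposure
brightness decay factor) — so passing detection tests demonstrate the
pipeline's geometry and bookkeeping, not robustness to real microscope
artefacts.

No pixel size is prescribed for the 10× objective, so `FrameSpec` leaves it
configurable; the defaults (1.25 µm/px, 512×512) give fields of view in the
range such cameras produce, and the fresh-targeting frame (160 px) spans
the 200 × 200 µm neighbourhood of one expected target.

# Detection

`segmentFrame()` implements local-variance segmentation: the sample
variance (n−1 denominator, matching `var()`) of each (2r+1)² window,
computed with integral images and symmetric border reflection, is
thresholded at `noise_level² × sensitivity` — so sensitivity 1 means
"variance above the noise floor", a single intuitive knob with consistent
units. Components are 8-connected with holes filled (keeping ring-like
fluorescent cells as one object), then gated on equivalent-circle diameter
(derived from component area — "size" has no other operational definition
here) and mean brightness. Touching cells are *not* split: the sorting
strategy avoids dense fluorescent clusters rather than resolving them.
Whether the original software thresholded variance or standard deviation,
and with what window, is not recorded anywhere; both the window radius and
the threshold semantics are therefore exposed as parameters rather than
hard-coded.

`detectMosaic()` maps tile-local detections to stage coordinates through
the per-tile offsets and merges cross-tile duplicates closer than the
dedup radius, keeping the duplicate farthest from its own tile border
(least edge truncation). `importExternalDetections()` accepts the ImageJ
"Analyze Particles" results dialect (XStart/YStart or X/Y, the BX/BY/
Width/Height bounding box, Mean) so an external segmenter can drive the
rest of the pipeline.

# Targeting

`adaptiveRetarget()` matches the expected (stale) position against fresh
detections within a search radius, nearest first, ties to the brighter
detection then the smaller id. The 50 µm default radius is a design choice:
it covers a few minutes of thin-layer drift (~5 µm/min) with margin while
staying below typical sparse-culture neighbour spacing, which bounds the
wrong-match probability. Lost targets are skipped and logged — a retry
would spend time in which every other target drifts further. The fresh
image uses the same detection parameters as the scan; nothing suggests the
original software did otherwise, and using one parameter set keeps the two
detections comparable.

# Scheduling

`planRoute()` is a greedy nearest-neighbour tour: the path the robot shows
visiting all detected cells is consistent with nearest-first ordering, and
greediness is trivially verifiable. An exact brute-force enumeration is
kept in the test suite as an oracle for n ≤ 7 (greedy equals it on
collinear and grid instances and can never beat it). `emitProtocol()`
expands a plan into the timed valve sequence — per pick: move, descend to
5 µm, −100 Pa vacuum for 10 ms, 1 s ambient equilibration through valve 2,
ascend; per deposit: move, descend, +4,200 Pa for 1 s, ascend — with
absolute timestamps that assume instantaneous moves (motor kinematics are
out of scope). The surface-touch z-calibration has no computational
content and is represented by the approach-height constant.

# The suspension digital twin

**Motion.** Only floating *speeds* were measured, not a process, so a
process had to be chosen: a persistent random walk (run-and-tumble). Each
cell draws one speed from Normal(mean, sd) truncated at zero — the
measured numbers are across-cell statistics — and a heading that is
redrawn uniformly with probability 1 − exp(−dt/τ). The persistence time τ
defaults to 300 s so that 120 s displacement-based speed estimates are
near-unbiased, matching how the speeds were measured; the estimator tests
confirm that pure drift is recovered exactly and that τ ≪ interval gives
the expected undershoot. Presets carry the three measured regimes: open
dish 39 ± 12, oil-covered thin layer 5.4 ± 1.1, thin layer inside a
miniature well 2.3 ± 0.6 µm/min. Boundaries reflect; there is no
z-motion, division or death.

**Capture.** `pickAt()` removes every cell within the capture radius of
the aim point and decrements the medium volume by the 1.4 nl pick volume
(also on a failed pick — fluid is drawn regardless). The sparse preset
uses the measured 34 ± 4 µm sorting resolution (the ±4 as optional
per-pick jitter). The dense preset uses an *effective* 63 µm radius: at
2,000 cells/mm² the observed ~25 co-picked neighbours per target imply
d·π·R² ≈ 25, i.e. R ≈ 63 µm, which is inconsistent with the sparse-mode
34 µm. The package does not try to reconcile the two (plausibly the
crowded aperture entrains a wider neighbourhood); it exposes both presets
and the workflows pick whichever regime applies.

**Deposition.** `depositAt()` scatters carried cells uniformly in a disc
of radius 127 µm around the aim and adds the 147 nl deposition volume.
The spread radius was never measured; 127 µm is calibrated so that
re-picking a deposited cluster at 34 µm retains bystanders at roughly the
observed pass-to-pass thinning rate, and it is documented as a
calibration, not a measurement. Note that for two independent uniform
points in a disc of radius R, P(|U₁−U₂| ≤ a) is slightly *below* the
leading-order (a/R)² (the exact pair-distance integral gives 0.0635 for
a = 34, R = 127 versus (34/127)² = 0.072); the tests assert the simulated
thinning against the exact integral, not the approximation.

**Microwells.** Loading is Bernoulli per well at the preset fill
efficiencies (0.25 fibroblast, 0.54 monocyte; 100 × 100 wells at 100 µm
pitch), capped by the applied-cell count — only aggregate efficiencies
were reported, so a spatially explicit settling model would be invented
detail. `pickFromWell()` yields the trapped cell with probability ~0.5,
else it stays stuck to the PDMS; `expectedUntrappedFraction()` is the
closed form the simulation is checked against.

# Workflow drivers and their statistics

`runSparseIsolation()` composes the full loop — population, scan, greedy
route, per target: advance motion one cycle (20 s, the 3 cells/min sorting
speed), fresh 200 × 200 µm frame, re-detect, correct, pick, deposit into
its own 2 × 2 mm² well. The sparse defaults are 2,000 cells in a
5 × 5 mm² well, moving at the in-well thin-layer speed of 2.3 µm/min —
the sparse experiments took place inside exactly such wells. `recovery_fraction`
is transferred targets / attempted, the quantity the hardware comparison
reports; bystander-free single-cell successes and co-pick contaminations
are reported separately. The observed ~75–80 % recovery aggregates failure
modes that were never itemised (cells sticking inside the pipette, failed
ejection), so the simulator represents them as a single calibrated
`transfer_success_prob = 0.8`; this is a calibration to the reported
recovery, not an independent prediction, and the spec-level tests treat it
as a regression. Disabling adaptive targeting under the same seeds
strictly lowers recovery — that comparison, not the absolute level, is the
scientifically meaningful claim the tests assert.

`runSuccessiveEnrichment()` starts from the 1,000:1 inoculum (50 labeled +
50,000 unlabeled in one well of four) and repeatedly transfers every
labeled cell, with whatever bystanders fall in the capture disc, onto a
500 µm grid in the next well. Pass 1 uses the dense 63 µm effective
radius; later passes re-pick the now-sparse deposited clusters at the
measured 34 µm. (Using the dense radius for every pass would contradict
the calibration that fixes the 127 µm deposit spread; the geometry of
"spread wide, re-pick narrow" is the mechanism that makes enrichment
work.) Purity and bystanders-per-labeled are reported per pass; cell
counts and volumes balance exactly by construction, and the tests assert
both.

`runMicrowellComparison()` loads an array preset with 300,000 applied
cells, selects every occupied well and attempts each pick, reporting the
untrapped fraction, fill fraction and recovery among selected wells.

`estimateFloatingSpeed()` mirrors the measurement protocol: displacements
over non-overlapping 120 s intervals (not the 30 s sampling), averaged per
cell and then across cells.

# Problem sizes, determinism and degenerate inputs

The test suite and the acceptance script run everything at the scale of
the original experiments where that is cheap (50,050-cell enrichment runs,
10,000-well arrays, 300,000 applied cells, 1,000-pick volume ledgers) and
at reduced replicate counts where only Monte-Carlo averaging is at stake
(tens of sessions / a handful of seeds rather than hundreds); each test
states its own tolerance derived from the binomial or Poisson error of the
size it uses. All stochastic functions accept a seed and are bit-stable
under it. Degenerate inputs are defined rather than accidental: empty
populations, frames and plans are legal and produce empty outputs;
infeasible hard-core packings, out-of-arena aim points, over-capacity
destination requests, inconsistent mosaic pixel sizes and malformed
external CSVs raise informative errors.

# Known limitations

* No fluid dynamics: aspiration is a hard capture disc, deposition a
  uniform scatter; no oil–medium interface physics, no z-dimension.
* The dense-regime capture radius and the deposit spread are calibrated
  effective parameters, not measurements; conclusions that depend on their
  precise values (absolute bystander counts, absolute enrichment rates)
  are reproduced by construction, whereas scaling laws (Poisson area law,
  geometric thinning, conservation) are genuine model output.
* Detection is tuned for the synthetic spot model; on real images the
  local-variance parameters would need the same operator tuning the
  hardware workflow relies on.
* Wall-clock throughput is represented only by the per-cycle time
  constant; no claims about sorting speed follow from the simulator.
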