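---
title: "Quantitative anisotropy and generalized deterministic fiber tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative anisotropy and generalized deterministic fiber tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qatrack)
```

## The problem

Deterministic tractography propagates a streamline through a field of
per-voxel fiber orientations and must decide, at every step, which
orientations are trustworthy and where to stop. Most trackers gate on a
voxel-level scalar: fractional anisotropy (FA) from the diffusion
tensor, generalized fractional anisotropy (GFA) from q-ball ODFs, or a
white-matter segmentation. These are *ratios* (or labels): every fiber
orientation in a voxel shares the same value, so a spurious noise peak
cannot be removed without removing the voxel's genuine fibers, and any
added isotropic partial volume (free water, gray matter, crossing
fibers) depresses the ratio and causes premature termination or false
continuation.

`qatrack` implements the alternative this package is built around:
**quantitative anisotropy (QA)**, a *per-orientation* index defined on
the spin distribution function (SDF) reconstructed by generalized
q-sampling imaging (GQI),

$$\mathrm{QA}(\hat a) = Z_0\,\big(\psi(\hat a) - \mathrm{iso}(\psi)\big),$$

where $\psi$ is the SDF, $\hat a$ a peak orientation of $\psi$,
$\mathrm{iso}(\psi)$ the isotropic background estimated as the minimum
sampled SDF value, and $Z_0$ a global constant scaling free-water
diffusion to 1. Because the SDF scales with spin density, QA measures
an *absolute amount* of directional diffusion: adding free water to a
voxel leaves the fiber's QA nearly unchanged while FA and GFA drop, and
each peak carries its own QA, so noisy peaks can be filtered
individually.

## Reconstruction

* **Tessellation** (`build_tessellation`). SDFs/ODFs are sampled on a
  subdivided icosahedron projected to the unit sphere; level $k$ gives
  $10\cdot4^k+2$ vertices. The default level 3 gives 642 directions and
  a mean adjacent-vertex arc of 8.64° (the "9°" angular resolution
  regime). The set is antipodally symmetric; since diffusion is
  symmetric, all functions are evaluated on the 321 hemisphere
  representatives.
* **GQI** (`gqi_sdf`). For each voxel and hemisphere direction
  $\hat u$:
  $\psi(\hat u) = \sum_i S_i\,\mathrm{sinc}\!\big(\sigma\sqrt{6 D b_i}\,
  \langle \hat g_i, \hat u\rangle\big)$,
  with $\sigma$ the diffusion sampling length ratio (default 1.25, the
  recommended value for this reconstruction) and $D$ a fixed free-water
  diffusivity, default $2.5\times10^{-3}\,\mathrm{mm^2/s}$ (body
  temperature). The absolute choice of $D$ is largely absorbed by the
  $Z_0$ normalization. Multiple $b=0$ volumes are averaged first; the
  summation includes the $b=0$ term, which contributes a constant to
  every direction and therefore cancels in $\psi(\hat a) -
  \mathrm{iso}(\psi)$. Small negative sums (possible in extreme noise)
  are clipped to zero.
* **Peaks and QA** (`extract_peaks`, `compute_z0`). A vertex is a peak
  iff its $\psi$ strictly exceeds every 1-ring neighbour after folding
  the sphere onto the hemisphere; plateaus therefore yield no peak
  (deterministic and conservative). Up to `max_peaks` (default 3,
  matching the deepest crossings routinely resolved, e.g. the
  three-way centrum semiovale crossing) are kept in descending QA
  order. $Z_0$ is the reciprocal of the mean maximum-$\psi$ over a
  free-water region. Phantoms pass their known water region; the
  `"auto"` rule takes the top 0.1% of voxels by $\mathrm{iso}$ value.
  This stand-in works when free water has the largest isotropic
  background (the usual in vivo situation, e.g. ventricles); on
  high-b phantoms where fiber voxels retain far more signal than free
  water it can select fiber voxels instead, which rescales QA
  globally — thresholds must then be calibrated on the same scale
  (`calibrate_threshold`), which is required practice anyway because
  comparable thresholds are acquisition-dependent.
* **FA** (`fit_dti`). Log-linear tensor fit, two-pass weighted least
  squares: an OLS pass, then weights equal to the squared *predicted*
  signal. (Weighting by the observed signal biases pure-noise voxels
  toward their upward excursions, producing spurious negative-definite
  tensors; predicted weights restore the familiar behavior in which
  background noise yields high FA.) Negative eigenvalues are clipped to
  zero before $\mathrm{FA} = \sqrt{\tfrac32 \sum_i(\lambda_i -
  \bar\lambda)^2 / \sum_i \lambda_i^2}$, keeping FA in $[0,1]$. Voxels
  with non-positive $b_0$ signal are flagged undefined.
* **GFA** (`qball_gfa`). Analytic q-ball: real even spherical harmonics
  (order 8) fitted to the outermost shell with Laplace–Beltrami
  regularization $\lambda = 0.006$, Funk–Radon transform via
  $2\pi P_l(0)$, ODF samples clipped at zero, and
  $\mathrm{GFA} = \sqrt{n\sum(\psi_i-\bar\psi)^2 / ((n-1)\sum\psi_i^2)}$
  over the hemisphere samples. Order 8 with these defaults is the
  standard deterministic desk-scale choice; grid (multi-b) data use the
  outermost shell and record a warning.

## The generalized tracker

`generate_tractography` implements Euler propagation
$r(s+\Delta s) = r(s) + \Delta s\,\hat u(r(s))$ with a
filtering–selection estimate of the propagation direction. At position
$r$ the up-to-8 voxels of the trilinear cell (voxel centers at integer
coordinates, so the cell is spanned by $\lfloor r\rfloor$ and
$\lfloor r\rfloor + 1$ per axis) are visited; in each voxel the fibers
whose index exceeds the threshold and whose sign-invariant turning
angle is below the angular threshold compete, the smallest-angle fiber
wins (ties go to the larger QA), and is sign-flipped onto the current
direction. The propagation direction is the weight-normalized sum of
the selected fibers with trilinear weights
$f(\Delta r) = (1-|\Delta r_x|)(1-|\Delta r_y|)(1-|\Delta r_z|)$, and
the track terminates when the summed weight of contributing voxels
falls below 0.5. With nearest-neighbour weighting and a vanishing step
the algorithm reduces to FACT (the test suite checks this against an
independent FACT implementation); with a voxel-level index substituted
for QA it reproduces classic scalar-gated streamline tracking — the
comparison design used throughout.

Choices the underlying description leaves open, fixed here:

* **Initial direction at a seed**: the qualifying peak with the largest
  index value (configurable to a seeded random qualifying peak).
* **Tie-break in selection**: equal turning angles go to the larger QA
  — deterministic and favors salient fibers.
* **Step size**: default half the smallest voxel dimension (e.g.
  1.25 mm at 2.5 mm isotropic).
* **Length guards**: tracks shorter than `min_length` (default 40 mm)
  are discarded as fragments; each half-track stops at `max_length`
  (default 300 mm), a runaway guard with no counterpart in the original
  description (closed-loop phantom strands would otherwise cycle
  forever).
* **Seeding**: uniform random voxel plus uniform sub-voxel offset from
  a seeded Mersenne–Twister stream; the seed is recorded in the run
  manifest, so a tractogram is reproducible bitwise. The global R RNG
  state is saved and restored around every seeded operation.
* **Coordinates**: tracking runs in continuous voxel coordinates
  (integers at voxel centers); streamlines are stored in mm with the
  seed point appearing once. TRK output uses the corner-origin voxmm
  convention; TCK stores mm directly; both are float32 little-endian.

## The synthetic phantoms

Physical diffusion phantoms cannot be shipped with a package, so two
simulators generate the corresponding study conditions from Gaussian
mixture compartments (fiber: axially symmetric tensor,
$\lambda_\parallel = 1.7\times10^{-3}$,
$\lambda_\perp = 0.2\times10^{-3}\,\mathrm{mm^2/s}$; free water
$2.5\times10^{-3}$; gel $2.0\times10^{-3}$; non-diffusive material
contributes nothing), with Rician noise formed from two seeded Gaussian
channels of standard deviation $S_0/\mathrm{SNR}$.

* **Crossing phantom** (`make_crossing_phantom`): two bundles crossing
  at 90° in a water bath with non-diffusive inserts, simulated with a
  160-direction $b=4000\,\mathrm{s/mm^2}$ shell plus $b_0$ on a
  $32\times32\times4$ grid (25 mm field of view). Each bundle carries
  fiber fraction 0.4 everywhere — the physical analogue is a capillary
  bundle whose fiber density does not change along its length — so the
  labeled conditions differ only in the surrounding partial volume:
  `single` 0.4 fiber / 0.3 water / 0.3 solid, `a` 0.4 fiber /
  0.6 water, `b` 0.4 + 0.4 crossing fibers / 0.2 water, `c` 0.4 fiber /
  0.6 solid, plus pure `water` and `solid` regions. Default SNR 30.
  Expected behavior (asserted by the tests at these conditions): FA
  drops in `a` and `b` and rises in `c`, while per-peak QA stays within
  20% of the single-fiber reference.
* **Spindle phantom** (`make_spindle_phantom`): six ring-shaped strands
  of decreasing fiber fraction (0.8 down to 0.3) wound at different
  heights around a non-diffusive plastic cylinder embedded in gel,
  2.5 mm voxels, 180 directions at $b=1000$ plus 20 $b_0$, SNR 30.
  The signal-free plastic body is essential: its voxels contain pure
  noise, and noise-only tensor fits produce characteristically high FA,
  so an FA threshold that keeps the weakest strand also admits the
  noisy core, which is exactly the failure mode that produces false
  branching tracks under FA gating while per-orientation QA (which
  scales with spin density and is near zero in the core) does not.
  Strand rings sit on alternate slices, so strand voxel sets are
  disjoint and separated by at least one background slice, and each
  ring is a closed trackable loop of circumference ~157 mm.

What the simulators deliberately do not model: restricted
(non-Gaussian) diffusion inside capillaries, susceptibility and EPI
distortion, T2 shine-through, B1/coil inhomogeneity, and partial-volume
bridging between neighbouring strands. Passing tests therefore show
that the indices and the tracker behave as designed under
Gaussian-mixture partial volume and Rician noise — not that they are
robust to every artifact of acquired data.

## Evaluation machinery

* `calibrate_threshold` sweeps candidate thresholds and scores the
  binarized index map against a reference mask by Dice (Jaccard
  optional); ties go to the smallest candidate. This mirrors picking
  "comparable" thresholds for FA/GFA/QA against a white-matter mask,
  which is necessary because index scales are scheme-dependent.
* `region_distribution` reports per-region quartiles (R type-7 linear
  interpolation); regions with fewer than 4 voxels are flagged
  low-confidence.
* `bootstrap_false_track_ci` gives a percentile bootstrap CI for the
  percentage of tracks labeled false (default 1000 resamples of
  `length(labels)` tracks with replacement) — each track is generated
  independently, so track-level resampling is the natural unit.
* `label_false_tracks` replaces expert judgment on synthetic data: a
  track is false when more than 10% of its points leave the 1-voxel
  dilation of its seed strand's mask. The 10%/1-voxel slack absorbs
  trilinear boundary overshoot without forgiving genuine bridging.

## Numerical notes and problem sizes

Isotropic voxels do not give an exactly constant SDF on a finite
direction scheme: the discrete sum over gradient directions leaves a
quadrature ripple of order $10^{-4}$–$10^{-3}$ relative, which is why
the isotropy test uses a $10^{-3}$ tolerance rather than machine
precision. Peak extraction requires strict inequality over the folded
1-ring, so symmetric plateaus produce no peak rather than an arbitrary
one. The test suite runs the full pipeline at sizes a laptop handles in
minutes: the crossing phantom at $32\times32\times4$ with 161 volumes,
the spindle at $30\times30\times13$ with 200 volumes and 1000 tracks
per tractography (the track count used for the resolution comparison),
three tracking seeds for the QA-vs-FA comparison, and 20 seeds for the
FACT-limit check on a $5^3$ field.

## Known limitations

* The free-water `"auto"` region heuristic can mis-identify free water
  on high-b phantom data (see above); pass an explicit region when the
  geometry is known.
* Anatomy gating is threshold-only; track rejection/continuation rules
  driven by tissue transitions are out of scope.
* Interpolation is trilinear or nearest-neighbour; spline interpolation
  is a known possible refinement and is not implemented.
* Probabilistic tracking, ODF sharpening/deconvolution, eddy/motion
  correction, and registration are out of scope; masks are assumed
  pre-registered.
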