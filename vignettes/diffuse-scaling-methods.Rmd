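---
title: "Methods: reciprocal-space mapping and scaling of diffuse scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-space mapping and scaling of diffuse scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A rotation-series diffraction experiment records photon counts on an area
detector while the crystal rotates in fine φ steps.  Upstream geometry
processing assigns each pixel fractional Miller indices (*h*, *k*, *l*);
`diffusemap` takes over from there.  Counts are accumulated into voxels of
a grid that subdivides the reciprocal unit cell by an integer factor per
axis (default 3, so each Bragg node sits at the center of a voxel spanning
−1/6 to 1/6 in each index).  For every (voxel, sweep) pair the observation
table stores the summed counts *n*, the number of contributing pixels, and
the unweighted mean scan coordinates (φ, detector *x*, *y*).  The mean is
pixel-weighted rather than intensity-weighted because the coordinates
describe where the voxel was sampled, not where photons happened to land;
this also keeps the coordinates stable at low counts.

Corrected intensities follow the Poisson counting model

$$I = \frac{n/\Delta t - r_{\mathrm{bg}}}{\Delta\Omega\,E\,A\,P},\qquad
\sigma = \frac{\sqrt{n}/\Delta t}{\Delta\Omega\,E\,A\,P},$$

where Δ*t* is the cumulative exposure (pixels × exposure per image) and
the background rate is interpolated from a map binned down in frames and
pixels.  The Poisson error of the background itself is strongly reduced by
that binning and is neglected.  Zero-count observations receive σ = 0 and
are excluded from weighted merging; we deliberately do not invent a sigma
floor, as that would bias the weights of real observations.

## Bragg masking

Strong pixels (counts strictly above a threshold, default 20 photons) are
mapped to their wrapped fractional offsets Δhkl ∈ [−0.5, 0.5)³ from the
nearest integer node, and a single trivariate Gaussian (mean and sample
covariance) is fitted per sweep.  A location is masked when its
Mahalanobis distance from the fitted mean is at most *n*σ (default 3), at
every predicted node regardless of intensity.  Strong pixels outside every
ellipsoid cannot be Bragg diffraction and are rejected as outliers.  We
fit the mean rather than pinning it at zero: for unbiased geometry the
fitted mean reduces to zero anyway, and a systematic offset in the
upstream indexing would otherwise displace every mask.  At least 10 points
are required for the covariance; fewer points abort with a message rather
than producing a degenerate ellipsoid.

## Scaling model

Equivalent observations disagree because of experimental artifacts.  Each
observation *i* is modelled as a linear transformation of the true
intensity,

$$I_i = m_i\,I_0(\mathbf h_i) + o_i,\qquad m = a\,b\,d,\qquad o = a\,c\,d,$$

with four physically motivated terms: `b(φ)` the illuminated-volume scale
per sweep, `a(x, y, φ)` absorption of the diffracted beam, `c(s, φ)` a
positive additive background offset, and `d(x, y)` the detector flat
field, fitted globally across sweeps.  Parameters are discrete samples on
1–3D grids; values at observation coordinates come from sparse multilinear
interpolation operators whose rows are non-negative and sum to one.

With the model fixed, the optimal merge is the inverse-variance mean of
the inverse-scaled observations per asymmetric-unit voxel.  With the merge
fixed, each parameter satisfies a linear least-squares problem
`||A x − b||²` (a diagonal matrix of partner factors over σ times the
interpolation operator).  One published form of the offset problem's
target vector contains the product a∘c∘d∘I₀, which is dimensionally
inconsistent with the model above; this package uses the consistent form
`b = (I − a∘b∘d∘I₀)/σ` for the offset fit.

Refinement alternates merge and parameter fits in the order b → c → a → d:
the volume scale first because it has the largest effect, the offset next
so the absorption and detector terms fit residual structure rather than
background leakage.  After each cycle the gauge freedom between an overall
scale and the merged intensity is removed by normalizing the mean of `b`
over all sweeps to 1.  Observations deviating from the merged value by
more than 5 standard errors are rejected between cycles.  Refinement halts
when the relative χ² change falls below 10⁻⁴ or after 20 cycles, and
aborts with diagnostics if χ² rises for three consecutive cycles.

### Regularization

Smoothness penalties use a discrete second-derivative operator along φ and
s axes and a five-point Laplacian over (x, y); both annihilate
affine/planar fields, so regularization never fights a legitimate smooth
trend.  Each penalty weight is re-normalized as
λ = α·‖A‖²_F / ‖B‖²_F, which makes a given α behave consistently across
grid spacings, data sizes and noise levels.  Default α = 1 for all
smoothness terms.

The offset `c` is special: an arbitrary function of *s* can be exchanged
between `c` and `I₀` without changing χ², so the model assumes that for
part of the scan the beam passes through crystal only and the offset is
exactly zero there.  The restraint clips negative control points to zero
and, if all are positive, subtracts a constant so the minimum is zero; an
additional identity-operator penalty keeps the offset as small as the data
allow.  Under the Frobenius re-normalization that identity penalty is
strong per unit α — it competes with the data term itself rather than with
a difference operator — so its default is α = 0.01: large enough to select
the minimal-offset solution along the degenerate direction, small enough
not to shrink a genuine offset (in noiseless simulations the recovered
offset amplitude is within a few percent of truth at this setting, as the
test suite verifies).

### Defaults and grid sizes

| term | coordinates | default grid | regularizers |
|------|-------------|--------------|--------------|
| a | x, y, φ | 5 × 5 × (φ every 10°) | Laplacian (x,y), 2nd deriv (φ) |
| b | φ | every 2.5° | 2nd deriv (φ) |
| c | s, φ | 15 × (φ every 5°) | 2nd deriv (s), 2nd deriv (φ), identity |
| d | x, y | 200 × 200 | Laplacian (x,y) |

All grids are overridable.  The test suite and the acceptance script use a
48 × 48 detector grid for `d`: on the simulator's 100-pixel detector that
spacing (~2 px) resolves the panel-edge ramps while keeping the normal
equations small; the 200 × 200 default mirrors the resolution appropriate
for a physical 2463 × 2527-pixel detector.

## Data-quality statistics

Precision is quantified per resolution shell (default 20 equal-width
shells in *s*; the bundled examples use 10 because the synthetic voxel set
is smaller than a full experiment).  CC½ correlates merges of random
halves, built per voxel by shuffling that voxel's observations and
assigning them alternately, with the starting half chosen by a per-voxel
fair coin so odd counts do not accumulate in one half (per-voxel imbalance
is at most 1).  CC_Friedel splits by whether the operator to the
asymmetric unit is improper; because inversion-related observations tend
to be measured far apart in scan coordinates, this split is sensitive to
uncorrected systematic error, and agreement with CC½ is evidence the
scaling model is adequate.  CC_Rep correlates independently scaled merges
of disjoint sweep groups.  Statistics on empty or nearly empty cells are
reported as missing values, never as zero.

Voxels centered on allowed integer nodes form the "halo" partition (their
central Bragg peak is removed at the pixel level by the ellipsoid mask;
the rest of the voxel retains the intense near-Bragg scattering); all
other voxels are "non-halo".  Shell means and SDs are normalized by a
single constant, the maximum over shells of the non-halo mean.  The
isotropic component subtracted for visualization is the non-halo shell
mean interpolated linearly between shell centers and clamped at the ends;
halo voxels are excluded from the curve because they would bias it upward.

## The simulator

The generator emulates the study conditions of a fine-sliced
room-temperature experiment on a cubic I-centered crystal: cell edge
79.48 Å, grid oversampling 3, Laue group m-3, 50° sweeps of 0.1° frames at
0.1 s per frame, four sweeps of 25 000 observations over 2000 sampled
asymmetric-unit voxels (multiplicity ≈ 50, comparable to a high-redundancy
multi-crystal experiment), and about 100 pixels contributing per
observation, which is the order of magnitude a 3×-oversampled grid yields
on a large pixel-array detector.

The truth field is the sum of

* an isotropic profile rising to a peak near *s* ≈ 0.33 Å⁻¹ (3 Å
  resolution) over a constant floor, in photons · pixel⁻¹ · s⁻¹;
* a band-limited variational field (a fixed set of random cosine waves)
  symmetrized by averaging over the Laue orbit — orbit averaging of
  incoherent waves damps the amplitude by about the square root of the
  group order, so the amplitude is restored after symmetrization; the
  default amplitude puts the non-halo variation at a few percent of the
  mean, matching the subtlety of real diffuse features;
* halo intensity `A_h·g(node)/(Δq² + ε)` decaying as the inverse square of
  the fractional distance to the nearest allowed node, with ε set to the
  square of a typical peak-mask radius (0.102) and a smooth node-to-node
  modulation `g`.

Artifact fields follow the scaling model's own structure: a sinusoidal
illuminated-volume factor per sweep (±30%), a smooth absorption field
(±10% across the detector), a background offset that is exactly zero for
half of each scan — the physical assumption the offset restraint relies
on — and a detector preset with one low-response chip rectangle and
panel-edge attenuation up to 20%.  Expected counts are
`Δt·[(m·I₀ + o)·f + r_bg]` with `f` the product of emitted correction
factors, and counts are drawn Poisson from one seeded generator with
per-sweep sub-streams, so a fixed seed reproduces every table bitwise.

An image mode rasterizes small per-pixel frames through a smooth synthetic
detector-to-reciprocal-space mapping (with optional Bragg spikes at
allowed nodes and a spatially varying background stack) to exercise peak
masking, background binning and chunked integration.  What the simulator
does **not** emulate: real diffraction geometry (Ewald-sphere curvature,
panel gaps), beam divergence and bandwidth, mosaic spread, radiation-damage
time dependence, and Compton scattering.  Passing tests therefore
demonstrate the correctness and statistical behavior of the algorithms
under the stated model, not the handling of geometry pathologies in real
data.

## Numerical choices

* Nearest-voxel ties at exactly half a voxel round half to even per axis —
  deterministic and unbiased.
* The asymmetric-unit representative is the lexicographically greatest
  orbit image; ties at special positions resolve to the first operator in
  the list (proper operators precede improper ones in the shipped
  presets), so the Friedel flag of a representative is always FALSE.
* Background and parameter interpolation clamp outside the axis range
  rather than extrapolate; a query whose entire interpolation weight falls
  on invalid background cells falls back to an equal-weight average of the
  valid cube corners, and is NA only if none exists.
* Binning uses ceiling division and keeps partial edge bins, matching the
  bin counts a 2463 × 2527-pixel detector produces when binned by 20
  (124 × 127).
* Normal equations are solved by sparse Cholesky factorization; a singular
  system raises an error suggesting a larger α rather than silently
  regularizing.
* All intervals involved in binning are half-open; shell edges include the
  right endpoint of the final shell.
* One printed account of the subdivision-3, I-centered grid gives
  "3³ × 2 − 1" diffuse voxels per Bragg peak; exhaustive enumeration (the
  package counts by brute force over one centering period, and the tests
  check an independent oracle) yields 53, which is what `count_diffuse_voxels()`
  returns.

## Problem sizes

The test suite refines 10⁵-observation simulations for the recovery
checks (a few seconds per refinement) and smaller configurations
elsewhere; the full suite runs in a few minutes on one CPU.  These sizes
were chosen so the statistical assertions (recovery correlations above
0.95–0.99, per-shell CC agreement within 0.02) have comfortable margins
under the stated noise model.

## Limitations

Geometry refinement, raw detector formats and absolute intensity scaling
are out of scope; observations must arrive with fractional Miller indices
(the simulator supplies them).  The scaling model is linear in its
parameters — nonlinear parameterizations such as an exponential B-factor
decay term are not implemented.  Error models beyond Poisson counting
(sigma inflation) are not applied.  The project store is a plain-text
directory of TSV tables and JSON metadata designed for transparency and
exact round-trips at these data sizes.
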