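# diffusemap

Reciprocal-space mapping, scaling and merging of macromolecular diffuse
X-ray scattering in R.

Diffuse scattering — the continuous intensity between Bragg peaks — encodes
correlated atomic displacements in protein crystals, but the signal of
interest is a small variation (often below 10%) on a smooth background, so
it is easily corrupted by experimental artifacts: changes in illuminated
volume as the crystal rotates, excess background scattering, absorption of
diffracted X-rays, and detector flat-field errors.  `diffusemap` implements
the numerical core of a rotation-series diffuse-scattering workflow for
crystallographers who want to reconstruct accurate three-dimensional maps
of the diffuse signal and quantify their precision.

## What the package does

* **Voxel grid and symmetry** — photon counts are accumulated on a grid
  that oversamples the reciprocal lattice by an integer factor per axis
  (voxel centers at fractional Miller indices *i/n*, *j/n*, *k/n*).
  Lattice centering supplies the reflection condition (e.g.
  *h* + *k* + *l* = 2*n* for I-centering), and Laue-group operators (the
  `m-3` preset covers space group I2₁3) map every voxel to a canonical
  asymmetric-unit representative with a Friedel flag.
* **Bragg masking and integration** — pixels above a photon threshold are
  fitted with a single ellipsoidal Gaussian in fractional-offset space;
  thresholding the Mahalanobis distance at *n*σ (default 3) masks every
  predicted peak region regardless of intensity, and unexplained strong
  pixels are rejected as outliers.  Integration is an associative merge
  over chunks, so worker count never changes the result.
* **Corrections** — `I = (n/Δt − r_bg)/(ΔΩ·E·A·P)` and
  `σ = √n/Δt/(ΔΩ·E·A·P)`, with the background rate interpolated from a
  binned background map.
* **Scaling** — each observation *i* is modelled as
  `I_i = m_i·I₀(h_i) + o_i` with `m = a·b·d` and `o = a·c·d`, where
  `b(φ)` is the illuminated-volume scale, `a(x,y,φ)` absorption,
  `c(s,φ)` a positive background offset and `d(x,y)` the detector flat
  field (global across sweeps).  Parameters live on 1–3D interpolation
  grids and are refined by regularized alternating least squares against
  the inverse-variance merge, with second-derivative and Laplacian
  smoothness penalties whose weights are re-normalized by a Frobenius
  ratio so one α works across grid sizes.
* **Quality statistics** — random-half (CC½), Friedel (CC_Friedel) and
  independent-crystal (CC_Rep) split correlations per resolution shell;
  halo / non-halo partition and shell mean/SD curves.
* **Maps** — symmetry expansion into a 3D array with an explicit
  missing-value marker, and subtraction of the isotropic (shell-mean)
  component to reveal variational features.
* **Simulator** — a synthetic rotation-series generator with known ground
  truth (isotropic profile peaking near 3 Å, symmetrized variational
  field, inverse-square halos at allowed nodes, all four artifact fields,
  Poisson counting), used to validate every stage end to end.

## Worked example

Simulate two 50° sweeps with all four artifact fields active, refine the
full scaling model and merge:

```r
library(diffusemap)

cfg <- simulation_config(seed = 1, n_sweeps = 2, obs_per_sweep = 10000,
                         n_voxels = 800)
sim <- simulate_experiment(cfg)
fit <- refine_scaling(sim$obs,
                      scale_config(full_model = TRUE, d_xy_points = 32),
                      grid = sim$grid)
print(fit)
#> scaling_fit: 9 cycle(s), chi2 312612 -> 18737.3, converged, 6 outlier(s) rejected
cor(fit$scale$m, sim$obs$true_m)
#> [1] 0.998
head(fit$merged[, c("h", "k", "l", "I", "sigma", "n_obs")], 4)
#>          h         k         l        I     sigma n_obs
#> 1 3.000000 1.6666667 2.0000000 23.06374 0.3965052    17
#> 2 3.000000 2.0000000 0.6666667 30.17314 0.3727403    26
#> 3 3.333333 0.3333333 0.0000000 26.25626 0.3508892    25
#> 4 3.666667 2.3333333 2.3333333 22.22099 0.3409381    24
```

The χ² drops from 312612 (neutral model) to 18737 over 20000 usable
observations — close to the χ² ≈ n expected at convergence — and the
fitted per-observation scale tracks the generator's true `m = a·b·d` with
correlation 0.998.  The merged table lists one row per asymmetric-unit
voxel: fractional Miller indices of the voxel center, the
inverse-variance-weighted intensity, its standard error and the number of
contributing observations.

A complete disk-based workflow (simulate → bin-background → mask-peaks →
integrate → correct → scale → merge → stats → map) is available through
`run_pipeline("myproject")` or the thin CLI wrapper
`inst/scripts/diffusemap-cli`; every stage reads and writes a plain-text
project directory and logs its parameters and seeds.

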