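# spectre

Volumetric, time-resolved reconstruction of electric-field potentials in
the brain from surface EEG, constrained by MRI-derived tissue properties.

## The problem

Conventional EEG "source localization" rests on the quasi-static
approximation: dropping the displacement current
$\varepsilon\,\partial E/\partial t$ from Maxwell's equations reduces the
electric potential to a static Poisson problem driven by a handful of
dipoles, with no time dependence, no tissue-structure sensitivity, and the
long-standing conclusion that deep sources are unreachable from the scalp.
At EEG frequencies, however, conduction and displacement currents are
*comparable* in brain tissue ($\sigma \approx \omega\varepsilon \approx
2.5\times10^{-2}$ for gray matter at 10 Hz), and keeping the displacement
current yields a damped **wave equation** for the potential:

$$\partial_t\!\left(\nabla^2\phi\right) = -\nabla\cdot\Sigma\cdot\nabla\phi,
\qquad \Sigma = \{\sigma_{ij}/\varepsilon\} \;\; [\mathrm{s}^{-1}],$$

with dispersion relation

$$\gamma = \frac{\Sigma_{ij}k_ik_j}{k^2}, \qquad
  \omega = -\frac{(\partial_i\Sigma_{ij})\,k_j}{k^2}.$$

Damping comes from the tissue tensor itself, oscillation from its spatial
*gradient*, and $\omega \sim 1/k$: long waves oscillate fastest and fill
the volume. Waves transverse to the fiber direction are only weakly damped
and can persist — which makes frequency-resolved, fully volumetric
reconstruction from surface electrodes a well-posed physical problem
rather than an ill-posed dipole fit.

The package is aimed at researchers in EEG analysis and computational
neuroimaging who want to work with this wave-physics forward model, its
inverse solver, and the associated mode analytics on standard NIfTI/EDF
data — or to validate the chain end to end on phantoms with known ground
truth.

## What is implemented

* **Tissue model** — labeled voxel grids (template dimensions
  91×109×91 / 182×218×182 / 207×256×215), per-label conductivity and
  permittivity tables, scaled conductivity-tensor fields, the idealized
  anisotropic boundary-layer tensor, layered-sphere phantoms
  (`makeMniGrid`, `buildTensorField`, `boundaryLayerModel`,
  `sphericalPhantom`).
* **Dispersion analytics** — complex plane-wave frequency, homogeneous
  decay rates, persistence ratio, EM reference numbers
  (`wetcowDispersion`, `homogeneousDecayRate`, `persistenceRatio`,
  `emVelocity`, `emWavelength`).
* **Forward solver** — pseudo-spectral RK4 integration of the wave
  equation on periodic grids, reduced boundary-layer branches, point
  sources, trilinear sensor sampling with calibrated noise
  (`evolveWetcow`, `simulateBoundaryLayer`, `sampleSensors`).
* **Inverse solver** — per-frequency-bin fixed-point iteration
  $\hat L\phi^{(k)} = \hat R\phi^{(k-1)}$ on the tissue-aware
  frequency-domain operator, measurement embedding, Cesàro accumulation,
  least-squares sensor rescaling, Hermitian band assembly back to a real
  4D potential (`sensorSpectrum`, `applyRhat`, `initializePhi0`,
  `iterateInverse`, `reconstructBand`).
* **Mode decomposition** — nonnegative space-time coupling matrix,
  eigenmode extraction with equilibrium distribution $\mu^*$, power maps
  scaled to [0,1] and thresholded at 0.6, atlas-region summaries
  (`couplingMatrix`, `espDecompose`, `modePowerMap`, `thresholdMap`,
  `regionPower`).
* **I/O and pipeline** — NIfTI volumes (RNifti), CSV/EDF recordings,
  TSV electrode tables, YAML run configs, a JSON-manifested end-to-end
  pipeline (`runPipeline`) and a CLI (`inst/cli/spectre.R`) with
  `phantom`, `simulate`, `dispersion`, `reconstruct`, `decompose` and
  `regions` subcommands.

## Worked example

A closed-loop phantom: simulate a deep 10 Hz point source in a two-shell
(white/gray matter) sphere on the standard 32³ grid, record 24 surface
sensors, then reconstruct the 8–12 Hz band and find the source (the
forward simulation takes about half a minute on one CPU).

```r
library(spectre)

## gray-matter damping rate from the printed constants (1/s)
homogeneousDecayRate(2.75e-2, 4.07e7 * 8.854187817e-12)
#> [1] 76.31142

## the classic EM estimate: 3000 km alpha wavelength (m)
emWavelength(100, 10)
#> [1] 3e+06

sc <- phantomScenario(seed = 1)
sc$sourceVoxels          # ground-truth source (0-based voxel)
#>      [,1] [,2] [,3]
#> [1,]   14   14   16
sc$recording
#> EEGRecording: 24 channels x 25 samples @ 125 Hz (t0 = 0.16 s)

out <- reconstructBand(sc$recording, sc$field, sc$sensors,
                       inverseConfig(band = c(8, 12)))
out
#> SpectralPotential: 1 bins (10-10 Hz), time domain 25 samples @ 125 Hz

v  <- out@volumes[[1]]                      # complex 10 Hz volume
pk <- arrayInd(which.max(Mod(v)), dim(v)) - 1L
pk                                          # reconstructed peak
#>      [,1] [,2] [,3]
#> [1,]   13   13   17
sqrt(sum((pk - sc$sourceVoxels)^2))         # localization error (voxels)
#> [1] 1.732051
```

The reconstructed potential peaks 1.7 voxels from the true deep source —
a source 9+ voxels from every sensor, the regime in which a quasi-static
dipole model has no depth information at all — and the time course at the
peak is a pure 10 Hz oscillation (out-of-bin energy below 1%). The solver
log (`out@diagnostics`) records 9 fixed-point iterations for this bin.
Over 10 seeded source positions the median localization error is about
1.4 voxels, and a two-source phantom (10 Hz deep, 20 Hz shallow) is
separated cleanly by reconstructing each band.

## Vignette

`vignettes/spectre-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, the numerical choices
(gauge, time step, smoothing, embedding, tolerances), what the synthetic
phantoms do and do not emulate, and known limitations.
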