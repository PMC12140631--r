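---
title: "Methods: tissue-constrained brain-wave modeling and the volumetric EEG inverse"
author: "spectre package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-constrained brain-wave modeling and the volumetric EEG inverse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectre)
```

## The model

Conventional EEG analysis drops the displacement current
$\varepsilon\,\partial E/\partial t$ from Maxwell's equations (the
quasi-static approximation), which reduces the electric potential to a
time-independent Poisson problem driven by discrete dipole "sources".
Keeping the displacement current in an inhomogeneous, anisotropic
conductor instead yields a damped wave equation for the potential,

$$\partial_t\!\left(\nabla^2\phi\right)
  = -\nabla\cdot\Sigma\cdot\nabla\phi,
  \qquad \Sigma = \{\sigma_{ij}/\varepsilon\},$$

where $\Sigma$ is the *scaled conductivity tensor* in units of 1/s.
Substituting a plane wave $\phi \sim e^{-i(k\cdot r - \Omega t)}$ gives the
complex dispersion relation implemented in `wetcowDispersion()`:

$$\gamma \equiv \Im[\Omega] = \frac{\Sigma_{ij}k_ik_j}{k^2},
  \qquad
  \omega \equiv \Re[\Omega] = -\frac{(\partial_i\Sigma_{ij})k_j}{k^2}.$$

The decay rate $\gamma$ is set by the tensor itself; the oscillation
frequency $\omega$ is driven *entirely by its spatial gradient* and grows
as $1/k$: long waves oscillate fastest and span the whole volume. With the
standard low-frequency gray/white-matter constants
($\sigma_{GM}=2.75\times10^{-2}$ S/m, $\varepsilon_{GM}=4.07\times10^{7}
\varepsilon_0$; $\sigma_{WM}=2.77\times10^{-2}$ S/m,
$\varepsilon_{WM}=2.76\times10^{7}\varepsilon_0$), homogeneous damping is
$\sigma/\varepsilon \approx 76$ and $113$ 1/s for GM and WM: far too fast
for persistent rhythms. Persistence comes from structure: in the idealized
fiber-boundary model (`boundaryLayerModel()`, `boundaryLayerTensor()`) a
thin layer with along-fiber profile $u(x)$ and small cross-fiber coupling
$\epsilon$ splits into a damped along-fiber oscillator (decay rate
$a = u(x_0)$) and an *undamped* transverse wave whose frequency is
$b/k$ with $b = u'(x_0)$. `simulateBoundaryLayer()` integrates both
branches spectrally; the tests verify amplitude conservation to 0.1% on
the transverse branch over $aT = 3$ while the parallel branch decays at
$a$ to within 2%.

## Forward solver

`evolveWetcow()` integrates the wave equation pseudo-spectrally on a
periodic voxel grid: the state is $u = \nabla^2\phi$, all derivatives are
Fourier collocation, $\phi$ is recovered with the spectral inverse
Laplacian in the zero-mean gauge (the $k=0$ coefficient is fixed to 0;
potentials are defined up to a constant), and time stepping is classical
RK4 with $\Delta t = 0.1/\max|\Sigma|$. The time step keeps the largest
operator eigenvalue well inside the RK4 stability region, and source-free
runs abort if the $L^2$ norm of $\phi$ ever grows, which it cannot do for
a positive-semidefinite tensor.

Point sources with sinusoidal time courses are additive right-hand-side
terms at single voxels; they are ground-truth fixtures for validation, not
part of the physical model (the model's internal nonlinear source term is
deliberately not implemented). `sampleSensors()` reads the potential at
(possibly fractional) electrode voxels by trilinear interpolation and adds
seeded Gaussian noise.

Two boundary choices deserve comment:

* **Periodic domain with an inert exterior.** There is no physical
  boundary condition at the head surface in the model statement; we use
  periodic boundaries and make the exterior electrically passive.
  Background voxels get $\sigma = 10^{-6}\sigma_{GM}$ with
  $\varepsilon = \varepsilon_{GM}$, so the background *scaled* tensor is
  $10^{-6}\Sigma_{GM}$ — the exterior neither conducts nor damps, and
  wrap-around coupling through it is negligible. (Assigning the vacuum
  permittivity instead would make $\sigma/\varepsilon$ in the background
  thirty times *larger* than in tissue — an aggressive absorber — and
  would shrink the stable time step by the same factor.)
* **Partial-volume smoothing.** `buildTensorField(..., smoothing = w)`
  optionally smooths the label-derived conductivity and permittivity with
  an isotropic Gaussian of sd `w` voxels. Hard label jumps are not
  representable spectrally (Gibbs oscillations in $\nabla\Sigma$), and
  physically a tissue interface is a thin resolved layer — exactly the
  premise of the boundary-layer model. Phantom scenarios default to
  `smoothing = 2`; the plateaus of each tissue compartment are preserved.

## The inverse solver

In the temporal Fourier domain the potential at angular frequency $w$
obeys

$$(\sigma_{ij} - I w \varepsilon\,\delta_{ij})\,\partial_i\partial_j
 \phi_w = \left[I w (\partial_i\varepsilon)\delta_{ij}
 - (\partial_i\sigma_{ij})\right]\partial_j\phi_w,$$

written as $\hat L\phi = \hat R\phi$ with $\hat L = \nabla^2$ and

$$\hat R = \frac{\sigma + I w\varepsilon}{\sigma^2 + w^2\varepsilon^2}
 \left[I w (\partial_i \varepsilon)\,\partial_i
 - (\partial_i\sigma_{ij})\,\partial_j
 - (\sigma_{ij} - \sigma\delta_{ij})\,\partial_i\partial_j\right],
 \qquad \sigma = \tfrac{1}{3}\mathrm{Tr}\,\sigma_{ij}.$$

Here $\sigma_{ij}$ is the *raw* conductivity tensor (S/m) and
$\varepsilon$ the absolute permittivity (F/m): at EEG frequencies
$\sigma \approx w\varepsilon$ (both $\sim 2.5\times10^{-2}$ for gray
matter at 10 Hz), which is precisely why the displacement current cannot
be dropped, and why the prefactor is well conditioned. The three bracketed
terms pick up permittivity gradients (gray/white interface), conductivity
gradients (tissue boundaries), and anisotropy (fiber tracts).

`iterateInverse()` runs the fixed-point scheme
$\hat L \phi^{(k)} = \hat R\phi^{(k-1)}$ per frequency bin, accumulating
$\tilde\phi = \alpha_K \sum_{k=0}^{K}\phi^{(k)}$. Design choices where the
scheme itself is underdetermined:

* **Accumulation weight** $\alpha_K = 1/(K{+}1)$ (a Cesàro average): with
  no prescription for $\alpha_K$, uniform weighting keeps the accumulated
  series bounded when the iterates decay, and the final least-squares
  rescale absorbs any constant factor anyway. Defaults $K = 20$,
  `tol = 1e-6` on the relative $L^2$ change of the accumulated sum;
  divergence (iterate norm growth beyond a configurable factor) is an
  error that reports the iterate count.
* **Convergence regime.** The iteration is a Neumann-type series whose
  gain scales like $|\nabla\sigma| / (|\sigma - Iw\varepsilon|\, w_{layer}
  k)$; it converges when tissue contrasts are resolved over a few voxels
  (hence the partial-volume smoothing) and diverges for hard jumps. On the
  smoothed two-shell phantom it contracts by roughly an order of magnitude
  every one to two iterates and terminates after about ten.
* **Measurement embedding.** How the electrode data enter the iteration
  is not prescribed; `initializePhi0()` isolates the choice. The default
  (`method = "minnorm"`) estimates an interior source distribution
  consistent with the measured bin coefficients: the gain matrix is built
  from the Green's functions of the tissue-aware frequency-domain operator
  (the operator is complex-symmetric, so one forward solve per sensor's
  trilinear interpolation stencil yields a full gain row by reciprocity,
  and the gain then matches the trilinear sampling used on the measurement
  side exactly), the depth-weighted minimum-norm estimate is standardized
  by its resolution variance to remove the superficial bias, and one
  iteratively-reweighted sharpening pass concentrates the estimate onto
  its dominant compact component before the spectral Poisson solve
  produces $\phi^{(0)}$. The reweight uses a tempered depth prior
  ($1/\|a_v\|^{3/2}$, i.e. exponent 3/4 on the squared column norms): the
  standardized map drifts slightly outward for shallow sources while the
  full depth prior pulls inward, and the tempered exponent balances the
  two so deep and shallow sources localize equally well; repeated
  reweighting re-introduces the inward drift, hence a single pass. A
  literal
  alternative (`method = "sensor"`) embeds the coefficients as point
  sources at the sensor voxels; it is simple and local but its $|\phi|$
  maxima sit at the electrodes, so it cannot localize depth.
* **Referencing.** Bin coefficients are re-referenced to the common
  average over channels before embedding (EEG potentials have an
  arbitrary reference).
* **Final scale.** After accumulation, $\tilde\phi_w$ is multiplied by
  the complex least-squares factor matching its sampled sensor values to
  the measured coefficients, so reconstructions are in recording units.

`reconstructBand()` solves every bin in the requested band independently
(no cross-frequency coupling, consistent with omitting the internal source
term), assembles the Hermitian-symmetric spectrum and inverse transforms
to the real 4D potential $\tilde\phi(t,x)$.

## Mode decomposition

`couplingMatrix()` builds $Q_{ij} = \max(0, \mathrm{corr}(\phi_i,
\phi_j))$ over voxel pairs within a neighborhood radius (default 2 voxels;
dense coupling available for small grids). Clipping at zero keeps $Q$
nonnegative so the equilibrium interpretation holds. `espDecompose()`
takes the leading eigenpairs: spatial maps are magnitude-normalized
eigenvectors (signs fixed deterministically), time courses are data
projections, amplitudes are eigenvalues, and the equilibrium distribution
$\mu^*$ is the squared leading eigenvector normalized to sum to one. This
is the operational core of the entropy-based decomposition; higher-order
field interactions and cross-modality coupling are out of scope.
`modePowerMap()` forms the amplitude-weighted sum of squared maps of the
leading $n$ modes rescaled to $[0,1]$ (eigenvalue weighting is our
reading of "weighted"; the rescale makes it invariant to common amplitude
scaling), and `thresholdMap()` applies the conventional inclusive 0.6
threshold, acting on absolute values for signed maps.

## Synthetic study conditions

The validation phantom (`phantomScenario()`) is a two-shell sphere on a
$32^3$ grid: white-matter core (radius 9), gray-matter shell (radius 13),
24 surface sensors on a Fibonacci lattice just inside the outer boundary,
and oscillatory point sources drawn within 4 voxels of the center — deep
positions, at least 8–9 voxels from every sensor, which is the regime a
quasi-static dipole model cannot reach. The two-source discrimination
scenario places its sources at distinct seeded depths (center distances 2
and 7 voxels, at least 5 voxels apart), one frequency each. CSF is omitted from the wave
phantom: its scaled conductivity ($\sigma/\varepsilon \sim 10^9$ 1/s)
equilibrates potentials essentially instantaneously relative to tissue,
so on the simulated time scales it would only pin a boundary value while
shrinking the stable explicit step by seven orders of magnitude. The
forward run covers 0.36 s with the first 0.16 s (about 12 damping
e-foldings) discarded as transient; sensors are sampled at 125 Hz and the
0.2 s analysis window makes 10 Hz (and 20 Hz for the two-source scenario)
exact DFT bins. Sources at 10 Hz, unit amplitude, no sensor noise in the
closed-loop study; `sampleSensors()` noise calibration is tested
separately.

The planted-mode generator (`makePlantedModes()`) uses three
disjoint-support Gaussian bumps with sinusoidal time courses at distinct
frequencies, geometric amplitudes $1, 0.8, 0.64$, and white noise at a
peak signal-to-noise ratio of 10.

What these conditions do **not** emulate: realistic cortical folding and
fiber anisotropy (phantom tensors are isotropic per tissue), electrode
forward-model mismatch, correlated physiological noise, multiple
simultaneous sources within one band, or real scalp/skull conduction.
Passing the closed-loop suite shows the solver chain inverts its own
physics on resolved tissue structure with deep sources; it does not by
itself certify performance on recorded EEG.

## Numerical choices and limitations

* Grid sizes in the shipped tests and acceptance study: $32^3$ phantoms
  (closed loop, decay recovery), a 512-point 1D domain for the
  gradient-frequency check, $10^3$ grids for mode recovery; chosen as the
  smallest sizes at which each measured quantity is grid-converged to
  well inside its tolerance.
* First-derivative operators zero the Nyquist plane (its $ik$ image has
  no conjugate partner for real fields); the Laplacian and its inverse
  keep full $|k|^2$.
* The wave-packet measurement of the gradient-driven frequency uses a
  windowed mode amplitude and a phase fit; the packet width is a
  compromise between spectral purity and sampling a locally uniform
  gradient (the residual error of the shipped configuration is ~0.5%,
  dominated by gradient curvature across the packet).
* Degenerate inputs: all-zero fields cannot choose a default time step
  (explicit `dt` required); zero measurements reconstruct the zero
  volume; constant voxel time courses are decoupled (with a message)
  rather than propagating NaN correlations; eigenmodes are returned only
  up to the positive-eigenvalue rank of $Q$, with a warning if more were
  requested.
* The per-label conductivity/permittivity constants are low-frequency
  averages; frequency dependence across EEG bands is not modeled (one
  constant set per reconstruction band).
* EDF support covers the plain 16-bit subset (no EDF+ annotations);
  per-bin complex volumes are written as paired real/imaginary NIfTI
  volumes.
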