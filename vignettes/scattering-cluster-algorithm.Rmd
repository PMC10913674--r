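---
title: "Dynamical electron diffraction with the scattering cluster algorithm"
author: "dynED"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical electron diffraction with the scattering cluster algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynED)
```

## The physical problem

3D electron diffraction (3D-ED, MicroED) solves crystal structures from
tilt series of diffraction patterns of sub-micrometre crystals.  Because
electrons scatter strongly, measured Bragg intensities deviate from the
kinematic values assumed by standard refinement: intensity is exchanged
dynamically between beams as the electron propagates through the specimen.
Structure refinement improves markedly — down to hydrogen sensitivity in
favourable cases — when the intensities are modelled dynamically, which
requires fast, accurate forward simulation at many specimen orientations
and (for precession) hundreds of incident-beam azimuths.

`dynED` implements two coupled simulation routes for zone-axis-oriented
crystals in the projection approximation (zero-order Laue zone only):

* a **Bloch-wave solver**: exact propagation through the Hermitian
  eigen-decomposition of the structure matrix, used as the reference; and
* the **scattering cluster algorithm (SCA)**: slice-by-slice integration of
  the coupled beam equations with a *cluster-truncated* structure matrix
  and an excitation-error filter, trading an `O(n^3)` eigen-decomposition
  per orientation for a matrix–vector product per slice.

## The model

For a beam set $\{\mathbf g\}$ of ZOLZ reflections, the column vector
$\boldsymbol\varphi(z)$ of diffracted-beam amplitudes obeys

$$\frac{d\boldsymbol\varphi}{dz} = 2\pi i\, \mathbf A\, \boldsymbol\varphi,
\qquad
\boldsymbol\varphi(z) = e^{2\pi i \mathbf A z}\,\boldsymbol\varphi(0),$$

with the structure matrix

$$A_{\mathbf g\mathbf g} = s_{\mathbf g}, \qquad
A_{\mathbf g\mathbf h} = \frac{U_{\mathbf g-\mathbf h}}{2K_n}
\quad (\mathbf g \neq \mathbf h),$$

where $s_{\mathbf g} = -(|\mathbf g|^2 + 2\mathbf K\cdot\mathbf g)/(2K_n)$
is the excitation error (positive inside the Ewald sphere),
$U_{\mathbf g} = \gamma_{\mathrm{rel}} F_{\mathbf g}/(\pi\Omega)$ the
relativistically corrected Fourier coefficient of the crystal potential,
$F_{\mathbf g} = \sum_j \mathrm{occ}_j f_j(|\mathbf g|)
e^{-2\pi i\,\mathbf g\cdot\mathbf r_j}$ the electron structure factor, and
$K_n$ the surface-normal component of the mean-inner-potential-corrected
incident wavevector $K = (k_0^2 + U_0)^{1/2}$.  The extinction distance is
$\xi_{\mathbf g} = K/|U_{\mathbf g}|$.  The problem is purely elastic — no
absorption, no thermal diffuse scattering — so $\mathbf A$ is Hermitian and
Bloch propagation is exactly unitary.

Several of these conventions (the sign of $s_{\mathbf g}$, the placement of
$2\pi$ in the propagator rather than in $\mathbf A$, $\gamma_{\mathrm{rel}}$
entering once through $U_{\mathbf g}$) are fixed jointly: the chosen set is
validated by the closed-form two-beam solution
$I_{\mathbf g}(z) = \sin^2(\pi z s_{\mathrm{eff}})/(1+(s\xi_{\mathbf g})^2)$
with $s_{\mathrm{eff}} = (s^2 + \xi_{\mathbf g}^{-2})^{1/2}$, which the test
suite reproduces to $10^{-10}$, and by the desk-scale numbers below.  Any
alternative scaling would have to co-vary in both solvers and would leave
all intensities unchanged.

## The scattering cluster truncation

Off-diagonal couplings depend only on the difference vector
$\mathbf g - \mathbf h$, and $U_{\boldsymbol\Delta}$ decays (non-monotonically)
with $|\boldsymbol\Delta|$ — rapidly so for light-element organics.  SCA
therefore computes couplings only for the *cluster*
$\{\boldsymbol\Delta : 0 < |\boldsymbol\Delta| \le g_{\max}\}$ and sets the
rest to zero.  Three tunable parameters control the algorithm:

* **`g_max`** (1/Å) — cluster radius.  For the two reference materials the
  converged values are 10|g~100~| (≈1.4 Å⁻¹, TIPS pentacene, 334 couplings)
  and 8|g~010~| (≈1.1 Å⁻¹, rubrene, 734 couplings).  Membership uses a
  closed ball; because radii are usually exact multiples of a reciprocal
  vector, lattice points lying exactly on the boundary are kept inside via
  a $10^{-9}$ relative tolerance — without it, floating-point rounding
  silently drops boundary Friedel pairs and the member counts change by 2.
  Counts with rounded literal radii (0.7/1.4/1.1 Å⁻¹) differ (88/350/724)
  and are exposed through the same function for comparison.
* **`dz`** (Å) — slice thickness of the forward-Euler integration.  The
  default recommendation at normal incidence is 0.2 Å; the first-order
  scheme visibly breaks down (total intensity grows beyond unity) for
  coarse slices, and the integrator aborts with a depth-stamped error when
  the total intensity exceeds 10× its initial value.  We use 0.2 Å for the
  rubrene geometry as well, having checked that halving it does not change
  the SCA-vs-Bloch R factor there.  A classical RK4 option
  (`method = "rk4"`) exists for exploration; it is *not* the default
  because the algorithm under study is defined by the cheap
  one-multiplication Euler step, including its characteristic failure
  modes.
* **`s_max`** (1/Å) — excitation-error filter.  Beams with
  $|s_{\mathbf g}| > s_{\max}$ are removed from the state vector for that
  orientation and reported with zero intensity.  The default rule
  `s_max = (lambda/2) * (g_max/2)^2` is the excitation error at half the
  cluster radius for normal incidence; at 200 kV it evaluates to
  5.8 × 10⁻³ Å⁻¹ (TIPS pentacene) and 3.9 × 10⁻³ Å⁻¹ (rubrene).  The
  two-beam estimate $t = 1/\sqrt{s_{\max}^2 + \xi^{-2}} \to 1/s_{\max}$
  (large-$\xi$, light-element limit) places the first rocking minima at
  172 Å and 256 Å for those values — the thicknesses below which a larger
  `s_max` would be advisable.  Note the thickness figures follow from the
  *2-significant-figure rounded* `s_max` values; the unrounded chain gives
  173 Å for TIPS pentacene.

The cluster potential is computed once per crystal: couplings come in
Hermitian pairs $U_{-\boldsymbol\Delta} = U_{\boldsymbol\Delta}^*$, so only
half are evaluated from the structure (367 of 734 for rubrene).  Across a
tilt or precession series only the matrix diagonal (excitation errors) and
the geometric factor $1/(2K_n)$ are rebuilt — this reuse is the source of
the method's efficiency for large unit cells, and the package asserts the
structural fact behind it: the number of evaluated couplings equals the
cluster size regardless of the beam count (4257 beams would otherwise need
4257² − 4257 = 18,117,792 off-diagonal entries).

## Precession

Precession electron diffraction rocks the incident beam around a cone of
semi-angle $\phi_p$ (2° in the reference setups) and incoherently averages
intensities over azimuths.  `precession_average()` samples the cone at `N`
uniform azimuths (azimuth 0 along **a***), reuses one cluster potential for
all of them, and averages $I_{\mathbf g}(z)$ beam-by-beam — beams are
tracked by Miller index, so no pattern alignment is needed.  Unitarity of
each elastic Bloch run survives the averaging, and the averaged 000
pendellösung is smoother (fewer significant thickness oscillations) than at
normal incidence, as expected when precession suppresses dynamical
transfer.

## Numerical choices

* Cartesian frame: **a** along x, **b** in the x–y plane, right-handed;
  reciprocal basis without the 2π factor, so $|\mathbf g| = 1/d$.
* The specimen normal is the unit vector along direct **c** (flat foil,
  [001] zone), so ZOLZ vectors satisfy $\mathbf g \cdot \mathbf n = 0$
  exactly.
* Eigen-decomposition uses the Hermitian (`symmetric = TRUE`) path after a
  Hermiticity guard; eigenvector phases are fixed (largest component real
  positive) so decompositions are reproducible across linear-algebra
  backends.  Intensities are phase-invariant either way.
* Slice count is `round(thickness/dz)`; the final partial slice is not
  subdivided.  Intensities are recorded every `max(1, round(record_z/dz))`
  slices (default spacing ≤ 10 Å) plus the final depth.
* The SCA inner loop (repeated complex matrix–vector products) is compiled
  (RcppArmadillo); everything else is plain R.
* Fractional coordinates are reduced mod 1 on ingest; CIF symmetry
  expansion de-duplicates atoms closer than $10^{-3}$ fractional distance
  (special positions); occupancies multiply scattering factors.
* Scattering factors ship as a plain-text five-Gaussian parametrization of
  electron atomic scattering factors (International Tables Vol. C, Table
  4.3.2.2 / Peng fits; provenance in the file header), evaluated with
  $q = 1/d$.  A real-space quadrature oracle in the test suite confirms the
  $U_{\mathbf g}$ convention against a direct Fourier integral of the
  superposed atomic potentials to ~10⁻⁴ relative.  No Debye–Waller damping
  is applied: the model is strictly elastic and static.

## What the synthetic generators do and do not emulate

Toy fixtures (`toy_crystal()`) are small deterministic light-element cells
used to exercise every code path: monatomic and rocksalt-like cubics,
an inversion-symmetric pair (real structure factors), and seeded
random-coordinate "organic" cells.  `synthetic_rubrene_like()` combines the
*real* rubrene lattice and unit-cell composition (168 C + 112 H) with
seeded random coordinates, standing in for the published structure whose
coordinates live in an external CIF.

Random coordinates reproduce realistic lattice geometry, beam sets,
excitation errors and total scattering power, but *not* the coherent
molecular arrangement of a real crystal: the distribution of
$|F_{\mathbf g}|$ across reflections differs, and with it the share of
scattering power outside a given cluster radius.  Consequently the
SCA-vs-Bloch R factor at the rubrene geometry (g_max = 8|g~010~|, 1105
beams, depths ≤ 1000 Å) is seed-dependent at the few-percent level —
typically 3–6%, dropping below 1% if the cluster is widened to
12|g~010~| — whereas the real material converges below 5%.  Passing tests
therefore demonstrate solver correctness and the algorithm's convergence
*behaviour*, not quantitative accuracy for any particular real compound.

## Problem sizes

The test suite runs toy beam sets of 2–81 beams for closed-form and oracle
comparisons, one 441-beam and one 1105-beam run for the material-geometry
R factors, and 6–8 azimuth precession averages on reduced grids — chosen as
the smallest sizes at which each scientific property is genuinely
exercised.  The full reference setups (1681/4257-beam grids, 500 azimuths)
are reachable through the same functions.

## Known limitations

* Elastic scattering only: no absorption potential, no phonon/plasmon
  losses; total intensity is conserved by construction.
* Projection approximation: ZOLZ only, flat untilted foil, [001] zone
  (general zones/normals are not implemented).
* Forward Euler is first order; thick specimens need small `dz` or the
  Bloch route.
* The minimal CIF reader targets the small-molecule dialect (cell block,
  symmetry operations as xyz strings, atom_site loop); it does not infer
  space groups from symbols or handle disorder or anisotropic displacement
  parameters.
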