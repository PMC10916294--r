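---
title: "Methods: grids, multipoles, transfer and ADP overlap in tham"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grids, multipoles, transfer and ADP overlap in tham}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tham)
```

## What the package computes

`tham` turns a molecular electron density into per-atom aspherical X-ray
form factors. The pipeline is

1. **Partition**: the molecular density $\rho(\mathbf r)$ is divided into
   Hirshfeld stockholder atoms
   $\rho_a = w_a \rho$, with $w_a$ the ratio of atom $a$'s spherical
   reference density to the promolecule (the sum of all spherical
   references). The weights are positive, sum to one wherever the
   promolecule is positive, and inherit the smoothness of the reference
   atoms.
2. **Projection**: each atomic density, sampled on an atom-centred
   radial × angular product grid oriented by the atom's local frame, is
   projected onto real spherical harmonics, giving radial functions
   $\rho_{lm}(r_i)$ at the radial nodes.
3. **Scattering**: form factors come either from the direct grid sum
   $\sum_p w_p \rho_a(\mathbf r_p) e^{2\pi i \mathbf S\cdot\mathbf r_p}$
   (the oracle; cost proportional to the full grid size per reflection)
   or from Hankel transforms of the radial functions,
   $f(\mathbf S) = 4\pi\sum_{lm} i^l h_{lm}(s) y_{lm}(\hat{\mathbf S})$,
   whose per-reflection cost scales with $(L_{\max}+1)^2$ — the reason
   the multipole route is roughly $N_{\rm ang}/(L_{\max}+1)^2$ times
   cheaper.
4. **Transfer**: atomic multipole densities are averaged per atom type
   and stored in a text databank; a target atom receives its type's
   density re-oriented by its own local frame $M_a$, so its form factor
   is the stored $f$ evaluated at $M_a\mathbf S$.

Conventions, used consistently everywhere: lengths in Å, $|\mathbf S|$
in Å⁻¹, densities in e·Å⁻³; Fourier transform
$F(\mathbf S)=\int\rho\,e^{+2\pi i\mathbf S\cdot\mathbf r}d^3r$, which
puts the $2\pi$ inside the Bessel argument $j_l(2\pi s r)$.

## Synthetic densities: what the generator emulates, and what it does not

Production databanks of this kind are built from quantum-chemistry
wavefunctions. This package deliberately replaces them with **analytic
Gaussian models** so that every stage has a closed-form oracle:

* each element is a *soft-core pseudoatom* — a sum of 2–3 Gaussians whose
  coefficients integrate exactly to the neutral electron count. Core
  exponents are kept moderate (12–14 Å⁻² for C/N/O) so that a 75-node
  radial grid resolves every shell and the valence/deformation features
  that carry the asphericality are not numerically swamped by a
  near-singular core. These atoms are element-*ordered*, not
  element-*accurate*: no comparison with tabulated scattering factors is
  intended or possible.
* every detected bond receives a positive Gaussian deformation lobe at
  its midpoint (exponent 3 Å⁻², width ≈ 0.4 Å) whose amplitude is a
  per-fixture fraction, drawn uniformly from 5–15 %, of the local
  promolecule density at that midpoint — the scale at which real bonding
  deformation densities sit. A *single shared fraction per fixture*
  keeps symmetry-equivalent bonds equivalent, so the point symmetry of
  the toy geometries (C2v water, Cs urea) survives in the total density;
  that is what makes exact self-transfer achievable for the averaged
  types and lets the transfer mechanism be tested at quadrature
  precision.
* three fixture topologies are packaged (`water-like`, `ethanol-like`,
  `urea-like`) with chemically sensible geometries; water is exactly
  C2v by construction.

Consequences for interpreting green tests: passing the closed-form
oracles demonstrates the correctness of the *machinery* — partition,
quadrature, projection, Hankel transform, frames, averaging, transfer,
formats — under densities whose smoothness is representative of valence
features. It does **not** demonstrate accuracy for real wavefunction
densities (sharper cores, exchange effects, lone pairs, crystal-field
polarisation), nor transferability error across genuinely different
chemical environments beyond the mild cis/trans spread the urea fixture
provides.

## Quadrature

* **Radial**: Mura–Knowles "log3" mapping $r = -\alpha\log(1-x^3)$ with
  uniform $x_i = i/(n+1)$ and Jacobian weights. Default $n = 75$; the
  per-element scale is $\alpha = 5\,\text{Å} \times r_{\rm cov}/r_{\rm
  cov}({\rm C})$, clamped to [2.5, 7.5] Å, so hydrogen's compact density
  and a diffuse heavy atom are resolved by the same node count. A
  75-node grid integrates Gaussian-type radial densities to ~1e−9; it is
  *not* meant to resolve integrands oscillating faster than the
  crystallographic range $s \lesssim 2$ Å⁻¹ (the Hankel decay contract at
  $s = 20$ Å⁻¹ is exercised on a 500-node grid for exactly this reason).
* **Angular**: Lebedev–Laikov rules of 6, 26, 110, 302 and 590 points
  (octahedral orbits; exact for spherical harmonics to degree 3, 7, 17,
  29, 41), verified in-code against the moment equations. The 5810-point
  size used for the ADP overlap integral is provided as a
  Gauss–Legendre(70 in $\cos\theta$) × uniform(83 in $\varphi$) product
  rule of the same point count — exact to degree 82, positive weights,
  $\sum w = 4\pi$. It is the package's own construction, not a Lebedev
  table, and for the smooth OC integrands the two are interchangeable at
  target accuracy.
* Angular weights are stored summing to $4\pi$, so harmonic projections
  read as plain weighted sums. Density work defaults to 590 points;
  projection at $L_{\max}$ requires a grid of degree $\ge 2 L_{\max}$ and
  errors out otherwise naming the requirement.

## Spherical harmonics and multipoles

Real (tesseral) harmonics with **orthonormal** normalisation and no
Condon–Shortley phase, evaluated by fully normalised associated-Legendre
recurrences (stable far beyond the $L \le 12$ used here); at the poles
the $m \ne 0$ terms vanish analytically, and the azimuth of a pole point
is irrelevant by the same factor. Orthonormality makes projection
coefficients plain inner products; the canonical index order (l
ascending, m from −l to l) is shared by `harmonic_table()`, the
in-memory coefficient matrices and the databank file.

Canonical storage truncates at $L_{\max} = 7$, which on the packaged
fixtures reproduces the direct form-factor sum to ≲ 2 × 10⁻⁴ of $f(0)$;
the expansion degree is configurable up to 12 (limited only by the
angular grid's exactness). Radial rows are interpolated — for
resampling between grids and for density reconstruction — by an
**8-point local Lagrange stencil in the Mura–Knowles mapping variable**
$x = (1 - e^{-r/\alpha})^{1/3}$, where the source nodes are exactly
uniform. This keeps resampling population drift at ~4 × 10⁻⁸ electrons,
below quadrature error; a cubic spline in $r$ plateaus near 10⁻⁵ on
these grids and was rejected. Resampling onto nodes beyond the source
grid zero-fills them (the multipole model already defines the density as
0 outside its outermost node), but refuses — as genuine extrapolation —
any source whose outermost coefficients have not decayed below 10⁻⁸ of
their row maximum.

## Form-factor evaluation

Spherical Bessel functions use `besselJ(x, l + 1/2)` with a series
switch below $x = 10^{-3}$ to avoid the 0/0 limit for $l \ge 1$. The
$i^l$ factor is accumulated in complex arithmetic (even $l$ real, odd
$l$ imaginary). At $\mathbf S = 0$ the direction is undefined and only
the monopole survives ($j_l(0) = 0$ for $l \ge 1$); an arbitrary
placeholder direction is used there.

Form-factor errors are reported **normalised by $f(0)$** (the atom's
electron population) throughout — the same normalisation used for the
$L_{\max}$ convergence criterion. Pointwise ratios $|\Delta f|/|f|$ are
ill-conditioned for hydrogen, whose form factor decays to ~10⁻² e at
$s = 1.5$ Å⁻¹ while the absolute deviations at stake are ~10⁻⁸ e.

## Typing, frames and the databank

Atom types are a deliberate simplification of production practice:
element plus the sorted multiset of bonded-neighbour elements, with
bonds detected at 1.3 × the covalent-radius sum (Cordero radii) and
inter-atomic distances below 0.4 Å rejected as overlaps. Ring, planarity
and second-shell descriptors are out of scope.

Local frames follow the alcohol-hydroxyl pattern: Z towards the resolved
`z` reference, Y the orthogonal component of the `xz` reference
direction, X = Y × Z (det M = +1 always). Selectors are element symbols
resolved among bonded neighbours first, then second-shell atoms, nearest
first with index as the final tie-break — a deterministic and
rotation-invariant rule. Derived types pick the heaviest neighbour for
Z and the next sorted neighbour (or heaviest second-shell element for
terminal atoms) for XZ. References within 1° of collinearity are
refused with the offending atom indices named.

Per-type averaging is the plain arithmetic mean of instance coefficient
matrices after resampling to the element's canonical radial grid; fewer
than three instances warns, since transferability rests on averaging
over environments. The text format (`THAM-BANK v1`) stores frames,
grids and coefficients at 17 significant digits, giving bit-exact round
trips; parse errors report the offending line.

Untyped atoms are an error by default (`policy = "skip"` drops them with
a warning); there is no spherical-atom fallback, deliberately — a silent
quality downgrade is worse than a loud failure.

## ADP overlap

Along each direction $\hat u$, the two zero-mean Gaussian ray profiles
$c_i e^{-q_i r^2/2}$ (with $q_i = \hat u^T U_i^{-1}\hat u$) cross at most
once for $r > 0$, at $r_c^2 = 2\ln(c_1/c_2)/(q_1 - q_2)$; the radial
pieces of $\int\min(p_1,p_2)$ are closed-form erf/exponential integrals
and only the angular sum is numerical (default 5810 points — far more
than these smooth integrands need, and configurable down for speed).
Edge cases: equal $q$ with unequal prefactors take the smaller-prefactor
profile on the whole ray; equal prefactors (no positive crossing) take
the faster-decaying profile; both equal, either. Agreement with a
brute-force 3D Riemann sum is ~10⁻⁴ over random SPD pairs with
eigenvalues in [0.005, 0.08] Å², an order tighter than the 10⁻³
acceptance band.

$S_{12}$ is evaluated directly from the closed determinant expression;
for any SPD $U$, $S_{12}(U, 2U) = 100\,(1 - 2^{9/4}/3^{3/2}) = 8.45$ to
two decimals, which the test suite and the acceptance script verify to
be independent of the tensor drawn.

ADPs enter as Cartesian tensors; conversion from crystallographic
`U_aniso` (CIF basis) is provided (`u_cif_to_cart()`, using the same
a-along-x orthogonalisation as the coordinate handling) and is the
caller's responsibility to invoke.

## Structure I/O and tsc output

The CIF reader covers the minimal subset the pipeline needs — cell, P1
symmetry, `atom_site` fractional coordinates, optional aniso U loop —
and errors loudly on anything else (non-P1 symmetry, orphan aniso
labels, unknown elements, missing cells). Reflection lists enumerate
all $hkl$ with $|\mathbf S| \le 1/d_{\min}$ (full sphere; optional
Friedel reduction keeps one hemisphere, justified by
$f(-\mathbf S) = \overline{f(\mathbf S)}$), refusing cutoffs that would
generate over 10⁷ candidates. tsc tables carry *static* form factors —
thermal smearing belongs to the refinement program — with complex
values written as `re,im` at 9 significant digits.

## Problem sizes and determinism

The test suite and examples run on the package's production defaults
(75 radial × 590 angular nodes, $L_{\max} = 7$) for all three fixtures;
oracle comparisons use 40–100 random scattering vectors per atom and
50 random tensor pairs for the OC cross-check, sizes at which every
tolerance above has at least an order-of-magnitude margin. All
randomness is seed-controlled; identical seeds give byte-identical tsc
output.

## Known limitations

* Synthetic Gaussian densities only; no interface to wavefunction
  densities, no Slater-type tails, no crystal-field embedding.
* Atom typing ignores bond orders, rings, planarity and anything beyond
  the first shell plus one frame reference; two chemically different
  environments with the same first shell share a type.
* P1 only; symmetry expansion and any refinement loop belong downstream.
* The 5810-point angular rule is a product rule, not the octahedral
  table of the same size (the five smaller sizes are genuine
  Lebedev–Laikov rules).
* Transfer accuracy across *different* molecules is exercised only
  mildly (amplitude-perturbed and multi-environment fixtures); no claim
  is made about real chemical transferability.
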