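---
title: "CTOCD-GRRO/GPRO shieldings: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CTOCD-GRRO/GPRO shieldings: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctocd)
```

## The model

A static homogeneous magnetic field **B** induces, to first order, a
current density in the electron cloud.  With a fixed vector-potential
origin $\mathbf r_0$ this *common-origin* (CO) current splits into a
paramagnetic response term and the Larmor diamagnetic term
$-\tfrac{1}{2c}\rho\,\mathbf B\times(\mathbf r-\mathbf r_0)$ (atomic
units, $c = 137.036$).  The exact sum is independent of $\mathbf r_0$, but
in a finite basis it is not — the gauge-origin problem.

CTOCD distributes the origin continuously, $\mathbf r_0 \to \mathbf d(\mathbf r)$.
For the point of evaluation $\mathbf r$, the angular momentum about
$\mathbf d(\mathbf r)$ decomposes as
$\hat L_{\mathbf d} = \hat L_{\mathbf r_0} - (\mathbf d-\mathbf r_0)\times\hat P$,
so the shifted current needs exactly two families of response quantities:
the three angular-momentum kernels (about an arbitrary internal origin)
and the three linear-momentum kernels.  This package materializes both as
per-point current contributions ($N\times3$ matrices per operator
component), so every scheme becomes a pointwise contraction:

* **DZ1** (ipsocentric, $\mathbf d = \mathbf r$): the diamagnetic term
  vanishes identically and is replaced by the linear-momentum contraction
  with $(\mathbf r-\mathbf r_0)\times\mathbf B$.  The $\mathbf r_0$
  dependence cancels *identically in any basis* — an operator identity,
  not a basis-set limit — which the origin-independence tests check at
  $10^{-8}$.
* **GRRO / GPRO**: $\mathbf d(\mathbf r) = \mathbf r - f(\rho)\nabla\ln\rho$
  with $f=\alpha$ or $f=\beta\rho^{-2/3}$.  The merged diamagnetic term is
  $-\tfrac{f}{2c}\mathbf B\times\nabla\rho$, divergenceless for *any*
  $f(\rho)$ since $\nabla\cdot(\nabla\rho\times\mathbf B)=0$; the extra
  paramagnetic ("delta") term is the linear-momentum contraction with
  $-f\nabla\ln\rho\times\mathbf B$.  Both are strictly proportional to the
  scheme parameter, which is the entire basis of the calibration method.

**Why the $-2/3$ exponent for GPRO.**  The shift $f\nabla\ln\rho$ must be
a length; $\nabla\ln\rho$ carries bohr$^{-1}$, so $f$ carries bohr$^2$ and
a dimensionless $\beta$ forces $f=\beta\rho^{-2/3}$.  The same exponent is
what connects GPRO to the Thomas–Fermi (Harris–Cina) local-density
current: matching $-\tfrac{\beta}{2c}\rho^{-2/3}\nabla\rho\times\mathbf B$
to the Landau-susceptibility current $c\,\nabla\chi\times\mathbf B$ with
$\chi=-e^2k_F/(12\pi^2mc^2)$, $k_F=(3\pi^2\rho)^{1/3}$ gives
$\beta_{\rm HC} = -(3\pi^2)^{1/3}/(18\pi^2) = -0.01741$, available as
`beta_harris_cina()`.  (The same constant can be written
$-1/(6(3\pi^2)^{2/3})$, which invites mis-reading the exponent as $-1/3$;
the $-1/3$ form is dimensionally inconsistent with a dimensionless
$\beta$.)

Shieldings follow from the Biot–Savart law; the sign and prefactor
convention ($-1/c$ with the $1/2c$ already inside the current tensor,
reported $\times10^6$) is pinned by an exactness identity rather than by
convention bookkeeping: for a spherical closed-shell atom the pipeline
must reproduce the Lamb formula $\sigma = 10^6\langle 1/r\rangle/(3c^2)$
from the same density, which the suite enforces to 0.1 ppm and the
closed-form model states to $10^{-13}$.

## The electronic-structure backend

No coupled-perturbed engine is assumed: the package carries a minimal
restricted Hartree–Fock implementation (McMurchie–Davidson integrals over
contracted Cartesian s/p Gaussians, DIIS-accelerated SCF, Boys function
via the regularized incomplete gamma) and solves the coupled-perturbed
equations for purely imaginary perturbations directly as a dense linear
system — for such perturbations only the exchange part of the
two-electron response survives, since the Coulomb contraction of a
symmetric ERI tensor with an antisymmetric density vanishes.  The method
label is therefore `"HF"`; hybrid-DFT reference states are outside the
current scope.  Everything downstream of the perturbed densities (the
CTOCD constructions, quadrature, Biot–Savart, calibration) is agnostic to
how the reference state was produced, and the structural properties the
tests assert — linearity, the DZ1 limit, origin independence, the
divergence-free diamagnetic term, Becke exactness, Lamb, calibration
closure — hold for *any* closed-shell reference in *any* basis.

Built-in bases: STO-3G for H, He, C, N, O, and an even-tempered generator
(`even_tempered_shells()`) for convergence studies.  The ipsocentric DZ1
current converges slowly with basis quality (its momentum-response sum
must resolve $\langle 1/r\rangle$), so the helium tests use an 8s6p
even-tempered set, for which the DZ1 and CO shieldings agree to ~0.1 ppm;
with STO-3G's single s function the helium DZ1 response is identically
zero, which is correct but uninformative.

The SCF backend is validated against an independently written s-only
Hartree–Fock oracle (closed-form s-Gaussian integrals) and the
coupled-perturbed solution against a finite-field *complex* SCF — two
genuinely different routes to the same quantities.

## Quadrature

Shieldings use atom-centred product grids with Becke fuzzy-cell weights
(k = 3 smoothing iterations, Bragg–Slater size adjustment with the
hydrogen radius at 0.35 Å, the standard $|a|\le 1/2$ clip): a 70-point
Gauss–Legendre radial rule mapped by $r = R_m(1+x)/(1-x)$ with $R_m$ the
Bragg–Slater radius, and a 24 × 48 Gauss–Legendre(cos θ) × uniform(φ)
angular product rule.  A product rule was preferred over tabulated
Lebedev grids: it is generated in code to arbitrary order, its
polynomial-exactness degree is transparent, and at these orders it
resolves the $1/|\mathbf r-\mathbf R_N|^2$ Biot–Savart kernel to well
below the 0.05 ppm refinement-stability contract the suite checks
(electron counts reproduce to $10^{-7}$, offset-Gaussian closed forms to
$10^{-8}$ relative at one refinement step up).  All orders are arguments
of `molecular_grid()`.

The per-atom parameter switch is implemented exactly through the linear
split: one pass accumulates, per nucleus and per cell, the DZ1 base
integral and the unit-kernel integral; any parameter assignment is then
an affine combination.  This also makes calibration cheap (one
decomposition, all probe values analytic) and makes the "equal parameters
= undecomposed integral" Becke-exactness statement an identity the tests
verify at $10^{-10}$ ppm.  Cross-talk — nucleus N reading cells of atoms
with a different parameter — is suppressed by the partition weight and
accepted; the suite bounds it by the full parameter sensitivity, and
uniform-parameter integration remains available.

## Numerical choices

* **Density floor** `rho_cut = 1e-10` bohr⁻³: the GPRO factor
  $\rho^{-2/3}$ and $\nabla\ln\rho$ diverge in density tails; below the
  floor the whole shift contribution is zeroed.  The kernel-suppression
  test pins this behaviour.
* **Divergence checks** use central differences.  The CTOCD diamagnetic
  term is divergenceless *analytically*, so the measured residual is pure
  finite-difference truncation, $O(h^2)$ against third derivatives of
  compact Gaussians.  A step of $2\times10^{-4}$ bohr puts the residual at
  ~$10^{-7}$ of the local current scale in the working shell
  ($\rho\in(10^{-6},10^{-4})$) with the roundoff floor still five orders
  below; $10^{-3}$ bohr would leave truncation at a few $10^{-6}$.
* **Probes** for calibration default to $\{0, -0.01\}$ (α) and
  $\{0, -0.05\}$ (β): inside the physically relevant negative range and
  far enough apart for slope stability.  Linearity makes the fitted
  parameter provably independent of the probe pair, asserted at
  $10^{-8}$.
* **Degenerate inputs**: a zero slope between probes raises a
  degenerate-slope error (flagged record in batch calibration); grid
  points coinciding with a nucleus are excluded from the Biot–Savart
  integrand (measure zero) with a log message; isolated atoms are valid
  molecules with empty bond sets; non-negative α/β trigger the
  tropicity warning rather than an error.
* **Dispersion** in parameter tables is the sample (n−1) standard
  deviation; single-member groups report sd = 0.

## Environment typing

Heavy atoms are keyed by element plus the sorted multiset of
nearest-neighbour elements (`C[C,H,H,N]`); hydrogens additionally carry
the second shell (`H[C][C,H,H]`), which is what makes proton parameters
transferable.  Keys are pure connectivity from covalent-radius bond
perception (scale 1.2, overridable): no aromaticity or hybridisation
perception, deliberately — bond-order perception from geometry alone is
fragile.  The known cost is that environments differing only in
hybridisation (e.g. an sp² imidazole-type nitrogen vs an amine nitrogen
with the same first shell) can share a key; richer keys would be needed
where that distinction drives the parameters.

## The F-test construction

The comparison statistic is the classical two-sample variance-ratio test
on two AD/MAD sets, larger variance in the numerator, two-sided p from
the F distribution, significance flagged at a stated level (default 1%).
Whether the sets are paired across molecules is left to the caller (the
test itself is pooled/unpaired); this construction is the package's
choice and is documented rather than hidden.

## What the fixtures do and do not show

The built-in geometries are standard textbook structures and the model
states are closed-form one-electron densities; the study conditions are
RHF with small bases on desk-scale molecules.  Passing tests therefore
demonstrate the *structural* correctness of the machinery — the
properties above are exact mathematics and hold regardless of basis — and
the internal consistency of the calibration chain (planted parameters are
recovered to $10^{-8}$ because linearity is exact).  They do not
demonstrate chemical accuracy of any particular parameter table: absolute
shieldings at STO-3G are far from basis-set-limit values (that distance
is precisely what calibrated parameters absorb, and why slopes here are
steeper than they would be in larger bases), and parameters calibrated on
one class of molecules transfer to chemically similar environments only.
Calibrating against genuine basis-set-limit references requires an
external source of those references.

## Known limitations

Closed-shell RHF references only; s/p bases (no d functions, hence no
second-row-metal or polarization-heavy work); no GIAO/CSGT/PZ reference
implementations; isotropic shieldings only — one scalar parameter can fix
one number per nucleus, and this construction is not profitably extended
to full tensor anisotropy; magnetizabilities are out of scope.
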