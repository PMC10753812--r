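---
title: "Converging correlated interaction energies to the basis-set limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converging correlated interaction energies to the basis-set limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbslab)
```

## The problem

Second-order Møller–Plesset (MP2) correlation energies converge slowly with
the size of the one-electron basis, because a finite basis struggles to
describe the wave function near the electron–electron cusp.  Estimates of
the complete-basis-set (CBS) limit are therefore reached by extrapolation,
on either of two very different basis-set families:

* **Gaussian-type orbitals (GTOs)**: the correlation-consistent cc-pVXZ and
  aug-cc-pVXZ families indexed by the cardinal number $X$ = 2 (D), 3 (T),
  4 (Q), 5, whose energies are extrapolated in $X$;
* **plane waves (PWs)**: a supercell basis fixed by the cell volume
  $\Omega$ and a kinetic-energy cutoff $E_\mathrm{cut}$, whose correlation
  energy is extrapolated in the number of virtual orbitals $n$ and, for
  isolated systems, in the supercell volume.

For weakly bound dimers the two routes must agree in the CBS limit, which
makes the PW side a BSSE-free reference for validating GTO extrapolation
laws (PWs do not depend on atomic positions, so they carry no basis set
superposition error).  This package implements the bookkeeping for both
routes and a homogeneous-electron-gas simulator that exercises the PW
convergence laws end to end at desk scale.

## The scheme registry

Every cardinal-number extrapolation law lives in one registry
(`scheme_registry()`), as a CBS constant plus shifted-power and/or
exponential terms.  Power laws with fixed exponents are linear in their
parameters and are solved exactly when the number of points equals the
number of free parameters; with more points an ordinary least-squares fit
is returned.  The two-point $X^{-3}$ law, for instance, has the closed form

$$E_\mathrm{CBS} = \frac{Y^3 E_Y - X^3 E_X}{Y^3 - X^3},$$

which the fitting engine reproduces to machine precision.

Some design choices deserve a note:

* **Forms with one nonlinear parameter** (the exponential rate in the
  Feller and Helgaker-HF laws, the free power in Martin-$\alpha$) are fitted
  by *profiling*: for every trial value of the nonlinear parameter the
  remaining problem is linear, so the fit reduces to a one-dimensional
  root-find (exact point counts) or Brent minimisation (over-determined
  input) with a $10^{-12}$ objective tolerance, at most 500 objective
  evaluations, and no starting-point or random-restart sensitivity.  At
  three points the exponential rate solves
  $(E_1-E_2)\,(g(X_2)-g(X_3)) = (E_2-E_3)\,(g(X_1)-g(X_2))$ exactly.
* **Fixed exponents**: the Truhlar laws use the published minimal-RMSD
  exponents 3.4 (HF) and 2.2 (correlation), which is what makes them
  usable on two points.  The Wilson laws are the two surviving members of
  the four-parameter shifted-power ansatz
  $E_\mathrm{CBS} + B(X+D)^{-\alpha} + C(X+D)^{-(\alpha+2)}$ under the
  constraints $(\alpha=3, B=0, D=0)$ and $(\alpha=4, C=0, D=1)$.  The
  Varandas laws use the $X - 3/8$ abscissa shift; `var34_fit` ties its
  fourth-order coefficient to the third-order one (ratio 1, a registry
  calibration constant) so that two points suffice.
* **Rovibi laws**: `rovibi34` combines the principal-expansion $X^{-3}$
  leading term with a $(X-\tfrac12)^{-4}$ next-order term; `rovibi45` uses
  $(X-\tfrac12)^{-4} + (X-\tfrac12)^{-5}$.  The $-\tfrac12$ shift averages
  the highest angular momentum carried by the basis, $L = X-1$ for
  hydrogen and $L = X$ for first-row atoms.  Both laws are members of the
  generic shifted-power family that `enumerate_generic_family()` builds
  ($\alpha,\beta \in \{3,4,5,6\}$, default shift grid
  $\{-1, -\tfrac12, 0, +\tfrac12\}$), and the family search is how such
  laws are found in the first place.
* **Component routing**: HF energies converge exponentially and are best
  treated by `helgaker_hf`; correlation energies follow power laws.
  `recommended_scheme()` encodes the practical rules: `helgaker_corr_x3`
  for a DT pair, `martin4` for TQ/Q5 pairs, `rovibi34` for three or more
  points.
* **Degenerate inputs**: duplicate $X$ values are an input error (never
  averaged); constant series return the constant with all coefficients
  exactly zero; every scheme is translation-equivariant, so extrapolating
  per subsystem and differencing equals extrapolating differences for
  linear forms at exact point counts.

```{r}
pts <- gen_cardinal_series("rovibi34", E_CBS = -20, coefs = c(1.2, 0.8), X = 2:4)
extrapolate(pts, "rovibi34")
```

## Counterpoise bookkeeping

For a dimer $AB$, `interaction_energies()` computes
$\Delta E_\mathrm{uncorr} = E_{AB} - E_A^{\{A\}} - E_B^{\{B\}}$,
$\Delta E_\mathrm{CP} = E_{AB} - E_A^{\{AB\}} - E_B^{\{AB\}}$ (monomers in
the full dimer basis with ghost functions on the partner), and their mean
$\Delta E_\mathrm{half}$.  `deviation_stats()` provides the comparison
statistics used for basis-set benchmarking: MAE, mean signed deviation, the
*signed* value of the largest-magnitude deviation (an absolute variant sits
behind a flag), and box-plot outliers beyond 1.5 times the interquartile
range.  Quartiles use linear interpolation between order statistics
(type 7), stated explicitly because the outlier rule inherits it.
Monomer geometries are assumed frozen; deformation energies are out of
scope.

## Plane-wave virtual-space extrapolation

The PW correlation energy converges like $1/N$ in the basis size, so the
partial sums $E_{c,n}$ over virtual orbitals follow

$$E_{c,n} \simeq \alpha + \beta\, n^{-1}
  \quad\text{or equivalently}\quad
  E_{c,n} \simeq \alpha + \beta'\, \varepsilon_n^{-3/2},$$

since the count of states below an eigenvalue $\varepsilon$ grows like
$\varepsilon^{3/2}$.  `virtual_fit()` fits the line; the intercept
$\alpha$ is the CBS estimate.  `windowed_average()` implements the
production protocol: fit every window ending at $n_\mathrm{max}$ with at
least `min_points` (default 3) entries, keep the windows on which the
linear law holds, and report the mean and standard deviation of the
accepted intercepts.  "The law holds" needs a quantitative proxy; the
default is $r^2 \ge 0.99$ together with a maximum internally studentized
residual of 3, both configurable.  This gate is meant for long
fixed-increment series (increments of 100 virtual orbitals, $n$ up to
$10^4$); the HEG demonstration below deliberately disables it.

Volume extrapolation (`volume_fit()`) defaults to linearity in
$1/\Omega$ — the first-order finite-size correction, matching the
abscissa on which such convergence plots are linear — with the exponent
configurable.

## Coulomb kernels for isolated systems

In reciprocal space the two-electron integrals reduce to a diagonal
quadrature $E = \Omega \sum_\mathbf{G} \rho_A^*(\mathbf{G})\,
\Phi(\mathbf{G})\, \rho_B(\mathbf{G})$ over densities stored as Fourier
series coefficients of $\Omega$-normalised plane waves — the $1/\Omega$
factors are carried by the quadrature, in one documented place, and pinned
down by analytic Gaussian tests.  The bare periodic kernel
$\tilde\Phi(\mathbf{G}) = 4\pi/G^2$ is singular at $\mathbf{G}=0$; three
treatments are provided:

* `bare_zeroed` simply drops the $\mathbf{G}=0$ component (uniform
  compensating background), which converges slowly with box size;
* `bap` replaces the singular component by the auxiliary-function value
  $\chi = 2\alpha\Omega/\sqrt{\pi} - \sum_{\mathbf{G}\ne 0}
  4\pi e^{-G^2/4\alpha^2}/G^2$, the difference between the self-energy of
  an isolated Gaussian charge and its periodically repeated analogue in a
  background.  The resulting total-energy correction is strictly linear in
  the electron count, so it cancels exactly in interaction energies — it
  accelerates total-energy convergence but cannot improve energy
  differences;
* `mt` (Martyna–Tuckerman) splits $1/r = \mathrm{erfc}(\alpha r)/r +
  \mathrm{erf}(\alpha r)/r$ and assembles
  $\Phi_\mathrm{MT}(\mathbf{G}) = 4\pi(1 - e^{-G^2/4\alpha^2})/G^2 +
  \bar\phi_\mathrm{lr}(\mathbf{G})$, where $\bar\phi_\mathrm{lr}$ are the
  Fourier-series components of the long-range part sampled on a centred
  minimum-image mesh of the cell and transformed with an FFT.  The two
  singular pieces cancel analytically and only their finite difference is
  kept, which decouples the cluster from its periodic images: the kernel
  converges to the isolated $1/r$ interaction once the box spans roughly
  twice the density extent.

The splitting parameter defaults to $\alpha = 7 / L_\mathrm{min}$
(`alpha_L_target = 7`); a warning is issued below $\alpha L = 5$, where the
long-range part stops fitting in the box.  The real-space mesh defaults to
the smallest even mesh resolving the kernel grid, and an explicit aliasing
check rejects coarser meshes.  Only orthorhombic (including cubic) cells
are supported.  On the Gaussian validation fixture (two unit charges of
width $\sigma = 1$ bohr at separation 4 bohr in a 24-bohr cell, 50 Ha
cutoff) the MT pair energy matches $\mathrm{erf}(2)/4$ to $2\times10^{-11}$
hartree and the self-energy matches $1/(2\sigma\sqrt{\pi})$ to machine
precision.

## The homogeneous-electron-gas simulator

The Fock eigenstates of the finite-cell homogeneous electron gas are pure
plane waves, which makes it the natural laboratory for the $1/N$
convergence law: no SCF step, exact momentum-conserving pair densities
(each occupied–virtual product has exactly one nonzero Fourier component),
and an exactly enumerable MP2 sum.  `heg_model()` fills the lowest closed
shells (valid electron counts 2, 14, 38, ... for cubic cells — anything
else would leave a partially filled degenerate shell and an open-shell
state); eigenvalues include the finite-cell exchange sum by default, since
MP2 denominators are Fock eigenvalues (a kinetic-only mode is kept for
debugging).  `mp2_correlation()` streams the partial sums $E_{c,n}$, each
equal to the exact MP2 energy of the virtual space truncated at $n$;
truncations that would split a degenerate shell are completed to the shell
boundary, so the series is independent of enumeration order.  The series
is non-positive throughout, and for every small basis it matches an
independent quadruple-loop oracle to $10^{-12}$ relative.

`cbs_demo()` ties the modules together: extrapolating the small-cutoff
series (both abscissa modes) lands closer to the large-cutoff direct value
than the small model's own truncated sum, because HEG virtuals are the
same plane waves in any basis — the small series is a prefix of the large
one, and its $1/n$ intercept estimates the common limit.  For these
shell-resolved series the demo averages over *all* tail windows
(`r2_min = 0`) and quotes their spread as the uncertainty: one point per
shell means shell-to-shell scatter is part of the signal, and the strict
production gate would reject every window.

Problem sizes used throughout the tests and the acceptance script — a
cubic cell of edge $2\pi$ bohr, 14 electrons, cutoffs of 6, 8 and 14
hartree (179 to 612 plane waves) — were chosen so every quantity is exactly
checkable against brute force while still reaching the asymptotic $1/n$
regime (last-quartile $r^2 > 0.999$).

```{r}
m6 <- heg_model(2 * pi, 6, 14)
m14 <- heg_model(2 * pi, 14, 14)
d <- cbs_demo(m6, m14)
c(truncation = d$truncation_error, extrapolated = d$extrapolation_error_inv_n)
```

## Basis counting

`count_functions()` embeds the published contracted spherical-harmonic
compositions (H: 5/14/30/55 cc, 9/23/46/80 aug; first-row B–Ne:
14/30/55/91 cc, 23/46/80/127 aug for $X$ = 2..5), cross-checked against the
2945-function aug-cc-pV5Z count of the indole·benzene complex
(C$_{14}$H$_{13}$N).  The growth laws `nb_growth()` are frozen to the forms
consistent with those compositions, $N_b^{cc} = (X+1)(X+2)(2X+3)/6$ and
$N_b^{aug} = N_b^{cc} + (X+1)^2$: both are cubic in $X$, which is what
makes the MP2 cost climb like $X^{12}$ through its $N_b^4$ factor.
`ng_estimate()` is the continuum (sphere-volume) estimate
$\Omega (2E_\mathrm{cut})^{3/2} / (6\pi^2)$ of the plane-wave count, which
approaches the exact lattice enumeration from either side as the cutoff
grows (within 2% by 50 Ha for a $(2\pi)^3$ cell); at $E_\mathrm{cut} = 0$
the estimate is 0 while the enumeration keeps the single $\mathbf{G} = 0$
state — a documented edge.

## Synthetic generators

`gen_cardinal_series()`, `gen_dimer_set()`, `gen_virtual_series()` and
`gen_gaussian_pair()` produce every input the analysis functions consume,
from laws with known limits, so all round-trip contracts are testable
without external data.  Noise is Gaussian by default (Student-t with 3
degrees of freedom behind a flag for robustness studies), generated under
an explicit integer seed through R's default generator without disturbing
the caller's RNG stream; the configuration is attached to each output for
provenance.  The generators emulate the *structure* of production data —
cardinal series with known CBS limits, BSSE/BSIE decompositions, $1/n$
tails — not the quantitative energetics of real dimer benchmarks; passing
tests therefore validate the machinery, not chemistry-specific accuracy on
any particular complex.

## Known limitations

* Only H and first-row elements in the basis tables; no core-valence or
  Cartesian-function counting.
* Orthorhombic cells only; no wire/surface boundary conditions and no
  k-points beyond $\Gamma$.
* No uncertainty quantification on $E_\mathrm{CBS}$ beyond the
  window-averaging spread; no automatic scheme recommendation beyond the
  encoded practical rules.
* The HEG simulator is spin-restricted and closed-shell by construction;
  it demonstrates convergence laws, not real-molecule energetics (no
  pseudopotentials, no real HF orbitals).
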