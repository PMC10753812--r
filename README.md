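# cbslab

Complete-basis-set (CBS) convergence machinery for correlated interaction
energies, for quantum chemists who need to push MP2-level energies to the
basis-set limit from either side of the Gaussian / plane-wave divide.

Correlated energies converge slowly with the one-electron basis: with
correlation-consistent Gaussian bases (cc-pVXZ, aug-cc-pVXZ) the energy
approaches the limit in powers of the cardinal number *X*; with plane waves
the correlation energy converges like 1/*N* in the number of virtual
orbitals. In both cases the limit is reached by extrapolation, and for
weakly bound dimers the two routes must agree — plane waves carry no basis
set superposition error (BSSE), so they referee Gaussian-side
extrapolation and counterpoise choices.

The package provides, as tested reusable components:

- **Scheme registry and fitting engine** — all common cardinal-number
  extrapolation laws (Feller, Peterson, Truhlar with the fixed exponents
  3.4/2.2, Martin `(X+1/2)^-4` and `-4/-6`, Wilson, Helgaker `X^-3` and
  exponential HF, Varandas `(X-3/8)` forms, and the shifted-power
  Rovibi34/45 laws `E + A X^-3 + B (X-1/2)^-4` and
  `E + A (X-1/2)^-4 + B (X-1/2)^-5`), solved exactly at matching point
  counts or by least squares, plus enumeration of the generic
  shifted-power family they belong to.
- **Counterpoise bookkeeping** — uncorrected / CP-corrected / half-CP
  interaction energies from dimer, monomer and ghost-basis energies, and
  deviation statistics (MAE, mean signed deviation, signed maximum
  deviation, 1.5-IQR outliers).
- **Plane-wave extrapolations** — linear virtual-space fits of partial
  sums against `1/n` or `eps_n^(-3/2)` with multi-window averaging and an
  uncertainty from the window spread, and supercell-volume extrapolation
  in `1/Omega`.
- **Coulomb kernels for isolated systems** — bare (G = 0 dropped),
  Gaussian auxiliary-function singularity correction (linear in the
  electron count, hence exactly cancelling in interaction energies), and
  the Martyna–Tuckerman screened kernel, validated against analytic
  Gaussian electrostatics.
- **A finite-cell homogeneous-electron-gas MP2 simulator** — Fock
  eigenstates are pure plane waves, so momentum-conserving pair densities
  and the diagonal reciprocal-space quadrature give an exactly checkable
  MP2 whose partial sums exercise the 1/n convergence law end to end.
- **Basis bookkeeping** — contracted (aug-)cc-pVXZ function counts for H
  and first-row elements, growth laws, and the plane-wave count estimate.
- **Seeded synthetic generators** for every input the other tools consume.

## Worked example

Extrapolate a correlation-energy series, check the counterpoise
arithmetic, and validate the Martyna–Tuckerman kernel on an analytic
fixture:

```r
library(cbslab)

## two-point X^-3 extrapolation of a series with a known limit
pts <- data.frame(X = 3:4, energy = -100 + 2 * (3:4)^-3)
extrapolate(pts, "helgaker_corr_x3")$E_CBS
#> [1] -100

## counterpoise flavours (kcal/mol toy numbers)
interaction_energies(dimer_energy_set(-2.0, -0.7, -0.9, -0.75, -0.95))
#> $uncorr: -0.4   $cp: -0.3   $half_cp: -0.35
## uncorr - cp = -0.1: the BSSE overbinds the dimer by 0.1 kcal/mol

## MT kernel vs analytic Gaussian electrostatics (hartree)
fx <- gen_gaussian_pair(L = 24, E_cut = 50, sigma = 1, d = 4)
k <- kernel_values(fx$grid, kernel_spec("mt"))
pair_coulomb_energy(fx$rho_A, fx$rho_B, k, fx$grid)
#> [1] 0.2488306        # erf(2)/4 = 0.2488307

## HEG: extrapolating a small-cutoff series beats its truncated sum
d <- cbs_demo(heg_model(2*pi, 6, 14), heg_model(2*pi, 14, 14))
c(truncation = d$truncation_error, extrapolated = d$extrapolation_error_inv_n)
#>  truncation extrapolated
#>  0.01442657  -0.01150028   # hartree, closer to the large-cutoff value
```

The quantities printed above mean: the fitted CBS limit of the cardinal
series (exactly −100 by construction); the three interaction-energy
flavours, whose difference isolates the BSSE; the reciprocal-space pair
energy of two unit Gaussian charges, which must equal `erf(d/2σ)/d` for an
isolated-system kernel; and the error of the 14-electron HEG correlation
energy before and after virtual-space extrapolation.

A thin command-line wrapper over the same functions ships in
`inst/cli/cbslab` (subcommands `extrapolate`, `cp`, `stats`, `pwfit`,
`volfit`, `kernel`, `heg`, `count`, `simulate`).

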