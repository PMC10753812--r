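Package: cbslab
Title: Complete-Basis-Set Convergence Machinery for Correlated Interaction Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converging second-order Moller-Plesset (MP2) interaction
    energies to the complete-basis-set (CBS) limit from both Gaussian-type
    (cc-pVXZ / aug-cc-pVXZ) and plane-wave calculations. Provides a registry of
    cardinal-number extrapolation laws (Feller, Peterson, Truhlar, Martin,
    Wilson, Helgaker, Varandas, and the shifted-power Rovibi34/45 family) with
    exact-solve and least-squares fitting, counterpoise bookkeeping for basis
    set superposition errors, virtual-space and supercell-volume extrapolation
    of plane-wave MP2 correlation energies with multi-window averaging,
    reciprocal-space Coulomb kernels for isolated systems (bare, auxiliary
    function, Martyna-Tuckerman), contracted basis-function counting, and a
    finite-cell homogeneous-electron-gas MP2 simulator that exercises the
    convergence laws end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
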