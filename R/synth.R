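## Seeded synthetic generators for every input the other modules consume.
## Each generator evaluates a known law exactly, optionally adds seeded
## Gaussian (or heavy-tailed) noise, and records its configuration so the
## same config reproduces the same output bit for bit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

noise_fun <- function(heavy_tailed) {
  if (heavy_tailed) function(n, sd) sd * stats::rt(n, df = 3)
  else function(n, sd) stats::rnorm(n, sd = sd)
}

#' Generate a cardinal-number energy series from a registered scheme
#'
#' Evaluates a scheme's functional form at the requested cardinal numbers
#' with known true parameters, then adds seeded noise.  Noise-free output
#' round-trips through [extrapolate()] to the true `E_CBS` by construction.
#'
#' @param scheme scheme id or `cbs_scheme`.
#' @param E_CBS true basis-set-limit energy.
#' @param coefs named (or positional) coefficients matching the scheme's
#'   `coef_names`.
#' @param theta value of the scheme's nonlinear parameter, if it has one.
#' @param X cardinal numbers to evaluate (default 2:5).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param heavy_tailed use Student-t (df = 3) noise for robustness tests.
#' @return data frame with columns `X`, `energy`; attribute `config` records
#'   the generator call.
#' @examples
#' gen_cardinal_series("helgaker_corr_x3", E_CBS = -1, coefs = 0.5)$energy
#' @export
gen_cardinal_series <- function(scheme, E_CBS, coefs, theta = NULL,
                                X = 2:5, noise_sd = 0, seed = 1,
                                heavy_tailed = FALSE) {
  sch <- get_scheme(scheme)
  if (!is.null(sch$theta) && is.null(theta))
    stop("scheme '", sch$id, "' needs its nonlinear parameter '",
         sch$theta$name, "'", call. = FALSE)
  B <- sch$basis(X, theta)
  stopifnot(length(coefs) == ncol(B))
  energy <- E_CBS + as.numeric(B %*% coefs)
  if (noise_sd > 0) {
    energy <- energy + with_seed(seed, noise_fun(heavy_tailed)(length(X), noise_sd))
  }
  out <- data.frame(X = X, energy = energy)
  attr(out, "config") <- list(scheme = sch$id, E_CBS = E_CBS, coefs = coefs,
                              theta = theta, noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a dimer energy set with controlled BSSE/BSIE structure
#'
#' Constructs dimer and monomer energies around a known true interaction
#' energy.  The basis set superposition error (`bsse`) lowers each
#' ghost-basis monomer energy below its own-basis value (split evenly by
#' default), so the counterpoise-corrected interaction energy recovers
#' `delta_true` exactly when `bsie = 0`; a nonzero `bsie` shifts the dimer
#' energy to emulate residual incompleteness.
#'
#' @param delta_true true interaction energy (kcal/mol, negative = bound).
#' @param E_A,E_B monomer own-basis energies.
#' @param bsse total basis set superposition error, `>= 0`.
#' @param bsse_split fraction of `bsse` assigned to monomer A.
#' @param bsie basis set incompleteness shift applied to the dimer energy.
#' @return a [dimer_energy_set()] with attribute `delta_true`.
#' @export
gen_dimer_set <- function(delta_true = -0.4, E_A = -0.7, E_B = -0.9,
                          bsse = 0, bsse_split = 0.5, bsie = 0) {
  stopifnot(bsse >= 0, bsse_split >= 0, bsse_split <= 1)
  ghost_A <- E_A - bsse * bsse_split
  ghost_B <- E_B - bsse * (1 - bsse_split)
  ## cp = E_AB - ghosts = delta_true + bsie  =>  E_AB fixed from the cp route
  E_AB <- delta_true + bsie + ghost_A + ghost_B
  s <- dimer_energy_set(E_AB, E_A, E_B, ghost_A, ghost_B, unit = "kcal/mol")
  attr(s, "delta_true") <- delta_true
  s
}

#' Generate a virtual-space convergence series with a known intercept
#'
#' Evaluates `alpha + beta / n` (or `alpha + beta * eps_n^(-3/2)` when an
#' eigenvalue schedule is supplied) on an `n` grid, plus seeded noise.
#'
#' @param alpha true intercept (the basis-set-limit value).
#' @param beta slope.
#' @param n integer grid (default `seq(100, 1000, by = 100)`).
#' @param eps_n optional eigenvalue schedule; when given, the law is linear
#'   in `eps_n^(-3/2)` instead of `1/n`.
#' @param noise_sd,seed,heavy_tailed as in [gen_cardinal_series()].
#' @return a [virtual_series()].
#' @export
gen_virtual_series <- function(alpha, beta, n = seq(100, 1000, by = 100),
                               eps_n = NULL, noise_sd = 0, seed = 1,
                               heavy_tailed = FALSE) {
  x <- if (is.null(eps_n)) 1 / n else eps_n^(-1.5)
  E <- alpha + beta * x
  if (noise_sd > 0) {
    E <- E + with_seed(seed, noise_fun(heavy_tailed)(length(n), noise_sd))
  }
  virtual_series(n = n, E_c_n = E, eps_n = eps_n, unit = "kcal/mol")
}

#' Generate a Gaussian charge fixture for kernel validation
#'
#' Two unit Gaussian charges of width `sigma` separated by `d` along x,
#' centred in a cubic cell, with their analytic interaction
#' `erf(d / (2 sigma)) / d` and self-energy `1 / (2 sigma sqrt(pi))`.
#'
#' @param L cubic cell edge (bohr).
#' @param E_cut cutoff (hartree).
#' @param sigma Gaussian width (bohr).
#' @param d separation (bohr).
#' @return list with `grid`, `rho_A`, `rho_B`, `E_pair_analytic`,
#'   `E_self_analytic`.
#' @export
gen_gaussian_pair <- function(L = 24, E_cut = 50, sigma = 1, d = 4) {
  grid <- g_grid(L, E_cut)
  ctr <- rep(L / 2, 3)
  rho_A <- gaussian_density(grid, sigma, ctr - c(d / 2, 0, 0))
  rho_B <- gaussian_density(grid, sigma, ctr + c(d / 2, 0, 0))
  list(grid = grid, rho_A = rho_A, rho_B = rho_B,
       E_pair_analytic = erf_(d / (2 * sigma)) / d,
       E_self_analytic = 1 / (2 * sigma * sqrt(pi)))
}
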