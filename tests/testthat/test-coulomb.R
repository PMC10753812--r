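test_that("G grids enumerate the integer lattice within the cutoff", {
  g <- g_grid(2 * pi, 1.1)
  expect_equal(nrow(g$G), 19)  # |G|^2 in {0, 1, 2}: 1 + 6 + 12
  expect_equal(sort(unique(round(g$G2))), c(0, 1, 2))
  # closed under inversion
  key <- paste(g$m[, 1], g$m[, 2], g$m[, 3])
  expect_setequal(key, paste(-g$m[, 1], -g$m[, 2], -g$m[, 3]))
  # Ry conversion: 2 Ry = 1 Ha
  expect_equal(nrow(g_grid(2 * pi, 2.2, unit = "ry")$G), 19)
  expect_equal(g$Omega, (2 * pi)^3)
})

test_that("bare kernel is 4 pi / G^2 off the origin and zero at G = 0", {
  g <- g_grid(2 * pi, 2)
  k <- kernel_values(g, kernel_spec("bare_zeroed"))
  expect_equal(k[g$G2 == 0], 0)
  expect_equal(k[abs(g$G2 - 1) < 1e-12], rep(4 * pi, 6))
  # depends only on |G| for cubic cells
  expect_equal(length(unique(round(k[abs(g$G2 - 2) < 1e-12], 10))), 1)
})

test_that("MT kernel reproduces isolated Gaussian electrostatics", {
  fx <- gen_gaussian_pair(L = 24, E_cut = 50, sigma = 1, d = 4)
  kmt <- kernel_values(fx$grid, kernel_spec("mt"))
  # inversion symmetry of the kernel
  key <- paste(fx$grid$m[, 1], fx$grid$m[, 2], fx$grid$m[, 3])
  inv <- match(paste(-fx$grid$m[, 1], -fx$grid$m[, 2], -fx$grid$m[, 3]), key)
  expect_equal(kmt, kmt[inv], tolerance = 1e-10)

  E_pair <- pair_coulomb_energy(fx$rho_A, fx$rho_B, kmt, fx$grid)
  expect_lt(abs(E_pair - erf(2) / 4), 1e-4)
  E_self <- 0.5 * pair_coulomb_energy(fx$rho_A, fx$rho_A, kmt, fx$grid)
  expect_lt(abs(E_self - 1 / (2 * sqrt(pi))), 1e-4)

  # point-like densities at separation 3 bohr interact as 1/r
  tight <- 0.35
  ctr <- rep(12, 3)
  rA <- gaussian_density(fx$grid, tight, ctr - c(1.5, 0, 0))
  rB <- gaussian_density(fx$grid, tight, ctr + c(1.5, 0, 0))
  E3 <- pair_coulomb_energy(rA, rB, kmt, fx$grid)
  expect_lt(abs(E3 - erf(3 / (2 * tight)) / 3), 1e-3)
  expect_lt(abs(E3 - 1 / 3), 1e-3)
})

test_that("MT beats the bare kernel at equal box size and improves with the box", {
  sizes <- c(10, 14, 18, 24)
  errs <- t(vapply(sizes, function(L) {
    fx <- gen_gaussian_pair(L = L, E_cut = 30, sigma = 1, d = 4)
    kb <- kernel_values(fx$grid, kernel_spec("bare_zeroed"))
    km <- kernel_values(fx$grid, kernel_spec("mt"))
    c(bare = abs(pair_coulomb_energy(fx$rho_A, fx$rho_B, kb, fx$grid) -
                   fx$E_pair_analytic),
      mt = abs(pair_coulomb_energy(fx$rho_A, fx$rho_B, km, fx$grid) -
                 fx$E_pair_analytic))
  }, c(bare = 0, mt = 0)))
  expect_true(all(errs[, "mt"] <= errs[, "bare"]))
  # monotone decrease once the box spans ~twice the density extent
  expect_true(all(diff(errs[, "mt"]) < 0))
  expect_lt(errs[nrow(errs), "mt"], 1e-4)
})

test_that("auxiliary-function correction is linear in N_e and cancels in differences", {
  g <- g_grid(12, 10)
  sp <- kernel_spec("bap")
  expect_equal(bap_correction(g, sp, 0), 0)
  c2 <- bap_correction(g, sp, 2)
  expect_equal(bap_correction(g, sp, 4), 2 * c2)
  expect_equal(bap_correction(g, sp, 10) - bap_correction(g, sp, 6) -
                 bap_correction(g, sp, 4), 0)
  # kernel value at G = 0 is the finite singularity value
  k <- kernel_values(g, sp)
  expect_equal(k[g$G2 == 0], bap_chi(g, 7 / 12))
  expect_true(is.finite(k[g$G2 == 0]) && k[g$G2 == 0] != 0)
})

test_that("singularity correction improves single-charge box convergence over bare", {
  # self-energy of one Gaussian: bare + chi-correction vs bare alone
  sizes <- c(10, 14, 18)
  err <- t(vapply(sizes, function(L) {
    g <- g_grid(L, 30)
    rho <- gaussian_density(g, 1, rep(L / 2, 3))
    kb <- kernel_values(g, kernel_spec("bare_zeroed"))
    self_bare <- 0.5 * pair_coulomb_energy(rho, rho, kb, g)
    # one unit charge: the G = 0 singularity value enters once per charge pair
    chi <- bap_chi(g, 7 / L)
    self_bap <- self_bare + 0.5 * chi / g$Omega
    truth <- 1 / (2 * sqrt(pi))
    c(bare = abs(self_bare - truth), bap = abs(self_bap - truth))
  }, c(bare = 0, bap = 0)))
  expect_true(all(err[, "bap"] < err[, "bare"]))
})

test_that("pair energies validate shapes and degenerate inputs", {
  g <- g_grid(8, 4)
  k <- kernel_values(g, kernel_spec("bare_zeroed"))
  zero <- rep(0, nrow(g$G))
  rho <- gaussian_density(g, 1, rep(4, 3))
  expect_equal(pair_coulomb_energy(zero, rho, k, g), 0)
  expect_error(pair_coulomb_energy(rho[-1], rho, k, g), "shape error")
  expect_warning(kernel_values(g, kernel_spec("mt", alpha_L_target = 3)),
                 "alpha \\* L")
})
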