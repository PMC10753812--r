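test_that("virtual fits recover exact linear laws in both abscissa modes", {
  n <- seq(100, 1000, by = 100)
  s <- gen_virtual_series(alpha = -10, beta = 5, n = n)
  f <- virtual_fit(s)
  expect_equal(f$alpha, -10, tolerance = 1e-12)
  expect_equal(f$beta, 5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  # eps_n = n^(2/3) makes eps^(-3/2) identical to 1/n: both modes agree
  s2 <- gen_virtual_series(alpha = -10, beta = 5, n = n, eps_n = n^(2 / 3))
  expect_equal(virtual_fit(s2, "eps_minus_3_2")$alpha, -10, tolerance = 1e-10)
  expect_equal(virtual_fit(s2, "inv_n")$alpha, -10, tolerance = 1e-10)
})

test_that("noisy virtual fits recover the intercept to the stated accuracy", {
  n <- seq(100, 10000, by = 100)
  s <- gen_virtual_series(alpha = -10, beta = 5, n = n, noise_sd = 1e-4, seed = 42)
  f <- virtual_fit(s)
  expect_lt(abs(f$alpha + 10), 1e-3)
  # closed-form least-squares oracle
  x <- 1 / n; y <- as.data.frame(s)$E_c_n
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  expect_equal(f$alpha, a, tolerance = 1e-12)
  expect_equal(f$beta, b, tolerance = 1e-12)
})

test_that("window enumeration and averaging follow the ending-at-n_max convention", {
  n <- seq(100, 1000, by = 100)
  s <- gen_virtual_series(alpha = -7, beta = 3, n = n)
  w <- windowed_average(s, min_points = 3)
  expect_equal(w$n_windows, 8)              # starts at 100..800
  expect_equal(nrow(w$accepted_windows), 8) # noiseless: all accepted
  expect_equal(w$alpha_mean, -7, tolerance = 1e-12)
  expect_equal(w$sigma, 0, tolerance = 1e-12)

  sn <- gen_virtual_series(alpha = -7, beta = 3, n = seq(100, 3000, 100),
                           noise_sd = 5e-3, seed = 7)
  # at this noise level no window is cleanly linear; average over all ranges
  wn <- windowed_average(sn, min_points = 3, r2_min = 0)
  expect_gt(wn$sigma, 0)
  expect_lt(abs(wn$alpha_mean + 7), 3 * wn$sigma + 1e-3)
  # per-window independent refit oracle for one window
  sub <- as.data.frame(sn)[as.data.frame(sn)$n >= 1500, ]
  ref <- stats::lm(E_c_n ~ I(1 / n), data = sub)
  expect_equal(wn$accepted_windows$alpha[wn$accepted_windows$n_start == 1500],
               unname(coef(ref)[1]), tolerance = 1e-10)
})

test_that("per-subsystem fits and differenced fits give the same interaction intercept", {
  n <- seq(100, 2000, by = 100)
  ab <- gen_virtual_series(-20, 8, n = n)
  a <- gen_virtual_series(-8, 3, n = n)
  b <- gen_virtual_series(-10.5, 2, n = n)
  sep <- virtual_fit(ab)$alpha - virtual_fit(a)$alpha - virtual_fit(b)$alpha
  diffd <- virtual_series(n, as.data.frame(ab)$E_c_n - as.data.frame(a)$E_c_n -
                            as.data.frame(b)$E_c_n)
  expect_equal(sep, virtual_fit(diffd)$alpha, tolerance = 1e-12)
})

test_that("volume extrapolation recovers 1/Omega laws and flags bad input", {
  expect_equal(volume_fit(c(500, 1000), c(-3, -3))$E_inf, -3)
  expect_equal(volume_fit(c(500, 1000), c(-3, -3))$coefficient, 0)

  Om <- c(500, 1000, 2000)
  f <- volume_fit(Om, -10 + 100 / Om)
  expect_equal(f$E_inf, -10, tolerance = 1e-12)
  expect_equal(f$coefficient, 100, tolerance = 1e-9)
  # a fourth consistent point leaves the intercept unchanged
  f4 <- volume_fit(c(Om, 4000), -10 + 100 / c(Om, 4000))
  expect_equal(f4$E_inf, f$E_inf, tolerance = 1e-12)
  # configurable exponent
  f2 <- volume_fit(Om, -10 + 1e4 / Om^2, exponent = 2)
  expect_equal(f2$E_inf, -10, tolerance = 1e-10)

  expect_error(volume_fit(c(500, 500), c(-1, -2)), "degenerate abscissa")
  expect_error(volume_fit(500, -1), "insufficient points")
})

test_that("virtual-series validation rejects malformed windows and eigenvalues", {
  expect_error(virtual_series(c(100, 100), c(-1, -2)), "strictly increasing")
  s <- gen_virtual_series(-1, 1, n = seq(100, 400, 100))
  expect_error(virtual_fit(s, window = c(350, 400)), "insufficient window")
  expect_error(virtual_fit(s, "eps_minus_3_2"), "invalid eigenvalue")
  s2 <- gen_virtual_series(-1, 1, n = seq(100, 400, 100),
                           eps_n = c(-1, 1, 2, 3))
  expect_error(virtual_fit(s2, "eps_minus_3_2"), "invalid eigenvalue")
})
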