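test_that("closed-form two-point extrapolations recover known limits", {
  # X^-3 law: E_CBS = (Y^3 E_Y - X^3 E_X) / (Y^3 - X^3)
  pts <- data.frame(X = 3:4, energy = -100 + 2 * (3:4)^-3)
  f <- extrapolate(pts, "helgaker_corr_x3")
  expect_equal(f$E_CBS, (4^3 * pts$energy[2] - 3^3 * pts$energy[1]) / (4^3 - 3^3))
  expect_equal(f$E_CBS, -100, tolerance = 1e-12)
  expect_identical(f$fit_mode, "exact-solve")

  # fixed-exponent power law with the published 3.4 exponent
  pts <- data.frame(X = 3:4, energy = -50 + 1.5 * (3:4)^-3.4)
  expect_lt(abs(extrapolate(pts, "truhlar_hf", component = "HF")$E_CBS + 50), 1e-10)

  # constant series: E_CBS equals the value, coefficient vanishes
  f <- extrapolate(data.frame(X = 3:4, energy = c(-76, -76)), "helgaker_corr_x3")
  expect_equal(f$E_CBS, -76)
  expect_equal(unname(f$params["A"]), 0)
})

test_that("every registered scheme round-trips its own noise-free series", {
  for (id in names(scheme_registry())) {
    sch <- get_scheme(id)
    tr <- scheme_truth(sch)
    pts <- gen_cardinal_series(sch, E_CBS = tr$E_CBS, coefs = tr$coefs,
                               theta = tr$theta, X = (2:5)[seq_len(sch$n_free)])
    f <- extrapolate(pts, sch, component = sch$components[1])
    expect_lt(abs(f$E_CBS - tr$E_CBS), 1e-9 * max(1, abs(tr$E_CBS)),
              label = paste0(id, " E_CBS error"))
    expect_lt(max(abs(f$residuals)) / max(1, abs(tr$E_CBS)), 1e-10,
              label = paste0(id, " residuals"))
  }
})

test_that("schemes are translation-equivariant and handle constant series", {
  shift <- 12.5
  for (id in names(scheme_registry())) {
    sch <- get_scheme(id)
    tr <- scheme_truth(sch)
    X <- (2:5)[seq_len(sch$n_free)]
    pts <- gen_cardinal_series(sch, E_CBS = tr$E_CBS, coefs = tr$coefs,
                               theta = tr$theta, X = X)
    f0 <- extrapolate(pts, sch, component = sch$components[1])
    pts$energy <- pts$energy + shift
    f1 <- extrapolate(pts, sch, component = sch$components[1])
    expect_equal(f1$E_CBS, f0$E_CBS + shift, tolerance = 1e-8,
                 label = paste0(id, " translated E_CBS"))

    const <- data.frame(X = (2:5)[seq_len(max(sch$min_points, 2))],
                        energy = -42)
    fc <- extrapolate(const, sch, component = sch$components[1])
    expect_equal(fc$E_CBS, -42, tolerance = 1e-9, label = paste0(id, " constant"))
    coef_vals <- fc$params[sch$coef_names]
    expect_true(all(abs(coef_vals) < 1e-8), label = paste0(id, " zero coefs"))
  }
})

test_that("over-determined fits match an independent grid-search minimizer", {
  set.seed(11)
  ids <- c("helgaker_corr_x3", "martin4", "rovibi34", "martin_alpha",
           "helgaker_hf", "peterson", "varandas34", "feller", "wilson45",
           "truhlar_corr")
  for (k in seq_along(ids)) {
    sch <- get_scheme(ids[k])
    tr <- scheme_truth(sch)
    pts <- gen_cardinal_series(sch, E_CBS = tr$E_CBS, coefs = tr$coefs,
                               theta = tr$theta, X = 2:5)
    pts$energy <- pts$energy + rnorm(4, sd = 0.02)
    f <- extrapolate(pts, sch, component = sch$components[1])
    oracle <- grid_search_fit(sch, pts$X, pts$energy)
    expect_lt(abs(f$E_CBS - oracle$E_CBS), 1e-6,
              label = paste0(ids[k], " vs grid search"))
    expect_lte(sum(f$residuals^2), oracle$rss + 1e-10,
               label = paste0(ids[k], " RSS"))
  }
})

test_that("per-subsystem extrapolation and differencing commute for linear schemes", {
  for (id in c("helgaker_corr_x3", "martin4", "rovibi34", "varandas34")) {
    sch <- get_scheme(id)
    X <- (2:5)[seq_len(sch$n_free)]
    dim_tr <- scheme_truth(sch)
    monA <- gen_cardinal_series(sch, -30.1, dim_tr$coefs * 0.4, X = X)
    monB <- gen_cardinal_series(sch, -45.2, dim_tr$coefs * 0.6, X = X)
    dimr <- gen_cardinal_series(sch, dim_tr$E_CBS, dim_tr$coefs, X = X)
    sep <- extrapolate(dimr, sch)$E_CBS - extrapolate(monA, sch)$E_CBS -
      extrapolate(monB, sch)$E_CBS
    diffd <- extrapolate(
      data.frame(X = X, energy = dimr$energy - monA$energy - monB$energy), sch)
    expect_equal(sep, diffd$E_CBS, tolerance = 1e-9, label = id)
  }
})

test_that("generic family enumeration counts, dedups, and contains the Rovibi forms", {
  expect_length(enumerate_generic_family(3, NULL, shifts = 0), 1)
  fam1 <- enumerate_generic_family(3, NULL, shifts = 0)[[1]]
  pts <- data.frame(X = 3:4, energy = -10 + 2 * (3:4)^-3)
  expect_equal(extrapolate(pts, fam1)$E_CBS,
               extrapolate(pts, "helgaker_corr_x3")$E_CBS)

  expect_length(enumerate_generic_family(3:6, 3:6, shifts = 0), 10)
  expect_error(enumerate_generic_family(integer(0)), "empty family")

  fam <- enumerate_generic_family(3:5, 4:5, shifts = c(0, -0.5))
  ids <- vapply(fam, `[[`, "", "id")
  pts3 <- data.frame(X = 2:4, energy = c(-0.95, -0.99, -0.998))
  for (target in list(c("rovibi34", "gen_p3s0_p4s-0.5"),
                      c("rovibi45", "gen_p4s-0.5_p5s-0.5"))) {
    expect_true(target[2] %in% ids)
    twin <- fam[[which(ids == target[2])]]
    expect_equal(extrapolate(pts3, twin)$E_CBS,
                 extrapolate(pts3, target[1])$E_CBS, tolerance = 1e-10)
  }
})

test_that("interpolation error reports the mean absolute residual", {
  sch <- get_scheme("rovibi34")
  pts <- gen_cardinal_series(sch, -20, c(1, 0.5), X = 2:4)
  expect_equal(interpolation_error(extrapolate(pts, sch)), 0, tolerance = 1e-12)

  # injected alternating residuals around a frozen linear fit
  base <- gen_cardinal_series("helgaker_corr_x3", -20, 1, X = 2:5)
  fit <- extrapolate(base, "helgaker_corr_x3")
  fit$residuals <- c(0.2, -0.2, 0.2, -0.2)
  expect_equal(interpolation_error(fit), 0.2)

  # model misfit: X^-3 law fitted to X^-4 data, residual MAE matches a refit
  pts4 <- data.frame(X = 2:5, energy = -5 + 3 * (2:5)^-4)
  f <- extrapolate(pts4, "helgaker_corr_x3")
  expect_gt(interpolation_error(f), 0)
  refit <- stats::lm(energy ~ I(X^-3), data = pts4)
  expect_equal(interpolation_error(f), mean(abs(stats::resid(refit))),
               tolerance = 1e-10)
})

test_that("input validation rejects bad point sets and mismatched components", {
  expect_error(extrapolate(data.frame(X = 3, energy = -1), "helgaker_corr_x3"),
               "insufficient points")
  expect_error(extrapolate(data.frame(X = c(3, 3), energy = c(-1, -2)),
                           "helgaker_corr_x3"), "degenerate abscissa")
  expect_error(extrapolate(data.frame(X = 2:4, energy = -(1:3)),
                           "truhlar_hf", component = "corr"),
               "not applicable")
  expect_error(get_scheme("nope"), "unknown scheme")
})

test_that("recommended schemes follow the component and point-set rules", {
  expect_identical(recommended_scheme(2:4, "HF")$id, "helgaker_hf")
  expect_identical(recommended_scheme(c(2, 3), "corr")$id, "helgaker_corr_x3")
  expect_identical(recommended_scheme(c(3, 4), "corr")$id, "martin4")
  expect_identical(recommended_scheme(2:5, "corr")$id, "rovibi34")
})
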