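# Shared fixtures and independent oracles used across test files.

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Independent MP2 oracle: naive quadruple loop over (i, j, a, b) with
# explicit momentum-conservation checks and per-integral kernel lookups,
# sharing nothing with the streamed partial-sum path beyond the model.
brute_mp2 <- function(model, n_keep = model$N_vir,
                      kernel = kernel_spec("bare_zeroed")) {
  dg <- g_grid(model$L, 4 * model$E_cut + 1e-9)
  kv <- kernel_values(dg, kernel)
  Om <- model$L^3
  dkey <- paste(dg$m[, 1], dg$m[, 2], dg$m[, 3])
  lookup <- function(v) kv[match(paste(v[1], v[2], v[3]), dkey)]
  mo <- model$m_occ
  mv <- model$m_vir[seq_len(n_keep), , drop = FALSE]
  eo <- model$eps_occ
  ev <- model$eps_vir[seq_len(n_keep)]
  E <- 0
  for (i in seq_len(model$N_occ)) for (j in seq_len(model$N_occ))
    for (a in seq_len(n_keep)) for (b in seq_len(n_keep)) {
      if (!all(mo[i, ] + mo[j, ] == mv[a, ] + mv[b, ])) next
      vd <- lookup(mv[a, ] - mo[i, ]) / Om
      vx <- lookup(mv[b, ] - mo[i, ]) / Om
      E <- E + vd * (2 * vd - vx) / (eo[i] + eo[j] - ev[a] - ev[b])
    }
  E
}

# Independent least-squares oracle: dense grid search over the nonlinear
# parameter (if any) with a pseudoinverse solve for the linear part.
grid_search_fit <- function(scheme, X, y, n_grid = 4000) {
  fit_lin <- function(A) {
    beta <- qr.coef(qr(A), y)
    list(beta = beta, rss = sum((y - A %*% beta)^2))
  }
  if (is.null(scheme$theta)) {
    f <- fit_lin(cbind(1, scheme$basis(X)))
    return(list(E_CBS = unname(f$beta[1]), rss = f$rss))
  }
  grid <- exp(seq(log(scheme$theta$lower), log(scheme$theta$upper),
                  length.out = n_grid))
  best <- NULL
  for (th in grid) {
    f <- fit_lin(cbind(1, scheme$basis(X, th)))
    if (is.null(best) || f$rss < best$rss) best <- c(f, theta = th)
  }
  # refine around the best grid node
  i <- which.min(abs(grid - best$theta))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(function(th) fit_lin(cbind(1, scheme$basis(X, th)))$rss,
                         c(lo, hi), tol = 1e-13)
  f <- fit_lin(cbind(1, scheme$basis(X, opt$minimum)))
  list(E_CBS = unname(f$beta[1]), rss = f$rss)
}

# Default true parameters for round-tripping any registered scheme.
scheme_truth <- function(scheme) {
  list(E_CBS = -75.3,
       coefs = seq_along(scheme$coef_names) + 0.25,
       theta = if (!is.null(scheme$theta)) scheme$theta$default else NULL)
}

# Small shared HEG models (memoised across test files).
heg_cache <- local({
  env <- new.env()
  function(L, E_cut, N_elec) {
    key <- paste(L, E_cut, N_elec)
    if (is.null(env[[key]])) env[[key]] <- heg_model(L, E_cut, N_elec)
    env[[key]]
  }
})
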