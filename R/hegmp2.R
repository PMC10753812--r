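## Desk-scale Gamma-point plane-wave MP2 for the finite-cell homogeneous
## electron gas (HEG).  The Fock eigenstates of the HEG are pure plane waves
## |G>, so the model exercises the full reciprocal-space MP2 machinery --
## momentum-conserving pair densities, diagonal two-electron quadrature,
## partial sums over virtual orbitals -- without any SCF step.

pack_key <- function(m, base) {
  (m[, 1] + base) * (2 * base + 1)^2 + (m[, 2] + base) * (2 * base + 1) + (m[, 3] + base)
}

#' Build a finite-cell homogeneous-electron-gas model
#'
#' Enumerates all plane waves `|G>` of a cubic cell with kinetic energy
#' `|G|^2 / 2 <= E_cut`, fills the lowest closed shells with `N_elec`
#' electrons (two per spatial orbital), and computes the orbital
#' eigenvalues.  Construction fails when the Fermi shell would be partially
#' filled, since the resulting state would be open-shell and the restricted
#' MP2 expression would not apply: valid electron counts for cubic cells are
#' 2, 14, 38, 54, ... (closed `|G|^2` shells).
#'
#' @param L cubic cell edge in bohr.
#' @param E_cut kinetic-energy cutoff in hartree.
#' @param N_elec even electron count filling complete shells.
#' @param exchange include the finite-cell exchange sum in the eigenvalues
#'   (default) or use bare kinetic eigenvalues (debugging aid).
#' @return an object of class `heg_model`: list with `grid` ([g_grid()]),
#'   `m_occ`/`m_vir` (integer triples), `eps_occ`/`eps_vir` (hartree,
#'   virtuals sorted by eigenvalue with degenerate shells contiguous),
#'   `N_occ`, `N_vir`, `N_G`, `shell_ends` (virtual indices at which a
#'   degenerate eigenvalue shell is complete), `exchange`.
#' @examples
#' m <- heg_model(2 * pi, E_cut = 1.1, N_elec = 2)
#' m$N_G   # 19
#' m$N_vir # 18
#' @export
heg_model <- function(L, E_cut, N_elec, exchange = TRUE) {
  stopifnot(L > 0, N_elec >= 2)
  if (N_elec %% 2 != 0)
    stop("N_elec must be even (spin-restricted closed shells)", call. = FALSE)
  grid <- g_grid(L, E_cut)
  ord <- order(grid$G2, grid$m[, 1], grid$m[, 2], grid$m[, 3])
  m <- grid$m[ord, , drop = FALSE]
  kin <- grid$G2[ord] / 2
  N_G <- nrow(m)
  N_occ <- N_elec / 2L
  if (N_occ > N_G) stop("basis smaller than the occupied space: raise E_cut", call. = FALSE)
  ## kinetic shells must close at the Fermi level
  if (N_occ < N_G && abs(kin[N_occ + 1] - kin[N_occ]) < 1e-12) {
    sizes <- as.numeric(table(round(kin, 9)))
    closed <- 2 * cumsum(sizes)
    stop("open shell at Fermi level: choose N_elec in {",
         paste(utils::head(closed, 6), collapse = ", "),
         ", ...} for this cell", call. = FALSE)
  }
  model <- list(grid = grid, L = L, E_cut = grid$E_cut, N_elec = N_elec,
                m_occ = m[seq_len(N_occ), , drop = FALSE],
                m_vir = m[setdiff(seq_len(N_G), seq_len(N_occ)), , drop = FALSE],
                N_occ = N_occ, N_vir = N_G - N_occ, N_G = N_G,
                exchange = exchange)
  eps <- hf_eigenvalues(model, exchange = exchange)
  model$eps_occ <- eps[seq_len(N_occ)]
  eps_vir <- eps[setdiff(seq_len(N_G), seq_len(N_occ))]
  ## sort virtuals by eigenvalue; ties broken by (|G|^2, lexicographic triple)
  ## so partial sums are independent of enumeration order
  mv <- model$m_vir
  kv2 <- rowSums(mv^2)
  ov <- order(round(eps_vir, 12), kv2, mv[, 1], mv[, 2], mv[, 3])
  model$m_vir <- mv[ov, , drop = FALSE]
  model$eps_vir <- eps_vir[ov]
  if (model$N_vir > 0) {
    d <- diff(model$eps_vir)
    model$shell_ends <- c(which(d > 1e-9), model$N_vir)
  } else {
    model$shell_ends <- integer(0)
  }
  structure(model, class = "heg_model")
}

#' @export
print.heg_model <- function(x, ...) {
  cat(sprintf("<heg_model> L = %.6g bohr, E_cut = %.4g Ha, N_elec = %d\n",
              x$L, x$E_cut, x$N_elec))
  cat(sprintf("  N_G = %d (N_occ = %d, N_vir = %d), exchange %s\n",
              x$N_G, x$N_occ, x$N_vir, if (x$exchange) "on" else "off"))
  invisible(x)
}

#' Hartree-Fock eigenvalues of the HEG plane-wave states
#'
#' With exchange off, `eps_k = |k|^2 / 2`.  With exchange on, the finite-cell
#' exchange sum over occupied states is subtracted:
#' `eps_k = |k|^2 / 2 - (4 pi / Omega) sum_{k' occ, k' != k} 1 / |k - k'|^2`,
#' the `G = 0` Coulomb component being excluded consistently with the bare
#' kernel treatment (the HEG background cancels it).
#'
#' @param model a (possibly partially built) `heg_model`.
#' @param exchange logical.
#' @return eigenvalues in hartree for all `N_G` states, in the model's
#'   enumeration order (occupied first).
#' @export
hf_eigenvalues <- function(model, exchange = TRUE) {
  b <- 2 * pi / model$L
  m_all <- rbind(model$m_occ, model$m_vir)
  kin <- rowSums(m_all^2) * b^2 / 2
  if (!exchange) return(kin)
  Omega <- model$L^3
  mo <- model$m_occ
  xch <- vapply(seq_len(nrow(m_all)), function(s) {
    dm <- sweep(mo, 2, m_all[s, ], `-`)
    d2 <- rowSums(dm^2) * b^2
    sum(1 / d2[d2 > 0])
  }, numeric(1))
  kin - (4 * pi / Omega) * xch
}

## Kernel values at difference vectors k_a - k_i.  Differences live on a grid
## of up to twice the wave-function G_max, i.e. within the density cutoff
## 4 E_cut; kernels are evaluated there once and looked up by integer triple.
difference_kernel <- function(model, spec) {
  dgrid <- g_grid(model$L, 4 * model$E_cut + 1e-9)
  vals <- kernel_values(dgrid, spec)
  base <- max(abs(dgrid$m))
  keys <- pack_key(dgrid$m, base)
  list(keys = keys, vals = vals[order(keys)], sorted = sort(keys), base = base)
}

diff_kernel_lookup <- function(dk, m) {
  idx <- findInterval(pack_key(m, dk$base), dk$sorted)
  dk$vals[idx]
}

#' MP2 correlation energy as a partial-sum series over virtual orbitals
#'
#' Evaluates the spin-restricted MP2 correlation energy of the HEG model
#' with the diagonal G-space two-electron quadrature and momentum-conserving
#' pair densities (each occupied-virtual product has exactly one nonzero
#' Fourier component, at `G = k_a - k_i`).  Returns the progression
#' `E_c,n`: each entry is the exact MP2 energy of the virtual space
#' truncated at the first `n` virtuals, reported at degenerate-shell
#' boundaries so the series is independent of basis enumeration order.
#'
#' @param model a [heg_model()].
#' @param kernel a [kernel_spec()]; default the bare kernel with `G = 0`
#'   dropped (the compensating background convention).
#' @param n_max largest virtual count to include (default all); snapped down
#'   to a shell boundary with a warning when it would split a degenerate
#'   shell.
#' @return a [virtual_series()] in hartree with `n` at shell boundaries,
#'   `eps_n` the eigenvalue of the n-th virtual, and `E_c_n` the truncated
#'   MP2 correlation energy (non-positive throughout).
#' @export
mp2_correlation <- function(model, kernel = kernel_spec("bare_zeroed"),
                            n_max = model$N_vir) {
  stopifnot(inherits(model, "heg_model"), n_max <= model$N_vir)
  if (model$N_vir == 0 || n_max == 0) {
    return(virtual_series(numeric(0), numeric(0), numeric(0), unit = "hartree"))
  }
  if (!n_max %in% model$shell_ends) {
    ## complete the split shell so the truncation is ordering-independent
    n_snap <- min(model$shell_ends[model$shell_ends >= n_max])
    warning(sprintf("n_max = %d splits a degenerate shell; completed to %d",
                    n_max, n_snap), call. = FALSE)
    n_max <- n_snap
  }
  dk <- difference_kernel(model, kernel)
  Omega <- model$L^3
  mo <- model$m_occ
  mv <- model$m_vir[seq_len(n_max), , drop = FALSE]
  eo <- model$eps_occ
  ev <- model$eps_vir[seq_len(n_max)]
  ## packing base for b-lookup must cover |m_i + m_j - m_a| componentwise
  kb_base <- 3L * max(abs(rbind(mo, mv))) + 1L
  vkeys <- pack_key(mv, kb_base)
  inc <- numeric(n_max)
  for (i in seq_len(model$N_occ)) {
    v_d_all <- diff_kernel_lookup(dk, sweep(mv, 2, mo[i, ], `-`)) / Omega
    for (j in seq_len(model$N_occ)) {
      ## momentum conservation fixes b: k_b = k_i + k_j - k_a
      mb <- -sweep(mv, 2, mo[i, ] + mo[j, ], `-`)
      bidx <- match(pack_key(mb, kb_base), vkeys)
      sel <- which(!is.na(bidx))
      if (!length(sel)) next
      b <- bidx[sel]
      v_d <- v_d_all[sel]
      v_x <- diff_kernel_lookup(dk, mb[sel, , drop = FALSE] -
                                  matrix(mo[i, ], length(sel), 3, byrow = TRUE)) / Omega
      denom <- eo[i] + eo[j] - ev[sel] - ev[b]
      contrib <- v_d * (2 * v_d - v_x) / denom
      ## a contribution enters E_c,n once both a and b fit below n
      at <- pmax(sel, b)
      agg <- rowsum(contrib, at)
      inc[as.integer(rownames(agg))] <- inc[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  Ecn <- cumsum(inc)
  ends <- model$shell_ends[model$shell_ends <= n_max]
  virtual_series(n = ends, E_c_n = Ecn[ends], eps_n = ev[ends],
                 unit = "hartree")
}

#' End-to-end basis-set-limit demonstration on the HEG
#'
#' Runs [mp2_correlation()] on two models that differ only in their cutoff,
#' extrapolates the small model's partial-sum series with both abscissa
#' modes (`1/n` and `eps_n^(-3/2)`) over windows in the tail of the series,
#' and compares the extrapolated values with the large model's direct
#' correlation energy.  Because HEG virtuals are exact plane waves, the
#' small model's series coincides with the large model's over the shared
#' `n` range, so its `1/n` intercept estimates the basis-set limit and
#' should land closer to the large-cutoff value than the small model's own
#' truncated sum.
#'
#' @param model_small,model_large two [heg_model()]s sharing `L`, `N_elec`
#'   and the exchange setting, differing in `E_cut`.
#' @param kernel a [kernel_spec()].
#' @param tail_fraction fraction of the series (by trailing entries) used
#'   for the extrapolation windows (default 0.5).
#' @param min_points minimum points per window (see [windowed_average()]).
#' @param r2_min,max_studentized window-acceptance thresholds passed to
#'   [windowed_average()].  The defaults accept every tail window: a
#'   shell-resolved series has one point per degenerate eigenvalue shell,
#'   so shell-to-shell scatter around the smooth `1/n` law is part of the
#'   signal, and the spread of the intercept across fitting ranges is the
#'   honest uncertainty; the strict production gate is meant for long
#'   fixed-increment series.
#' @return list with the two window-averaged extrapolations
#'   (`extrap_inv_n`, `extrap_eps`), `direct_small`, `direct_large`,
#'   `truncation_error`, `extrapolation_error_inv_n`,
#'   `extrapolation_error_eps` (all hartree).
#' @export
cbs_demo <- function(model_small, model_large,
                     kernel = kernel_spec("bare_zeroed"),
                     tail_fraction = 0.5, min_points = 3,
                     r2_min = 0, max_studentized = Inf) {
  stopifnot(inherits(model_small, "heg_model"), inherits(model_large, "heg_model"))
  if (model_small$L != model_large$L || model_small$N_elec != model_large$N_elec ||
      model_small$exchange != model_large$exchange) {
    stop("models must differ only in E_cut", call. = FALSE)
  }
  s_small <- mp2_correlation(model_small, kernel)
  s_large <- mp2_correlation(model_large, kernel)
  direct_small <- s_small$E_c_n[nrow(s_small)]
  direct_large <- s_large$E_c_n[nrow(s_large)]
  tail <- tail_series(s_small, tail_fraction)
  w_inv <- windowed_average(tail, mode = "inv_n", min_points = min_points,
                            r2_min = r2_min, max_studentized = max_studentized)
  w_eps <- windowed_average(tail, mode = "eps_minus_3_2", min_points = min_points,
                            r2_min = r2_min, max_studentized = max_studentized)
  list(extrap_inv_n = w_inv, extrap_eps = w_eps,
       direct_small = direct_small, direct_large = direct_large,
       truncation_error = direct_small - direct_large,
       extrapolation_error_inv_n = w_inv$alpha_mean - direct_large,
       extrapolation_error_eps = w_eps$alpha_mean - direct_large)
}

#' Trailing window of a virtual series
#'
#' @param series a [virtual_series()].
#' @param fraction trailing fraction of entries to keep (0 < fraction <= 1).
#' @return a [virtual_series()] over the kept entries.
#' @export
tail_series <- function(series, fraction = 0.25) {
  stopifnot(inherits(series, "virtual_series"), fraction > 0, fraction <= 1)
  df <- as.data.frame(series)
  keep <- df[seq.int(max(1L, nrow(df) - ceiling(fraction * nrow(df)) + 1L), nrow(df)), ]
  virtual_series(keep$n, keep$E_c_n, keep$eps_n, unit = attr(series, "unit"))
}
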