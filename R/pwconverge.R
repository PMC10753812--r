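## Plane-wave-side extrapolations: linear virtual-space fits in 1/n or
## eps_n^(-3/2), multi-window averaging of the intercept, and supercell
## volume extrapolation in 1/Omega.

#' Construct a virtual-space convergence series
#'
#' Ordered triples `(n, eps_n, E_c_n)`: the number of virtual orbitals
#' included, the eigenvalue of the n-th virtual (hartree), and the partial
#' MP2 correlation sum truncated at n.  The partial sums converge to the
#' basis-set limit like `1/n` in the tail, which is what [virtual_fit()]
#' exploits.
#'
#' @param n integer vector, strictly increasing.
#' @param E_c_n partial correlation sums (one per `n`).
#' @param eps_n optional eigenvalue abscissa (hartree), needed for the
#'   `eps_minus_3_2` mode.
#' @param increment nominal spacing in n (bookkeeping; production series use
#'   an increment of 100 virtual orbitals).
#' @param unit energy unit of `E_c_n`.
#' @return an object of class `virtual_series` (a data frame with attributes
#'   `increment`, `n_max`, `unit`).
#' @export
virtual_series <- function(n, E_c_n, eps_n = NULL, increment = NULL,
                           unit = "hartree") {
  stopifnot(length(n) == length(E_c_n))
  if (is.unsorted(n, strictly = TRUE))
    stop("n must be strictly increasing", call. = FALSE)
  if (!is.null(eps_n)) stopifnot(length(eps_n) == length(n))
  df <- data.frame(n = as.numeric(n),
                   eps_n = if (is.null(eps_n)) NA_real_ else as.numeric(eps_n),
                   E_c_n = as.numeric(E_c_n))
  structure(df, class = c("virtual_series", "data.frame"),
            increment = increment %||% (if (length(n) > 1) n[2] - n[1] else 1),
            n_max = n[length(n)], unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear virtual-space extrapolation
#'
#' Ordinary least-squares line of the partial sums `E_c_n` against `1/n`
#' (mode `inv_n`) or `eps_n^(-3/2)` (mode `eps_minus_3_2`) over a window of
#' the series.  The intercept `alpha` is the basis-set-limit estimate of the
#' correlation energy; `beta` is the slope.
#'
#' @param series a [virtual_series()].
#' @param mode abscissa choice, `"inv_n"` or `"eps_minus_3_2"`.
#' @param window `c(n_start, n_max)` limits (inclusive) in n; default the
#'   whole series.
#' @return list with `alpha`, `beta`, `window`, `abscissa_mode`,
#'   `r_squared`, `n_points`, `residuals`.
#' @examples
#' s <- virtual_series(n = seq(100, 1000, 100), E_c_n = -10 + 5 / seq(100, 1000, 100))
#' virtual_fit(s)$alpha  # -10
#' @export
virtual_fit <- function(series, mode = c("inv_n", "eps_minus_3_2"),
                        window = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "virtual_series"))
  df <- as.data.frame(series)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    df <- df[df$n >= window[1] & df$n <= window[2], , drop = FALSE]
  }
  if (nrow(df) < 2) stop("insufficient window: need at least 2 points", call. = FALSE)
  if (mode == "eps_minus_3_2") {
    if (anyNA(df$eps_n)) stop("invalid eigenvalue: eps_n missing", call. = FALSE)
    if (any(df$eps_n <= 0))
      stop("invalid eigenvalue: eps_n must be positive in eps mode", call. = FALSE)
    x <- df$eps_n^(-1.5)
  } else {
    x <- 1 / df$n
  }
  fit <- stats::lm.fit(cbind(1, x), df$E_c_n)
  r <- fit$residuals
  tss <- sum((df$E_c_n - mean(df$E_c_n))^2)
  r2 <- if (tss > 0) 1 - sum(r^2) / tss else 1
  list(alpha = unname(fit$coefficients[1]),
       beta = unname(fit$coefficients[2]),
       window = range(df$n), abscissa_mode = mode,
       r_squared = r2, n_points = nrow(df), residuals = unname(r))
}

## Internally studentized residuals of a simple linear fit; NA-safe for the
## minimal window sizes where the leverage leaves no degrees of freedom.
studentized_max <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(0)
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  s2 <- sum(r^2) / (n - 2)
  if (s2 <= 0) return(0)
  h <- rowSums((X %*% solve(crossprod(X))) * X)
  max(abs(r / sqrt(s2 * pmax(1e-300, 1 - h))))
}

#' Multi-window averaged virtual-space extrapolation
#'
#' Fits every window `[n_start, n_max]` whose start lies on the series grid
#' and which contains at least `min_points` entries, keeps the windows on
#' which the linear law holds, and averages their intercepts.  The standard
#' deviation of the accepted intercepts is the reported extrapolation
#' uncertainty (the sigma quoted next to extrapolated correlation
#' energies).  Validity of a window is judged by `r_squared >= r2_min` and a
#' maximum internally studentized residual below `max_studentized`; both
#' thresholds are configurable proxies for "the linear law holds".
#'
#' @inheritParams virtual_fit
#' @param min_points smallest number of points per window (default 3).
#' @param r2_min coefficient-of-determination acceptance threshold.
#' @param max_studentized studentized-residual acceptance threshold.
#' @return list with `alpha_mean`, `sigma`, `accepted_windows` (data frame of
#'   `n_start`, `alpha`, `r_squared`), `n_windows` (candidates).
#' @export
windowed_average <- function(series, mode = c("inv_n", "eps_minus_3_2"),
                             min_points = 3, r2_min = 0.99,
                             max_studentized = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "virtual_series"))
  df <- as.data.frame(series)
  if (nrow(df) < min_points)
    stop("insufficient window: series shorter than min_points", call. = FALSE)
  n_max <- df$n[nrow(df)]
  starts <- df$n[seq_len(nrow(df) - min_points + 1)]
  res <- lapply(starts, function(ns) {
    sub <- df[df$n >= ns, , drop = FALSE]
    f <- virtual_fit(series, mode = mode, window = c(ns, n_max))
    x <- if (mode == "inv_n") 1 / sub$n else sub$eps_n^(-1.5)
    data.frame(n_start = ns, alpha = f$alpha, r_squared = f$r_squared,
               stud_max = studentized_max(x, sub$E_c_n))
  })
  res <- do.call(rbind, res)
  ok <- res$r_squared >= r2_min & res$stud_max <= max_studentized
  if (!any(ok)) {
    stop(paste0("no valid window: none passed r2 >= ", r2_min,
                " and studentized <= ", max_studentized, "; diagnostics:\n",
                paste(utils::capture.output(print(res)), collapse = "\n")),
         call. = FALSE)
  }
  acc <- res[ok, c("n_start", "alpha", "r_squared")]
  list(alpha_mean = mean(acc$alpha),
       sigma = if (nrow(acc) > 1) stats::sd(acc$alpha) else 0,
       accepted_windows = acc, n_windows = nrow(res))
}

#' Supercell-volume extrapolation
#'
#' Least-squares fit of correlation energies against `1/Omega^exponent`
#' (default exponent 1: first-order finite-size correction).  The intercept
#' `E_inf` is the infinite-volume estimate.
#'
#' @param Omega supercell volumes (positive, strictly increasing once sorted;
#'   duplicates are an error).
#' @param E_c correlation energies at each volume.
#' @param exponent power of `1/Omega` used as abscissa (default 1).
#' @return list with `E_inf`, `coefficient`, `exponent`, `r_squared`.
#' @examples
#' volume_fit(c(500, 1000, 2000), -10 + 100 / c(500, 1000, 2000))$E_inf  # -10
#' @export
volume_fit <- function(Omega, E_c, exponent = 1) {
  stopifnot(length(Omega) == length(E_c), all(Omega > 0), exponent > 0)
  if (length(Omega) < 2) stop("insufficient points: need >= 2 volumes", call. = FALSE)
  if (anyDuplicated(Omega)) stop("degenerate abscissa: duplicate Omega", call. = FALSE)
  o <- order(Omega)
  Omega <- Omega[o]; E_c <- E_c[o]
  x <- Omega^(-exponent)
  fit <- stats::lm.fit(cbind(1, x), E_c)
  r <- fit$residuals
  tss <- sum((E_c - mean(E_c))^2)
  list(E_inf = unname(fit$coefficients[1]),
       coefficient = unname(fit$coefficients[2]),
       exponent = exponent,
       r_squared = if (tss > 0) 1 - sum(r^2) / tss else 1)
}
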