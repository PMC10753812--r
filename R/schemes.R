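## Scheme registry: every cardinal-number extrapolation law lives here.
##
## A scheme is a CBS constant plus shifted-power and/or exponential terms.
## Linear-in-parameter forms are solved exactly (point count = parameter
## count) or by least squares; forms with one nonlinear parameter (an
## exponential rate or a free power) are fitted by profiling that parameter:
## for every trial value the remaining problem is linear, so the fit is
## deterministic and needs no starting guesses.

new_scheme <- function(id, label, coef_names, basis,
                       components = c("corr", "total"),
                       theta = NULL) {
  ## basis: function(X, theta) -> matrix of term values (no intercept column)
  ## theta: NULL, or list(name, lower, upper, default) for the one nonlinear
  ##        parameter
  n_free <- 1L + length(coef_names) + (!is.null(theta))
  structure(
    list(id = id, label = label, coef_names = coef_names, basis = basis,
         components = components, theta = theta,
         n_free = n_free, min_points = n_free),
    class = "cbs_scheme"
  )
}

#' @export
print.cbs_scheme <- function(x, ...) {
  cat(sprintf("<cbs_scheme> %s: %s\n", x$id, x$label))
  cat(sprintf("  free parameters: %d (E_CBS%s%s); minimum points: %d\n",
              x$n_free,
              if (length(x$coef_names)) paste0(", ", paste(x$coef_names, collapse = ", ")) else "",
              if (!is.null(x$theta)) paste0(", ", x$theta$name) else "",
              x$min_points))
  cat(sprintf("  applicable components: %s\n", paste(x$components, collapse = ", ")))
  invisible(x)
}

power_basis <- function(powers, shifts) {
  force(powers); force(shifts)
  function(X, theta = NULL) {
    vapply(seq_along(powers),
           function(k) (X + shifts[k])^(-powers[k]),
           numeric(length(X)))
  }
}

#' Registry of CBS extrapolation schemes
#'
#' Returns the named list of all registered cardinal-number extrapolation
#' laws.  Every law has the form `E(X) = E_CBS + sum of terms`, where each
#' term is a shifted power `A (X + s)^(-p)` or an exponential `A exp(-c X)`.
#' The registered forms are:
#'
#' | id                 | form                                          | free | components |
#' |--------------------|-----------------------------------------------|------|------------|
#' | `feller`           | `E + B exp(-C X)`                             | 3    | HF, corr, total |
#' | `peterson`         | `E + B exp(-(X-1)) + C exp(-(X-1)^2)`         | 3    | HF, corr, total |
#' | `truhlar_hf`       | `E + A X^-3.4`                                | 2    | HF, total  |
#' | `truhlar_corr`     | `E + A X^-2.2`                                | 2    | corr, total |
#' | `martin4`          | `E + A (X+1/2)^-4`                            | 2    | corr, total |
#' | `martin46`         | `E + A (X+1/2)^-4 + B (X+1/2)^-6`             | 3    | corr, total |
#' | `martin_alpha`     | `E + A (X+1/2)^-alpha`, alpha free            | 3    | corr, total |
#' | `wilson35`         | `E + A X^-5`                                  | 2    | corr, total |
#' | `wilson45`         | `E + A (X+1)^-4`                              | 2    | corr, total |
#' | `helgaker_hf`      | `E + A exp(-alpha X)`, alpha free             | 3    | HF, total  |
#' | `helgaker_corr_x3` | `E + A X^-3`                                  | 2    | corr, total |
#' | `varandas34`       | `E + A (X-3/8)^-3 + B (X-3/8)^-4`             | 3    | corr, total |
#' | `varandas3_fit`    | `E + A (X-3/8)^-3`                            | 2    | corr, total |
#' | `var34_fit`        | `E + A ((X-3/8)^-3 + (X-3/8)^-4)`             | 2    | corr, total |
#' | `rovibi34`         | `E + A X^-3 + B (X-1/2)^-4`                   | 3    | corr, total |
#' | `rovibi45`         | `E + A (X-1/2)^-4 + B (X-1/2)^-5`             | 3    | corr, total |
#'
#' The fixed Truhlar exponents (3.4 for HF, 2.2 for correlation) are the
#' published minimal-RMSD values, which make those laws usable for two-point
#' extrapolations.  The Wilson laws are the two surviving members of the
#' four-parameter shifted-power ansatz under the constraints (alpha = 3,
#' B = 0, D = 0) and (alpha = 4, C = 0, D = 1).  `var34_fit` ties the
#' fourth-order coefficient to the third-order one (ratio 1) so that two
#' points suffice.  The Rovibi laws combine a principal-expansion `X^-3`
#' (or `(X-1/2)^-4`) leading term with a next-order term whose `-1/2` shift
#' averages the highest angular momentum `L = X - 1` (hydrogen) and `L = X`
#' (first-row atoms).
#'
#' @return named list of `cbs_scheme` objects.
#' @seealso [extrapolate()], [get_scheme()], [enumerate_generic_family()]
#' @export
scheme_registry <- function() {
  reg <- list(
    feller = new_scheme(
      "feller", "E_CBS + B exp(-C X)", "B",
      function(X, theta) matrix(exp(-theta * X), ncol = 1),
      components = c("HF", "corr", "total"),
      theta = list(name = "C", lower = 1e-4, upper = 25, default = 1)
    ),
    peterson = new_scheme(
      "peterson", "E_CBS + B exp(-(X-1)) + C exp(-(X-1)^2)", c("B", "C"),
      function(X, theta = NULL) cbind(exp(-(X - 1)), exp(-(X - 1)^2)),
      components = c("HF", "corr", "total")
    ),
    truhlar_hf = new_scheme(
      "truhlar_hf", "E_CBS + A X^-3.4 (alpha fixed at 3.4)", "A",
      power_basis(3.4, 0), components = c("HF", "total")
    ),
    truhlar_corr = new_scheme(
      "truhlar_corr", "E_CBS + A X^-2.2 (beta fixed at 2.2)", "A",
      power_basis(2.2, 0)
    ),
    martin4 = new_scheme(
      "martin4", "E_CBS + A (X+1/2)^-4", "A",
      power_basis(4, 0.5)
    ),
    martin46 = new_scheme(
      "martin46", "E_CBS + A (X+1/2)^-4 + B (X+1/2)^-6", c("A", "B"),
      power_basis(c(4, 6), c(0.5, 0.5))
    ),
    martin_alpha = new_scheme(
      "martin_alpha", "E_CBS + A (X+1/2)^-alpha (alpha free)", "A",
      function(X, theta) matrix((X + 0.5)^(-theta), ncol = 1),
      theta = list(name = "alpha", lower = 0.5, upper = 14, default = 4)
    ),
    wilson35 = new_scheme(
      "wilson35", "E_CBS + A X^-5", "A",
      power_basis(5, 0)
    ),
    wilson45 = new_scheme(
      "wilson45", "E_CBS + A (X+1)^-4", "A",
      power_basis(4, 1)
    ),
    helgaker_hf = new_scheme(
      "helgaker_hf", "E_CBS + A exp(-alpha X) (alpha free)", "A",
      function(X, theta) matrix(exp(-theta * X), ncol = 1),
      components = c("HF", "total"),
      theta = list(name = "alpha", lower = 1e-4, upper = 25, default = 1.63)
    ),
    helgaker_corr_x3 = new_scheme(
      "helgaker_corr_x3", "E_CBS + A X^-3", "A",
      power_basis(3, 0)
    ),
    varandas34 = new_scheme(
      "varandas34", "E_CBS + A (X-3/8)^-3 + B (X-3/8)^-4", c("A", "B"),
      power_basis(c(3, 4), c(-3 / 8, -3 / 8))
    ),
    varandas3_fit = new_scheme(
      "varandas3_fit", "E_CBS + A (X-3/8)^-3", "A",
      power_basis(3, -3 / 8)
    ),
    var34_fit = new_scheme(
      "var34_fit", "E_CBS + A ((X-3/8)^-3 + (X-3/8)^-4)", "A",
      function(X, theta = NULL) {
        t <- X - 3 / 8
        matrix(t^(-3) + t^(-4), ncol = 1)
      }
    ),
    rovibi34 = new_scheme(
      "rovibi34", "E_CBS + A X^-3 + B (X-1/2)^-4", c("A", "B"),
      power_basis(c(3, 4), c(0, -0.5))
    ),
    rovibi45 = new_scheme(
      "rovibi45", "E_CBS + A (X-1/2)^-4 + B (X-1/2)^-5", c("A", "B"),
      power_basis(c(4, 5), c(-0.5, -0.5))
    )
  )
  reg
}

#' Look up a scheme by id
#'
#' @param id scheme identifier (see [scheme_registry()]), or a `cbs_scheme`
#'   object, which is returned unchanged.
#' @return a `cbs_scheme`.
#' @export
get_scheme <- function(id) {
  if (inherits(id, "cbs_scheme")) return(id)
  reg <- scheme_registry()
  if (!id %in% names(reg)) {
    stop("unknown scheme '", id, "'; registered schemes: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[id]]
}

#' Build a generic shifted-power scheme
#'
#' Single-power form `E_CBS + A (X + shift_alpha)^-alpha` or two-power form
#' `E_CBS + A (X + shift_alpha)^-alpha + B (X + shift_beta)^-beta`.
#'
#' @param alpha leading (positive) power.
#' @param beta optional second power, must exceed `alpha`.
#' @param shift_alpha,shift_beta rational X-shifts; `X + shift` must stay
#'   positive for X >= 2.
#' @return a `cbs_scheme` with a systematic id such as `"gen_p3s0"` or
#'   `"gen_p3s0_p4s-0.5"`.
#' @export
generic_scheme <- function(alpha, beta = NULL, shift_alpha = 0, shift_beta = 0) {
  stopifnot(alpha > 0)
  fmt <- function(p, s) sprintf("p%ss%s", format(p), format(s))
  if (is.null(beta)) {
    id <- sprintf("gen_%s", fmt(alpha, shift_alpha))
    new_scheme(id,
               sprintf("E_CBS + A (X%+g)^-%g", shift_alpha, alpha), "A",
               power_basis(alpha, shift_alpha))
  } else {
    if (beta <= alpha) stop("beta must exceed alpha", call. = FALSE)
    id <- sprintf("gen_%s_%s", fmt(alpha, shift_alpha), fmt(beta, shift_beta))
    new_scheme(id,
               sprintf("E_CBS + A (X%+g)^-%g + B (X%+g)^-%g",
                       shift_alpha, alpha, shift_beta, beta),
               c("A", "B"),
               power_basis(c(alpha, beta), c(shift_alpha, shift_beta)))
  }
}

#' Enumerate the generic shifted-power scheme family
#'
#' Generates one single-power scheme per (alpha, shift) pair and one
#' two-power scheme per (alpha < beta, shift_alpha, shift_beta) combination,
#' deduplicated.  This is the family searched to find improved three-point
#' laws; with shifts `{0, -1/2}` it contains schemes equivalent to
#' `rovibi34` and `rovibi45`.
#'
#' @param alphas set of leading powers, a subset of `3:6`.
#' @param betas set of second powers (may be empty, `NULL`, for single-power
#'   laws only), a subset of `3:6`.
#' @param shifts finite set of rational X-shifts; default `c(-1, -1/2, 0, 1/2)`.
#' @return list of `cbs_scheme` objects.
#' @examples
#' length(enumerate_generic_family(3:6, 3:6, shifts = 0))  # 4 + 6 = 10
#' @export
enumerate_generic_family <- function(alphas, betas = alphas,
                                     shifts = c(-1, -0.5, 0, 0.5)) {
  if (length(alphas) == 0) stop("empty family: no alphas supplied", call. = FALSE)
  stopifnot(all(alphas %in% 3:6), all(shifts > -2))
  if (!is.null(betas) && length(betas)) stopifnot(all(betas %in% 3:6))
  specs <- list()
  for (a in sort(unique(alphas))) {
    for (sa in sort(unique(shifts))) {
      sp <- generic_scheme(a, shift_alpha = sa)
      specs[[sp$id]] <- sp
    }
  }
  if (!is.null(betas)) {
    for (a in sort(unique(alphas))) {
      for (b in sort(unique(betas))) {
        if (b <= a) next
        for (sa in sort(unique(shifts))) {
          for (sb in sort(unique(shifts))) {
            sp <- generic_scheme(a, b, sa, sb)
            specs[[sp$id]] <- sp
          }
        }
      }
    }
  }
  unname(specs)
}

## Fitting engine -------------------------------------------------------------

as_points <- function(points) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, length, 1L) == 2)) {
    points <- data.frame(X = vapply(points, `[[`, 0, 1),
                         energy = vapply(points, `[[`, 0, 2))
  }
  stopifnot(is.data.frame(points))
  names(points)[1:2] <- c("X", "energy")
  points$X <- as.numeric(points$X)
  points$energy <- as.numeric(points$energy)
  if (anyDuplicated(points$X)) stop("degenerate abscissa: duplicate X values", call. = FALSE)
  points[order(points$X), , drop = FALSE]
}

solve_linear <- function(A, y) {
  ## exact solve when square, least squares otherwise
  if (nrow(A) == ncol(A)) {
    as.numeric(solve(A, y))
  } else {
    as.numeric(qr.coef(qr(A), y))
  }
}

rss_at_theta <- function(scheme, X, y, theta) {
  A <- cbind(1, scheme$basis(X, theta))
  beta <- solve_linear(A, y)
  r <- y - as.numeric(A %*% beta)
  list(rss = sum(r^2), beta = beta, resid = r)
}

## For one-nonlinear-parameter schemes with point count == parameter count the
## exact interpolation condition is a single scalar root: after eliminating
## E_CBS and the linear coefficient from three points (X1<X2<X3),
##   (E1-E2) (g(X2)-g(X3)) = (E2-E3) (g(X1)-g(X2)),   g = theta-term.
profile_exact <- function(scheme, X, y) {
  g <- function(theta) as.numeric(scheme$basis(X, theta))
  h <- function(theta) {
    gv <- g(theta)
    (y[1] - y[2]) * (gv[2] - gv[3]) - (y[2] - y[3]) * (gv[1] - gv[2])
  }
  lo <- scheme$theta$lower
  hi <- scheme$theta$upper
  grid <- exp(seq(log(lo), log(hi), length.out = 200))
  hv <- vapply(grid, h, 0)
  sgn <- sign(hv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0) return(NULL)
  uniroot(h, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-15)$root
}

#' Extrapolate a cardinal-number energy series to the basis-set limit
#'
#' Fits one of the registered extrapolation laws to `(X, energy)` points.
#' When the point count equals the number of free parameters the linear (or
#' profiled) system is solved exactly, so residuals vanish; with more points
#' an ordinary least-squares fit is returned.
#'
#' @param points a data frame (or 2-column matrix, or list of pairs) with
#'   columns `X` (cardinal number) and `energy`, strictly increasing in `X`.
#' @param scheme a scheme id (see [scheme_registry()]) or `cbs_scheme`.
#' @param component one of `"HF"`, `"corr"`, `"total"`; checked against the
#'   scheme's applicability.
#' @param unit energy unit carried through to the result (bookkeeping only;
#'   the fit itself is unit-agnostic).
#' @return an object of class `cbs_fit` with elements `E_CBS`, `params`
#'   (named coefficient vector, including any nonlinear parameter),
#'   `residuals`, `points`, `fit_mode` (`"exact-solve"` or
#'   `"least-squares"`), `converged`, `scheme`, `unit`.
#' @examples
#' pts <- data.frame(X = 3:4, energy = -100 + 2 * (3:4)^-3)
#' extrapolate(pts, "helgaker_corr_x3")$E_CBS  # -100
#' @export
extrapolate <- function(points, scheme, component = "corr", unit = NULL) {
  scheme <- get_scheme(scheme)
  component <- match.arg(component, c("HF", "corr", "total"))
  if (!component %in% scheme$components) {
    stop(sprintf("scheme '%s' is not applicable to component '%s' (allowed: %s)",
                 scheme$id, component, paste(scheme$components, collapse = ", ")),
         call. = FALSE)
  }
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < scheme$min_points) {
    stop(sprintf("insufficient points: scheme '%s' needs at least %d, got %d",
                 scheme$id, scheme$min_points, n), call. = FALSE)
  }
  X <- pts$X
  y <- pts$energy
  exact <- n == scheme$n_free
  theta_val <- NULL
  converged <- TRUE

  if (is.null(scheme$theta)) {
    A <- cbind(1, scheme$basis(X))
    beta <- solve_linear(A, y)
    resid <- y - as.numeric(A %*% beta)
  } else {
    if (isTRUE(diff(range(y)) == 0)) {
      ## constant series: coefficients vanish, nonlinear parameter moot
      theta_val <- scheme$theta$default
      beta <- c(y[1], rep(0, length(scheme$coef_names)))
      resid <- rep(0, n)
    } else if (exact) {
      theta_val <- profile_exact(scheme, X, y)
      if (is.null(theta_val)) {
        ## no interpolating parameter value: fall back to best least squares
        opt <- stats::optimize(function(th) rss_at_theta(scheme, X, y, th)$rss,
                               c(scheme$theta$lower, scheme$theta$upper),
                               tol = 1e-12)
        theta_val <- opt$minimum
        converged <- FALSE
      }
      fit <- rss_at_theta(scheme, X, y, theta_val)
      beta <- fit$beta
      resid <- fit$resid
      if (!converged && fit$rss > 1e-8 * max(1, sum(y^2))) {
        stop(sprintf(paste0("fit failed: scheme '%s' has no interpolating ",
                            "parameter in [%g, %g] (best residual sum %.3e)"),
                     scheme$id, scheme$theta$lower, scheme$theta$upper, fit$rss),
             call. = FALSE)
      }
    } else {
      opt <- stats::optimize(function(th) rss_at_theta(scheme, X, y, th)$rss,
                             c(scheme$theta$lower, scheme$theta$upper),
                             tol = 1e-12)
      theta_val <- opt$minimum
      fit <- rss_at_theta(scheme, X, y, theta_val)
      beta <- fit$beta
      resid <- fit$resid
    }
  }

  if (!all(is.finite(beta))) {
    stop(sprintf("fit failed: non-finite parameters for scheme '%s'", scheme$id),
         call. = FALSE)
  }
  params <- stats::setNames(beta[-1], scheme$coef_names)
  if (!is.null(theta_val)) params[scheme$theta$name] <- theta_val
  structure(
    list(E_CBS = beta[1], params = params, residuals = resid,
         points = pts, fit_mode = if (exact) "exact-solve" else "least-squares",
         converged = converged, scheme = scheme$id, unit = unit),
    class = "cbs_fit"
  )
}

#' @export
print.cbs_fit <- function(x, ...) {
  cat(sprintf("<cbs_fit> scheme %s (%s, %d points)\n",
              x$scheme, x$fit_mode, nrow(x$points)))
  cat(sprintf("  E_CBS = %.10g%s\n", x$E_CBS,
              if (!is.null(x$unit)) paste0(" ", x$unit) else ""))
  if (length(x$params)) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$params), x$params),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  interpolation MAE = %.3g\n", interpolation_error(x)))
  invisible(x)
}

#' Mean absolute residual of an extrapolation fit
#'
#' How faithfully the fitted law reproduces the single data points: the mean
#' of absolute residuals over the fitted points, in the input unit.  Zero for
#' exact-solve fits.
#'
#' @param result a `cbs_fit` from [extrapolate()].
#' @return numeric scalar.
#' @export
interpolation_error <- function(result) {
  stopifnot(inherits(result, "cbs_fit"), length(result$residuals) >= 1)
  mean(abs(result$residuals))
}

#' Recommended scheme for a given component and point set
#'
#' Encodes the study's practical recommendations: Hartree-Fock energies are
#' extrapolated with the three-point exponential (`helgaker_hf`); correlation
#' energies with `helgaker_corr_x3` for a DT pair, `martin4` for higher
#' two-point pairs (TQ, Q5), and `rovibi34` when three or more points are
#' available.
#'
#' @param X integer vector of available cardinal numbers.
#' @param component `"HF"`, `"corr"`, or `"total"`.
#' @return a `cbs_scheme`.
#' @export
recommended_scheme <- function(X, component = "corr") {
  component <- match.arg(component, c("HF", "corr", "total"))
  X <- sort(unique(X))
  if (component == "HF") return(get_scheme("helgaker_hf"))
  if (length(X) >= 3) return(get_scheme("rovibi34"))
  if (length(X) == 2 && X[1] == 2) return(get_scheme("helgaker_corr_x3"))
  get_scheme("martin4")
}
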