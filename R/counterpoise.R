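## Counterpoise bookkeeping for dimer interaction energies and the deviation
## statistics used to compare basis-set results against a reference.

#' Construct a dimer energy set
#'
#' Bundles the five energies entering counterpoise-corrected interaction
#' energies: the dimer energy, each monomer in its own basis, and (optionally)
#' each monomer in the full dimer basis with ghost functions at the partner's
#' positions.  Monomer geometries are assumed frozen at their in-dimer
#' structures; deformation energies are not handled.
#'
#' @param E_AB dimer energy.
#' @param E_A_own,E_B_own monomer energies in their own bases.
#' @param E_A_ghost,E_B_ghost monomer energies in the full dimer basis
#'   (ghost functions on the partner); optional.
#' @param unit energy unit, `"hartree"` or `"kcal/mol"`.
#' @return an object of class `dimer_energy_set`.
#' @export
dimer_energy_set <- function(E_AB, E_A_own, E_B_own,
                             E_A_ghost = NA_real_, E_B_ghost = NA_real_,
                             unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  s <- list(E_AB = E_AB, E_A_own = E_A_own, E_B_own = E_B_own,
            E_A_ghost = E_A_ghost, E_B_ghost = E_B_ghost, unit = unit)
  stopifnot(all(vapply(s[1:3], function(x) is.numeric(x) && is.finite(x), TRUE)))
  ## variationally, a monomer can only be stabilised by extra (ghost) basis
  ## functions; MP2 correlation is not variational, hence a warning only
  if (is.finite(E_A_ghost) && E_A_ghost > E_A_own + 1e-12)
    warning("E_A_ghost above E_A_own: not variational at this level?", call. = FALSE)
  if (is.finite(E_B_ghost) && E_B_ghost > E_B_own + 1e-12)
    warning("E_B_ghost above E_B_own: not variational at this level?", call. = FALSE)
  structure(s, class = "dimer_energy_set")
}

#' Uncorrected, counterpoise-corrected, and half-corrected interaction energies
#'
#' Computes the three standard interaction-energy flavours:
#' \deqn{\Delta E_{uncorr} = E_{AB} - E_A^{\{A\}} - E_B^{\{B\}}}
#' \deqn{\Delta E_{CP} = E_{AB} - E_A^{\{AB\}} - E_B^{\{AB\}}}
#' \deqn{\Delta E_{half} = (\Delta E_{uncorr} + \Delta E_{CP})/2}
#' where `{A}` is the monomer basis and `{AB}` the full dimer basis with
#' ghost functions on the partner.  The difference `uncorr - cp` estimates
#' the basis set superposition error, which tends to overbind dimers.
#'
#' @param s a [dimer_energy_set()].
#' @return named list `uncorr`, `cp`, `half_cp` in kcal/mol (`cp` and
#'   `half_cp` are `NA` when ghost energies are absent).
#' @examples
#' s <- dimer_energy_set(-2.0, -0.7, -0.9, -0.75, -0.95)
#' interaction_energies(s)  # uncorr -0.4, cp -0.3, half_cp -0.35
#' @export
interaction_energies <- function(s) {
  stopifnot(inherits(s, "dimer_energy_set"))
  to_kcal <- function(x) if (s$unit == "hartree") convert_energy(x, "hartree", "kcal/mol") else x
  uncorr <- s$E_AB - s$E_A_own - s$E_B_own
  if (is.finite(s$E_A_ghost) && is.finite(s$E_B_ghost)) {
    cp <- s$E_AB - s$E_A_ghost - s$E_B_ghost
    half <- (uncorr + cp) / 2
  } else {
    cp <- NA_real_
    half <- NA_real_
  }
  list(uncorr = to_kcal(uncorr), cp = to_kcal(cp), half_cp = to_kcal(half))
}

#' Deviation statistics between two energy vectors
#'
#' Statistics of the differences `values - reference`: mean absolute error,
#' mean signed deviation, the signed value of the largest-magnitude
#' deviation, median and quartiles, and outlier labels under the box-plot
#' rule (further than 1.5 times the interquartile range from the first or
#' third quartile).  Quartiles use linear interpolation between order
#' statistics (type 7), which the outlier rule inherits.
#'
#' @param values numeric vector.
#' @param reference numeric vector of the same length.
#' @param labels optional labels for outlier reporting.
#' @param absolute_max if `TRUE`, report `max_dev` as an absolute value
#'   instead of the signed default.
#' @return an object of class `deviation_stats`: list with `mae`, `msd`,
#'   `max_dev`, `median`, `q1`, `q3`, `outliers`, `n`.
#' @examples
#' deviation_stats(c(0.1, -0.3, 0.2), c(0, 0, 0))
#' @export
deviation_stats <- function(values, reference, labels = NULL,
                            absolute_max = FALSE) {
  if (length(values) != length(reference))
    stop("shape error: values and reference differ in length", call. = FALSE)
  stopifnot(length(values) >= 1)
  if (is.null(labels)) labels <- as.character(seq_along(values))
  if (length(labels) != length(values))
    stop("shape error: labels length mismatch", call. = FALSE)
  d <- values - reference
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- d < q[1] - 1.5 * iqr | d > q[3] + 1.5 * iqr
  imax <- which.max(abs(d))
  structure(
    list(mae = mean(abs(d)), msd = mean(d),
         max_dev = if (absolute_max) abs(d[imax]) else d[imax],
         median = q[2], q1 = q[1], q3 = q[3],
         outliers = labels[out], n = length(d)),
    class = "deviation_stats"
  )
}

#' @export
print.deviation_stats <- function(x, ...) {
  cat(sprintf("<deviation_stats> n = %d\n", x$n))
  cat(sprintf("  MAE %.4g | MSD %.4g | max dev %.4g (signed)\n",
              x$mae, x$msd, x$max_dev))
  cat(sprintf("  median %.4g [Q1 %.4g, Q3 %.4g]\n", x$median, x$q1, x$q3))
  if (length(x$outliers))
    cat("  outliers (1.5 IQR):", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
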