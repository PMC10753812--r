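## Basis-size bookkeeping: contracted spherical-harmonic function counts for
## (aug-)cc-pVXZ, the cardinal-number growth laws, and the plane-wave count
## estimate for a cell and cutoff.

## Contracted spherical function counts per element and cardinal number,
## X = 2 (D) .. 5, from the published correlation-consistent compositions
## (e.g. H/cc-pVDZ [2s1p] = 5, first-row cc-pVDZ [3s2p1d] = 14).
.basis_counts <- list(
  cc = list(H = c(`2` = 5, `3` = 14, `4` = 30, `5` = 55),
            first_row = c(`2` = 14, `3` = 30, `4` = 55, `5` = 91)),
  `aug-cc` = list(H = c(`2` = 9, `3` = 23, `4` = 46, `5` = 80),
                  first_row = c(`2` = 23, `3` = 46, `4` = 80, `5` = 127))
)

.first_row <- c("B", "C", "N", "O", "F", "Ne")

#' Parse a Hill-notation molecular formula
#'
#' @param formula string such as `"C14H13N"` or `"H2O"`.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C14H13N")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  agg <- tapply(n, el, sum)[unique(el)]
  stats::setNames(as.integer(agg), names(agg))
}

#' Count contracted basis functions for a molecule
#'
#' Sum over atoms of the per-element contracted spherical-harmonic function
#' count of the requested correlation-consistent family and cardinal
#' number.  Hydrogen and the first-row elements B-Ne are supported.
#'
#' @param formula a Hill-notation string or a named count vector from
#'   [parse_formula()].
#' @param family `"cc"` or `"aug-cc"`.
#' @param X cardinal number, 2 (D) to 5.
#' @return integer function count.
#' @examples
#' count_functions("H2O", "aug-cc", 3)      # 92
#' count_functions("C14H13N", "aug-cc", 5)  # 2945
#' @export
count_functions <- function(formula, family = c("cc", "aug-cc"), X) {
  family <- match.arg(family)
  stopifnot(length(X) == 1, X %in% 2:5)
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  tab <- .basis_counts[[family]]
  per <- vapply(names(counts), function(el) {
    if (el == "H") tab$H[[as.character(X)]]
    else if (el %in% .first_row) tab$first_row[[as.character(X)]]
    else stop("element not in table: ", el,
              " (H and first-row B-Ne supported)", call. = FALSE)
  }, numeric(1))
  as.integer(sum(per * counts))
}

#' Basis-size growth with the cardinal number
#'
#' Number of contracted spherical functions per first-row atom:
#' `N_b(cc) = (X+1)(X+2)(2X+3)/6` and `N_b(aug) = N_b(cc) + (X+1)^2` (one
#' diffuse function per angular momentum `l = 0..X` adds `(X+1)^2`
#' spherical components).  Both grow cubically in `X`, which is what makes
#' the MP2 cost climb like `X^12` through its `N_b^4` factor.
#'
#' @param X cardinal number(s), `>= 2`.
#' @param family `"cc"` or `"aug-cc"`.
#' @return numeric vector of per-atom function counts.
#' @examples
#' nb_growth(2:5, "cc")  # 14 30 55 91
#' @export
nb_growth <- function(X, family = c("cc", "aug-cc")) {
  family <- match.arg(family)
  stopifnot(all(X >= 2))
  nb <- (X + 1) * (X + 2) * (2 * X + 3) / 6
  if (family == "aug-cc") nb <- nb + (X + 1)^2
  nb
}

#' Continuum estimate of the plane-wave count
#'
#' Sphere-volume estimate of the number of G vectors with
#' `|G|^2 / 2 <= E_cut` in a cell of volume `Omega`:
#' `N_G ~ Omega (2 E_cut)^(3/2) / (6 pi^2)`.  The estimate tends to the
#' exact lattice enumeration as the cutoff grows; at `E_cut = 0` it returns
#' 0 while the enumeration keeps the single `G = 0` state.
#'
#' @param Omega cell volume in bohr^3.
#' @param E_cut cutoff in hartree.
#' @return real-valued estimate of `N_G`.
#' @examples
#' ng_estimate((2 * pi)^3, 2)  # ~33.5; exact enumeration gives 33
#' @export
ng_estimate <- function(Omega, E_cut) {
  stopifnot(Omega > 0, E_cut >= 0)
  Omega * (2 * E_cut)^1.5 / (6 * pi^2)
}

#' Virtual-orbital count bookkeeping
#'
#' `N_vir = N_G - N_occ`: the virtual space is the algebraic consequence of
#' the basis being larger than the number of occupied orbitals.
#'
#' @param N_G basis size.
#' @param N_occ occupied-orbital count.
#' @return integer virtual count.
#' @examples
#' virtual_count(408126, 37)  # 408089
#' @export
virtual_count <- function(N_G, N_occ) {
  stopifnot(N_G >= N_occ, N_occ >= 0)
  as.integer(N_G) - as.integer(N_occ)
}
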