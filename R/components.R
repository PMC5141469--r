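#' Atomic composition
#'
#' A bag of atoms (element symbol -> count) with a count of labile hydrogens,
#' the subset of H that exchanges for D in D2O buffers. Counts may be
#' fractional, which is convenient for average-residue or mixture
#' compositions.
#'
#' @param counts named numeric vector, element symbol -> count.
#' @param n_exchangeable_H number of labile hydrogens (must not exceed the H
#'   count).
#' @return An object of class `atomic_composition`.
#' @export
atomic_composition <- function(counts, n_exchangeable_H = 0) {
  if (length(counts) == 0 || is.null(names(counts)))
    stop("counts must be a non-empty named vector")
  unknown <- setdiff(names(counts), names(.neutron_b))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("element counts must be >= 0")
  nH <- if ("H" %in% names(counts)) counts[["H"]] else 0
  if (n_exchangeable_H < 0 || n_exchangeable_H > nH + 1e-9)
    stop("n_exchangeable_H must lie in [0, H count]")
  structure(list(counts = counts, n_exchangeable_H = n_exchangeable_H),
            class = "atomic_composition")
}

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C24H46O11"`. Element symbols are one capital letter
#'   optionally followed by a lowercase letter, each followed by an optional
#'   integer count.
#' @param n_exchangeable_H labile hydrogen count.
#' @return An `atomic_composition`.
#' @export
parse_formula <- function(formula, n_exchangeable_H = 0) {
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- numeric(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  atomic_composition(counts, n_exchangeable_H)
}

composition_mass <- function(comp) {
  sum(comp$counts * .atomic_mass[names(comp$counts)])
}

## Non-exchanged scattering length of a composition, fm per formula unit.
composition_b0 <- function(comp) {
  sum(comp$counts * .neutron_b[names(comp$counts)])
}

#' Hydrogen/deuterium exchange model
#'
#' Fraction of labile hydrogens replaced by deuterium in pure D2O, with a
#' low/high band used for uncertainty propagation. The default band 0.70-0.90
#' around 0.80 reflects the commonly assumed 70-90 percent exchange for
#' solvent-exposed labile hydrogens.
#'
#' @param fraction central exchange fraction at 100 percent D2O.
#' @param low,high band limits for error propagation.
#' @return An object of class `exchange_model`.
#' @export
exchange_model <- function(fraction = 0.80, low = 0.70, high = 0.90) {
  if (!(0 <= low && low <= fraction && fraction <= high && high <= 1))
    stop("require 0 <= low <= fraction <= high <= 1")
  structure(list(fraction = fraction, low = low, high = high),
            class = "exchange_model")
}

#' Chemical component of a scattering particle
#'
#' @param name label.
#' @param composition an `atomic_composition`, or a formula string.
#' @param n_exchangeable_H labile H count (used when `composition` is a
#'   formula string).
#' @param specific_volume partial specific volume in ml/g; used to derive the
#'   dry volume when `dry_volume` is not given.
#' @param dry_volume volume per formula unit in cubic Angstroms; overrides
#'   `specific_volume`.
#' @param role one of `"protein"`, `"lipid"`, `"detergent"`, `"other"`.
#' @return An object of class `sans_component`.
#' @export
component <- function(name, composition, n_exchangeable_H = 0,
                      specific_volume = NULL, dry_volume = NULL,
                      role = c("other", "protein", "lipid", "detergent")) {
  role <- match.arg(role)
  if (is.character(composition))
    composition <- parse_formula(composition, n_exchangeable_H)
  stopifnot(inherits(composition, "atomic_composition"))
  molar_mass <- composition_mass(composition)
  if (is.null(dry_volume)) {
    if (is.null(specific_volume))
      stop("give either dry_volume [A^3] or specific_volume [ml/g]")
    dry_volume <- molar_mass * specific_volume / .N_AVOGADRO * 1e24
  }
  if (dry_volume <= 0) stop("dry_volume must be > 0")
  if (molar_mass <= 0) stop("molar_mass must be > 0")
  structure(list(name = name, composition = composition,
                 dry_volume = dry_volume, molar_mass = molar_mass,
                 role = role),
            class = "sans_component")
}

#' @export
print.sans_component <- function(x, ...) {
  cat(sprintf("<component '%s' (%s): M = %.1f g/mol, V = %.1f A^3, %g labile H>\n",
              x$name, x$role, x$molar_mass, x$dry_volume,
              x$composition$n_exchangeable_H))
  invisible(x)
}

#' Neutron scattering length of a component at a given D2O fraction
#'
#' Sum of atomic coherent scattering lengths plus the labile-hydrogen
#' exchange term `n_ex * exchange_fraction * f_d2o * (b_D - b_H)`. The value
#' is affine in `f_d2o`.
#'
#' @param comp a `sans_component` (or `atomic_composition`).
#' @param f_d2o D2O volume fraction of the solvent, 0-1.
#' @param xm an `exchange_model`; its band gives the low/high values.
#' @return list with `value`, `low`, `high` in cm per formula unit.
#' @export
component_scattering_length <- function(comp, f_d2o, xm = exchange_model()) {
  cc <- if (inherits(comp, "sans_component")) comp$composition else comp
  stopifnot(inherits(cc, "atomic_composition"))
  if (any(f_d2o < 0) || any(f_d2o > 1)) stop("f_d2o must lie in [0, 1]")
  b0 <- composition_b0(cc)
  db <- .neutron_b[["D"]] - .neutron_b[["H"]]
  b_at <- function(fex) (b0 + cc$n_exchangeable_H * fex * f_d2o * db) * .CM_PER_FM
  list(value = b_at(xm$fraction), low = b_at(xm$low), high = b_at(xm$high))
}

## Component SLD [1/A^2] as affine function of f_d2o: returns c(intercept, slope)
component_sld_line <- function(comp, fex) {
  cc <- comp$composition
  db <- .neutron_b[["D"]] - .neutron_b[["H"]]
  b0 <- composition_b0(cc)
  c(intercept = b0 * .FM_PER_A / comp$dry_volume,
    slope = cc$n_exchangeable_H * fex * db * .FM_PER_A / comp$dry_volume)
}

#' Component scattering-length density
#'
#' @inheritParams component_scattering_length
#' @return SLD in inverse square Angstroms (central exchange fraction).
#' @export
component_sld <- function(comp, f_d2o, xm = exchange_model()) {
  ln <- component_sld_line(comp, xm$fraction)
  ln[["intercept"]] + f_d2o * ln[["slope"]]
}

#' Contrast match point of a component
#'
#' The solvent D2O percentage at which the component's scattering-length
#' density (including labile-H exchange) equals the solvent's. Both are
#' linear in the D2O fraction, so the match point is the crossing of two
#' straight lines. Values outside 0-100 are returned but flagged.
#'
#' @param comp a `sans_component`.
#' @param xm an `exchange_model`; the band endpoints give `low`/`high`.
#' @return list with `value`, `low`, `high` (percent D2O) and `in_range`.
#' @export
match_point <- function(comp, xm = exchange_model()) {
  stopifnot(inherits(comp, "sans_component"))
  root_at <- function(fex) {
    ln <- component_sld_line(comp, fex)
    denom <- (.SLD_D2O - .SLD_H2O) - ln[["slope"]]
    if (abs(denom) < 1e-12 * abs(.SLD_D2O - .SLD_H2O))
      stop("component and solvent SLD lines are parallel: no match point")
    (ln[["intercept"]] - .SLD_H2O) / denom
  }
  v <- frac_to_pct(root_at(xm$fraction))
  lo <- frac_to_pct(root_at(xm$low))
  hi <- frac_to_pct(root_at(xm$high))
  list(value = v, low = min(lo, hi), high = max(lo, hi),
       in_range = v >= 0 && v <= 100)
}

#' Match point of a mixture
#'
#' Given numeric match points, returns the volume-fraction weighted mean --
#' the standard recast of the component-sum relation used to mix and unmix
#' match points. Given component objects, solves the exact zero of the
#' summed excess scattering length instead: when the components' labile-H
#' exchange slopes differ, the exact root deviates slightly from the
#' volume-weighted mean of the individual match points (the weighted mean
#' weights each component by volume times its own contrast slope). Both
#' forms are bounded by the extreme component match points and monotone in
#' each volume fraction.
#'
#' @param cmps numeric vector of match points (percent D2O), or a list of
#'   `sans_component` objects.
#' @param fractions volume fractions (renormalised to sum 1).
#' @param xm exchange model used when `cmps` are components.
#' @return Match point in percent D2O.
#' @export
mixture_match_point <- function(cmps, fractions, xm = exchange_model()) {
  if (length(cmps) != length(fractions))
    stop("cmps and fractions must have equal length")
  if (!length(cmps)) stop("empty component list")
  if (any(fractions < 0) || sum(fractions) <= 0)
    stop("fractions must be >= 0 with positive sum")
  fractions <- fractions / sum(fractions)
  if (is.list(cmps)) {
    ## exact root of sum_i v_i (rho_i(f) - rho_s(f)) = 0
    num <- 0; den <- 0
    for (i in seq_along(cmps)) {
      stopifnot(inherits(cmps[[i]], "sans_component"))
      ln <- component_sld_line(cmps[[i]], xm$fraction)
      num <- num + fractions[i] * (ln[["intercept"]] - .SLD_H2O)
      den <- den + fractions[i] * ((.SLD_D2O - .SLD_H2O) - ln[["slope"]])
    }
    if (abs(den) < 1e-18) stop("mixture has no match point (parallel lines)")
    return(frac_to_pct(num / den))
  }
  sum(cmps * fractions)
}

#' Invert two-component match-point mixing
#'
#' Given the match point of a two-component mixture and the match points of
#' the pure components, return the volume fraction of component a:
#' `(cmp_total - cmp_b) / (cmp_a - cmp_b)`.
#'
#' @param cmp_total,cmp_a,cmp_b match points in percent D2O.
#' @return Volume fraction of a in \[0, 1\] (clamped with a warning when the
#'   algebraic solution falls outside).
#' @export
solve_mixing_fraction <- function(cmp_total, cmp_a, cmp_b) {
  if (abs(cmp_a - cmp_b) < 1e-12)
    stop("component match points coincide: mixing fraction is undetermined")
  f <- (cmp_total - cmp_b) / (cmp_a - cmp_b)
  if (f < 0 || f > 1) {
    warning(sprintf("mixing fraction %.3f outside [0, 1]; clamped", f))
    f <- min(max(f, 0), 1)
  }
  f
}
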