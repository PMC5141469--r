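#' Water calibration constants
#'
#' Constants of the water-normalisation bracket used to put raw forward
#' intensities on absolute scale: the transmission of a 1 mm water cell, the
#' wavelength-dependent anisotropy factor f(lambda) of water scattering, and
#' the water path length. Defaults are the 6 Angstrom values
#' (f(lambda) = 0.8, T_water = 0.53, 0.1 cm cell).
#'
#' @param T_water transmission of the water calibration cell.
#' @param f_lambda water scattering anisotropy factor at the wavelength used.
#' @param t_water water cell path length, cm.
#' @return list of calibration constants.
#' @export
water_calibration <- function(T_water = 0.53, f_lambda = 0.8, t_water = 0.1) {
  stopifnot(T_water > 0, T_water <= 1, f_lambda > 0, t_water > 0)
  list(T_water = T_water, f_lambda = f_lambda, t_water = t_water)
}

#' Convert a water-normalised forward intensity to absolute scale
#'
#' Jacrot-style normalisation: the sample count rate divided by the water
#' count rate, corrected for transmissions and path lengths, times the known
#' isotropic cross-section of water `(1 - T_w) / (4 pi t_w f(lambda))`.
#'
#' @param I0_ratio forward intensity of the sample divided by the forward
#'   intensity of water, both background-corrected count rates.
#' @param transmission sample transmission.
#' @param path_length sample path length, cm.
#' @param calib a [water_calibration()].
#' @return I(0) in 1/cm.
#' @export
absolute_I0_from_water <- function(I0_ratio, transmission, path_length,
                                   calib = water_calibration()) {
  stopifnot(transmission > 0, transmission <= 1, path_length > 0)
  I0_ratio * (calib$T_water * calib$t_water) /
    (transmission * path_length) *
    (1 - calib$T_water) / (4 * pi * calib$t_water * calib$f_lambda)
}

#' Per-particle excess scattering length from absolute-scale I(0)
#'
#' On absolute scale, `I(0) = n (rho V)^2` with `n = c NA / MW` the particle
#' number density, so the magnitude of the per-particle excess scattering
#' length is `sqrt(I(0) MW / (c NA))`. The sign (which side of the match
#' point the solvent lies on) is assigned later by [fit_cv_line()].
#'
#' @param I0 forward intensity, 1/cm (absolute scale). If the value is a raw
#'   water-normalised ratio, convert first with [absolute_I0_from_water()].
#' @param I0_err uncertainty on I0, 1/cm.
#' @param concentration protein concentration, mg/ml.
#' @param M_W molar mass of the protein component, g/mol (per particle).
#' @return list with `rhoV` and `rhoV_err`, cm per particle.
#' @export
scattering_length_from_I0 <- function(I0, I0_err, concentration, M_W) {
  stopifnot(concentration > 0, M_W > 0)
  if (any(I0 < 0)) stop("I0 must be >= 0 (buffer-subtracted forward intensity)")
  n_dens <- concentration * 1e-3 * .N_AVOGADRO / M_W   # particles / cm^3
  rhoV <- sqrt(I0 / n_dens)
  rhoV_err <- ifelse(rhoV > 0, I0_err / (2 * sqrt(I0 * n_dens)), NA_real_)
  list(rhoV = rhoV, rhoV_err = rhoV_err)
}

#' Excess scattering length of a component at a given solvent
#'
#' `(SLD_component(f) - SLD_solvent(f)) * V`, in cm per formula unit; the
#' theoretical straight line a pure component traces on the
#' contrast-variation plot. Vanishes at the component's match point.
#'
#' @param comp a `sans_component`.
#' @param d2o_pct solvent percent D2O (vectorised).
#' @param xm exchange model.
#' @return list with `value`, `low`, `high` (exchange band), cm.
#' @export
component_excess_b <- function(comp, d2o_pct, xm = exchange_model()) {
  f <- pct_to_frac(d2o_pct)
  at <- function(fex) {
    ln <- component_sld_line(comp, fex)
    sld <- ln[["intercept"]] + f * ln[["slope"]]
    (sld - solvent_sld(f)) * comp$dry_volume * .A_TO_CM
  }
  v <- at(xm$fraction); a <- at(xm$low); b <- at(xm$high)
  list(value = v, low = pmin(a, b), high = pmax(a, b))
}

#' Fit the contrast-variation line
#'
#' Fits a weighted straight line of signed per-particle excess scattering
#' length versus percent D2O and returns its root, the contrast match point
#' of the whole particle. Guinier analysis yields only |rho V|; the sign
#' changes where the line crosses zero. Under `sign_policy = "auto"` every
#' candidate crossing between adjacent solvent points (and both all-positive
#' and all-negative assignments) is tried and the assignment with the
#' smallest chi-square is kept, oriented so that the slope is negative
#' (particles denser than H2O-rich solvent scatter with positive excess at
#' low D2O). A chi-square per degree of freedom far above 1 signals
#' polydispersity or a composition change along the series.
#'
#' @param d2o_pct percent D2O per point.
#' @param rhoV per-particle excess scattering length magnitudes (cm), e.g.
#'   from [scattering_length_from_I0()]; signed values are accepted with
#'   `sign_policy = "as_given"`.
#' @param rhoV_err uncertainties (cm).
#' @param sign_policy `"auto"` or `"as_given"`.
#' @return An object of class `cv_line`: `intercept`, `slope`, `cov`, `cmp`
#'   (percent D2O), `cmp_err`, `chi2_red`, `points` (data.frame with signed
#'   values), `n`.
#' @export
fit_cv_line <- function(d2o_pct, rhoV, rhoV_err,
                        sign_policy = c("auto", "as_given")) {
  sign_policy <- match.arg(sign_policy)
  n <- length(d2o_pct)
  stopifnot(length(rhoV) == n, length(rhoV_err) == n)
  if (n < 2) stop("need at least 2 contrast points")
  if (n < 3) warning("only 2 contrast points: exact interpolation, no dof")
  ord <- order(d2o_pct)
  x <- d2o_pct[ord]; y <- rhoV[ord]; s <- rhoV_err[ord]
  s[!is.finite(s) | s <= 0] <- max(s[is.finite(s) & s > 0], 1e-30)

  fit_with <- function(ysigned) wls_fit(cbind(1, x), ysigned, s)

  if (sign_policy == "as_given") {
    best <- fit_with(y)
    ybest <- y
  } else {
    yabs <- abs(y)
    cands <- lapply(0:n, function(k) {
      sgn <- c(rep(1, k), rep(-1, n - k))
      yabs * sgn
    })
    fits <- lapply(cands, fit_with)
    chi <- vapply(fits, function(ft) ft$chi2, numeric(1))
    roots <- vapply(fits, function(ft)
      if (abs(ft$coef[2]) > 1e-300) -ft$coef[1] / ft$coef[2] else NA_real_,
      numeric(1))
    ## candidates statistically indistinguishable from the best; among
    ## those, a root inside the measured contrast span is preferred (the
    ## series is designed to bracket the match point). Distinct surviving
    ## roots are a genuine ambiguity.
    tiny <- 1e-9 * sum((yabs / s)^2)
    near <- which(chi <= min(chi) * (1 + 1e-3) + tiny)
    in_span <- near[!is.na(roots[near]) &
                      roots[near] >= min(x) & roots[near] <= max(x)]
    pool <- if (length(in_span)) in_span else near
    rr <- roots[pool][!is.na(roots[pool])]
    if (length(rr) > 1 && diff(range(rr)) > 1)
      stop("ambiguous sign assignment; candidate match points: ",
           paste(sprintf("%.2f", sort(unique(rr))), collapse = ", "))
    k <- pool[which.min(chi[pool])]
    best <- fits[[k]]; ybest <- cands[[k]]
    if (best$coef[2] > 0) {  # orient: positive excess below the match point
      ybest <- -ybest
      best <- fit_with(ybest)
    }
  }
  a <- best$coef[1]; b <- best$coef[2]
  if (abs(b) < 1e-300) stop("contrast-variation line has zero slope")
  cmp <- -a / b
  va <- best$cov[1, 1]; vb <- best$cov[2, 2]; vab <- best$cov[1, 2]
  cmp_err <- sqrt(va / b^2 + a^2 * vb / b^4 - 2 * a * vab / b^3)
  structure(list(intercept = a, slope = b, cov = best$cov,
                 cmp = cmp, cmp_err = cmp_err,
                 chi2_red = best$chi2_red,
                 points = data.frame(d2o_pct = x, rhoV = ybest, rhoV_err = s),
                 n = n),
            class = "cv_line")
}

#' @export
print.cv_line <- function(x, ...) {
  cat(sprintf("<cv_line: %d points, CMP = %.2f +/- %.2f %% D2O, chi2/dof = %.3g>\n",
              x$n, x$cmp, x$cmp_err, x$chi2_red))
  invisible(x)
}

## value and error of the fitted line at x0
cv_line_at <- function(line, x0) {
  v <- line$intercept + line$slope * x0
  X <- c(1, x0)
  err <- sqrt(drop(t(X) %*% line$cov %*% X))
  list(value = v, err = err)
}

#' Oligomeric state from the contrast-variation line
#'
#' At the non-protein match point only the protein contributes to the
#' particle's excess scattering length. That protein contribution is
#' extrapolated along the (straight) protein contrast line to 0 percent
#' D2O -- where labile-H exchange has no effect and the theoretical protein
#' scattering length is composition-only -- and divided by the theoretical
#' per-copy excess scattering length, giving the number of copies of the
#' protein set.
#'
#' @param line a fitted [fit_cv_line()] object.
#' @param protein the protein `sans_component` (one copy of the full subunit
#'   set).
#' @param cmp_nonprotein match point of the non-protein component, percent
#'   D2O.
#' @param xm exchange model (affects only the protein match point used for
#'   the extrapolation, not the 0 percent D2O reference value).
#' @return list with `n_copies`, `n_copies_err`, `cmp_protein`.
#' @export
oligomeric_state <- function(line, protein, cmp_nonprotein,
                             xm = exchange_model()) {
  stopifnot(inherits(line, "cv_line"), inherits(protein, "sans_component"))
  cmp_P <- match_point(protein, xm)$value
  rng <- range(line$points$d2o_pct)
  if (cmp_nonprotein < rng[1] - 20 || cmp_nonprotein > rng[2] + 20)
    warning("non-protein match point far outside the measured contrast span; ",
            "extrapolation is unreliable")
  at_np <- cv_line_at(line, cmp_nonprotein)
  ## protein-only line passes through (cmp_nonprotein, at_np) and (cmp_P, 0)
  scale0 <- cmp_P / (cmp_P - cmp_nonprotein)
  b_obs0 <- at_np$value * scale0
  b_obs0_err <- abs(at_np$err * scale0)
  per_copy <- component_excess_b(protein, 0, xm)$value  # exchange-free at 0%
  list(n_copies = b_obs0 / per_copy,
       n_copies_err = b_obs0_err / abs(per_copy),
       cmp_protein = cmp_P)
}

#' Subtract the theoretical protein line from the contrast-variation line
#'
#' Subtracts `n_copies` times the protein component's theoretical excess
#' scattering length from each measured point and refits, yielding the
#' contrast-variation line of the non-protein (lipid/detergent) moiety and
#' its match point. The labile-H exchange band is propagated into the match
#' point error.
#'
#' @inheritParams oligomeric_state
#' @param n_copies protein copies per particle (from [oligomeric_state()] or
#'   known).
#' @return A `cv_line` for the non-protein component with extra fields
#'   `cmp_band` (match-point range over the exchange band) and `cmp_err_total`
#'   (fit error and half band width in quadrature); NULL residual handled by
#'   error.
#' @export
subtract_protein <- function(line, protein, n_copies, xm = exchange_model()) {
  stopifnot(inherits(line, "cv_line"))
  if (n_copies < 0) stop("n_copies must be >= 0")
  pts <- line$points
  refit_at <- function(fex) {
    xm1 <- exchange_model(fex, max(xm$low * 0, 0), 1)
    bp <- component_excess_b(protein, pts$d2o_pct, xm1)$value * n_copies
    fit_cv_line(pts$d2o_pct, pts$rhoV - bp, pts$rhoV_err,
                sign_policy = "as_given")
  }
  res <- refit_at(xm$fraction)
  slope_sig <- abs(res$slope) / sqrt(res$cov[2, 2])
  int_sig <- abs(res$intercept) / sqrt(res$cov[1, 1])
  if (slope_sig < 2 && int_sig < 2)
    warning("residual line indistinguishable from zero: ",
            "no detectable non-protein component")
  band <- range(vapply(c(xm$low, xm$high),
                       function(fex) refit_at(fex)$cmp, numeric(1)))
  res$cmp_band <- band
  res$cmp_err_total <- sqrt(res$cmp_err^2 + (diff(band) / 2)^2)
  res
}

#' Lipid and detergent volumes from the non-protein contrast line
#'
#' The residual (non-protein) contrast-variation line carries two pieces of
#' information -- intercept and slope on absolute scale -- and the
#' lipid/detergent moiety has two unknown volumes. Writing the residual as
#' `V_L u_L(x) + V_D u_D(x)`, with `u` the known per-unit-volume excess
#' scattering length lines of the two components, gives a 2x2 linear system
#' whose solution is the exact volume split (this is how the experimental
#' line determines both the volume and the match point of the lipid/
#' detergent component). Negative solutions are truncated to zero with a
#' warning: the residual then is not consistent with a physical mixture of
#' the two components (wrong copy-number hypothesis, or wrong component
#' definitions).
#'
#' @param np_line residual `cv_line` from [subtract_protein()].
#' @param lipid,detergent `sans_component` objects.
#' @param xm exchange model.
#' @param clamp truncate negative volumes to zero (with warning)?
#' @param tol_volume absolute volume tolerance (cubic Angstroms) added to
#'   the 2-sigma feasibility band; lets a residual that is zero within a
#'   small fraction of the particle volume count as physical.
#' @return list with `V_lipid`, `V_detergent` (cubic Angstroms), their
#'   errors, `cov`, `cmp_nonprotein_eq` (the volume-weighted mean of the two
#'   component match points at the solved split, i.e. the match point on the
#'   mixing-rule scale) and `feasible` (both raw volumes non-negative).
#' @export
nonprotein_volumes_from_line <- function(np_line, lipid, detergent,
                                         xm = exchange_model(),
                                         clamp = TRUE, tol_volume = 0) {
  stopifnot(inherits(np_line, "cv_line"))
  u_line <- function(comp) {
    ln <- component_sld_line(comp, xm$fraction)
    ## excess per unit volume vs percent D2O: a + b * x  [cm / A^3]
    a <- (ln[["intercept"]] - .SLD_H2O) * .A_TO_CM
    b <- ((ln[["slope"]] - (.SLD_D2O - .SLD_H2O)) / 100) * .A_TO_CM
    c(a, b)
  }
  M <- cbind(u_line(lipid), u_line(detergent))
  rhs <- c(np_line$intercept, np_line$slope)
  if (abs(det(M)) < 1e-300 ||
      rcond(M / max(abs(M))) < 1e-12)
    stop("lipid and detergent contrast lines are degenerate: split undetermined")
  V <- solve(M, rhs)
  covV <- solve(M) %*% np_line$cov %*% t(solve(M))
  feasible <- all(V >= -2 * sqrt(pmax(diag(covV), 0)) - tol_volume - 1e-9)
  raw <- V
  if (any(V < 0)) {
    if (clamp) {
      warning(sprintf(
        "negative component volume (lipid %.3g, detergent %.3g A^3) truncated to 0",
        V[1], V[2]))
      V <- pmax(V, 0)
    }
  }
  cmps <- c(match_point(lipid, xm)$value, match_point(detergent, xm)$value)
  cmp_eq <- if (sum(V) > 0) sum(V * cmps) / sum(V) else NA_real_
  list(V_lipid = V[1], V_detergent = V[2],
       V_lipid_err = sqrt(max(covV[1, 1], 0)),
       V_detergent_err = sqrt(max(covV[2, 2], 0)),
       cov = covV, raw = raw,
       cmp_nonprotein_eq = cmp_eq, feasible = feasible)
}

#' Protein concentration from A280
#'
#' For the holo-translocon preset the conversion is `c = 0.5 A mg/ml`
#' (extinction coefficient 497,000 1/(M cm), 250 kDa). The general form is
#' `c = A * MW / (epsilon * path)`.
#'
#' @param A280 absorbance at 280 nm.
#' @param epsilon molar extinction coefficient, 1/(M cm); NULL selects the
#'   holo-translocon preset factor 0.5.
#' @param M_W molar mass, g/mol.
#' @param path_length cuvette path, cm.
#' @return concentration in mg/ml.
#' @export
concentration_from_absorbance <- function(A280, epsilon = NULL,
                                          M_W = NULL, path_length = 1) {
  stopifnot(all(A280 >= 0))
  if (is.null(epsilon)) return(0.5 * A280)
  stopifnot(epsilon > 0, M_W > 0, path_length > 0)
  A280 * M_W / (epsilon * path_length)
}
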