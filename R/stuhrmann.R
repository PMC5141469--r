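#' Mean particle contrast
#'
#' Volume-weighted mean scattering-length density of the particle minus the
#' solvent SLD, with a low/high band from the labile-H exchange model.
#'
#' @param components list of `sans_component`.
#' @param fractions volume fractions (renormalised).
#' @param d2o_pct solvent percent D2O (vectorised).
#' @param xm exchange model.
#' @return list with `value`, `low`, `high` in inverse square Angstroms.
#' @export
mean_contrast <- function(components, fractions, d2o_pct,
                          xm = exchange_model()) {
  stopifnot(length(components) == length(fractions))
  fractions <- fractions / sum(fractions)
  f <- pct_to_frac(d2o_pct)
  at <- function(fex) {
    sld <- 0
    for (i in seq_along(components)) {
      ln <- component_sld_line(components[[i]], fex)
      sld <- sld + fractions[i] * (ln[["intercept"]] + f * ln[["slope"]])
    }
    sld - solvent_sld(f)
  }
  v <- at(xm$fraction); a <- at(xm$low); b <- at(xm$high)
  list(value = v, low = pmin(a, b), high = pmax(a, b))
}

#' Protein share of total contrast-weighted scattering
#'
#' `X = drho_P V_P / (drho_P V_P + drho_L V_L)`. At the non-protein match
#' point X = 1 (only protein scatters); at the protein match point X = 0.
#' Undefined at the particle match point, where the total contrast
#' vanishes.
#'
#' @param protein,nonprotein `sans_component` objects.
#' @param V_P,V_L their volumes in the particle, cubic Angstroms.
#' @param d2o_pct solvent percent D2O (vectorised).
#' @param xm exchange model.
#' @return list with `value`, `low`, `high` (exchange band).
#' @export
contrast_fraction_X <- function(protein, nonprotein, V_P, V_L, d2o_pct,
                                xm = exchange_model()) {
  stopifnot(V_P > 0, V_L >= 0)
  f <- pct_to_frac(d2o_pct)
  at <- function(fex) {
    lp <- component_sld_line(protein, fex)
    ll <- component_sld_line(nonprotein, fex)
    bp <- (lp[["intercept"]] + f * lp[["slope"]] - solvent_sld(f)) * V_P
    bl <- (ll[["intercept"]] + f * ll[["slope"]] - solvent_sld(f)) * V_L
    tot <- bp + bl
    if (any(abs(tot) < 1e-12 * (abs(bp) + abs(bl))))
      stop("total contrast is zero (particle match point): X undefined")
    bp / tot
  }
  v <- at(xm$fraction); a <- at(xm$low); b <- at(xm$high)
  list(value = v, low = pmin(a, b), high = pmax(a, b))
}

## shared effective-variance weighted polynomial fit of y on columns X with
## x-errors entering through the current slope estimate; 3 refinement passes
effvar_fit <- function(X, y, sy, dx_dcoef = NULL, sx = NULL) {
  sig <- sy
  fit <- wls_fit(X, y, pmax(sig, 1e-300))
  if (!is.null(sx)) {
    for (k in 1:3) {
      dy_dx <- drop(dx_dcoef(fit$coef))
      sig <- sqrt(sy^2 + (dy_dx * sx)^2)
      fit <- wls_fit(X, y, pmax(sig, 1e-300))
    }
  }
  fit
}

#' Stuhrmann analysis
#'
#' Weighted fit of `Rg^2 = Rc^2 + alpha / drho - beta / drho^2`: the radius
#' of gyration at infinite contrast, the radial scattering-density
#' coefficient alpha (positive when the higher-SLD material is peripheral)
#' and the centre-separation coefficient beta. Points with |drho| below
#' `exclude_frac` of the series maximum are dropped (their Rg errors
#' explode near the particle match point). x-errors (the exchange band on
#' drho) are handled by effective-variance weighting.
#'
#' @param d2o_pct solvent percent D2O per point (bookkeeping only).
#' @param Rg,Rg_err Guinier radii and errors, Angstroms.
#' @param drho mean particle contrast per point, inverse square Angstroms.
#' @param drho_err error on drho (e.g. half the exchange band).
#' @param model `"auto"` (F-test at `alpha_level`), `"linear"` or
#'   `"parabolic"`.
#' @param exclude_frac low-contrast exclusion threshold as a fraction of
#'   max |drho|.
#' @param alpha_level significance level of the nested F-test.
#' @return An object of class `stuhrmann_result`: `Rc2`, `Rc2_err`, `alpha`,
#'   `alpha_err`, `beta`, `beta_err`, `model`, `chi2_red`, `n_used`,
#'   `excluded`, plus `fits` with both candidate fits.
#' @export
stuhrmann_fit <- function(d2o_pct, Rg, Rg_err, drho, drho_err = 0,
                          model = c("auto", "linear", "parabolic"),
                          exclude_frac = 0.10, alpha_level = 0.05) {
  model <- match.arg(model)
  n <- length(Rg)
  stopifnot(length(d2o_pct) == n, length(Rg_err) == n, length(drho) == n)
  drho_err <- rep(drho_err, length.out = n)
  keep <- is.finite(Rg) & is.finite(drho) &
    abs(drho) >= exclude_frac * max(abs(drho))
  if (sum(keep) < 3) stop("fewer than 3 usable contrast points")
  x_raw <- 1 / drho[keep]
  ## scale 1/drho (of order 1e6 A^2) to keep the normal equations
  ## well-conditioned; coefficients and covariance are rescaled afterwards
  xs <- max(abs(x_raw))
  x <- x_raw / xs
  sx <- drho_err[keep] / drho[keep]^2 / xs
  y <- Rg[keep]^2
  sy <- 2 * Rg[keep] * Rg_err[keep]
  sy[sy <= 0] <- max(sy[sy > 0], 1e-6)

  unscale <- function(ft, powers) {
    sc <- xs^powers
    ft$coef <- ft$coef / sc
    ft$cov <- ft$cov / outer(sc, sc)
    ft
  }
  lin <- unscale(effvar_fit(cbind(1, x), y, sy,
                            dx_dcoef = function(b) b[2], sx = sx),
                 c(0, 1))
  par_ok <- sum(keep) >= 4
  par <- if (par_ok)
    unscale(effvar_fit(cbind(1, x, x^2), y, sy,
                       dx_dcoef = function(b) b[2] + 2 * b[3] * x, sx = sx),
            c(0, 1, 2))
  use <- switch(model,
    linear = "linear",
    parabolic = if (par_ok) "parabolic" else stop("parabolic fit needs >= 4 points"),
    auto = {
      if (par_ok && par$dof > 0 && par$chi2 < lin$chi2) {
        Fstat <- (lin$chi2 - par$chi2) / (par$chi2 / par$dof)
        pF <- stats::pf(Fstat, 1, par$dof, lower.tail = FALSE)
        if (is.finite(pF) && pF < alpha_level) "parabolic" else "linear"
      } else "linear"
    })
  ft <- if (use == "parabolic") par else lin
  beta <- if (use == "parabolic") -ft$coef[3] else 0
  beta_err <- if (use == "parabolic") sqrt(ft$cov[3, 3]) else 0
  structure(list(Rc2 = ft$coef[1], Rc2_err = sqrt(ft$cov[1, 1]),
                 alpha = ft$coef[2], alpha_err = sqrt(ft$cov[2, 2]),
                 beta = beta, beta_err = beta_err,
                 model = use, chi2_red = ft$chi2_red, n_used = sum(keep),
                 excluded = which(!keep),
                 fits = list(linear = lin,
                             parabolic = if (par_ok) par else NULL)),
            class = "stuhrmann_result")
}

#' @export
print.stuhrmann_result <- function(x, ...) {
  cat(sprintf(
    "<stuhrmann (%s): Rc = %.1f A, alpha = %.3g +/- %.2g, beta = %.3g; %d pts>\n",
    x$model, sqrt(max(x$Rc2, 0)), x$alpha, x$alpha_err, x$beta, x$n_used))
  invisible(x)
}

#' Parallel-axis decomposition of the radius of gyration
#'
#' Fits `Rg^2 = X Rg_P^2 + (1 - X) Rg_L^2 + X (1 - X) D^2` where X is the
#' protein contrast share from [contrast_fraction_X()]. The intercepts at
#' X = 1 and X = 0 give the protein and non-protein radii of gyration; D is
#' the separation of their centres of mass (fixed at 0 in the linear
#' model). Negative fitted squares are reported and flagged, never clipped
#' silently.
#'
#' @param X protein contrast fraction per point.
#' @param Rg,Rg_err Guinier radii and errors, Angstroms.
#' @param X_err optional error on X (exchange band), used by
#'   effective-variance weighting.
#' @param model `"linear"` (D = 0) or `"quadratic"`.
#' @return An object of class `parallel_axis_result`: `Rg_P`, `Rg_P_err`,
#'   `Rg_L`, `Rg_L_err`, `D`, `D_err`, `Rg_P2`/`Rg_L2`/`D2` raw squares,
#'   `model`, `chi2_red`, `flags`.
#' @export
parallel_axis_fit <- function(X, Rg, Rg_err, X_err = 0,
                              model = c("linear", "quadratic")) {
  model <- match.arg(model)
  n <- length(X)
  stopifnot(length(Rg) == n, length(Rg_err) == n)
  X_err <- rep(X_err, length.out = n)
  keep <- is.finite(X) & is.finite(Rg)
  x <- X[keep]; y <- Rg[keep]^2
  sy <- 2 * Rg[keep] * Rg_err[keep]
  sy[sy <= 0] <- max(sy[sy > 0], 1e-6)
  sx <- X_err[keep]
  flags <- character(0)
  if (diff(range(x)) < 0.3)
    flags <- c(flags, "narrow_X_range_extrapolation")
  np <- if (model == "quadratic") 3 else 2
  if (sum(keep) < np + 1) stop("too few points for the ", model, " model")
  if (model == "linear") {
    ft <- effvar_fit(cbind(1, x), y, sy,
                     dx_dcoef = function(b) b[2], sx = sx)
    RL2 <- ft$coef[1]; RP2 <- ft$coef[1] + ft$coef[2]
    vL <- ft$cov[1, 1]
    vP <- ft$cov[1, 1] + ft$cov[2, 2] + 2 * ft$cov[1, 2]
    D2 <- 0; vD <- 0
  } else {
    ft <- effvar_fit(cbind(1, x, x * (1 - x)), y, sy,
                     dx_dcoef = function(b) b[2] + b[3] * (1 - 2 * x), sx = sx)
    RL2 <- ft$coef[1]; RP2 <- ft$coef[1] + ft$coef[2]
    D2 <- ft$coef[3]
    vL <- ft$cov[1, 1]
    vP <- ft$cov[1, 1] + ft$cov[2, 2] + 2 * ft$cov[1, 2]
    vD <- ft$cov[3, 3]
  }
  sq <- function(v2, var2, lab) {
    if (v2 < 0) {
      flags <<- c(flags, paste0("imaginary_", lab))
      c(NA_real_, NA_real_)
    } else {
      r <- sqrt(v2)
      c(r, if (r > 0) sqrt(var2) / (2 * r) else NA_real_)
    }
  }
  p <- sq(RP2, vP, "Rg_P"); l <- sq(RL2, vL, "Rg_L"); d <- sq(D2, vD, "D")
  structure(list(Rg_P = p[1], Rg_P_err = p[2], Rg_L = l[1], Rg_L_err = l[2],
                 D = d[1], D_err = d[2],
                 Rg_P2 = RP2, Rg_L2 = RL2, D2 = D2,
                 model = model, chi2_red = ft$chi2_red, flags = flags),
            class = "parallel_axis_result")
}

#' @export
print.parallel_axis_result <- function(x, ...) {
  cat(sprintf(
    "<parallel-axis (%s): Rg_P = %.1f +/- %.2g A, Rg_L = %.1f +/- %.2g A, D = %.2g A>\n",
    x$model, x$Rg_P, x$Rg_P_err, x$Rg_L, x$Rg_L_err, x$D))
  invisible(x)
}
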