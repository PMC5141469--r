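#' Guinier fit of a scattering curve
#'
#' Weighted straight-line fit of ln I versus q^2 over the low-q region,
#' giving the forward intensity I(0) and radius of gyration Rg. With
#' `window_policy = "qrg"` the upper window edge is chosen self-consistently
#' so that `q_max * Rg <= qrg_limit`; with `"fixed"` the window is the q
#' range given in `q_window`. Points with non-positive intensity are
#' excluded, never truncated. Weights are 1/sigma^2 on ln I with
#' sigma_lnI = sigma_I / I; parameter errors come from the unscaled weighted
#' covariance so they propagate the measurement uncertainties directly.
#'
#' @param curve a [scattering_curve()].
#' @param qrg_limit validity limit for q*Rg at the window's upper edge
#'   (default 1.3; globular shapes often stay linear further, so larger
#'   values are allowed).
#' @param window_policy `"qrg"` (self-consistent) or `"fixed"`.
#' @param q_window numeric length-2, used when `window_policy = "fixed"` and
#'   as the initial/outer limits otherwise.
#' @param min_points minimum usable points in the window.
#' @param runs_z_limit threshold on the Wald-Wolfowitz runs statistic of the
#'   fit residuals: the window's upper edge is trimmed while the residuals
#'   show a systematic trend stronger than this (set `Inf` to disable).
#' @return An object of class `guinier_result`: list with `I0`, `I0_err`,
#'   `Rg`, `Rg_err`, `q_window`, `qRg_max`, `n_points`, `chi2_red`,
#'   `runs_z` (residual-trend statistic), `valid` and `flags`.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3,
                        window_policy = c("qrg", "fixed"),
                        q_window = NULL, min_points = 5,
                        runs_z_limit = 2.5) {
  window_policy <- match.arg(window_policy)
  stopifnot(inherits(curve, "scattering_curve"))
  usable <- curve$I > 0 & curve$sigma_I > 0
  if (!is.null(q_window))
    usable <- usable & curve$q >= q_window[1] & curve$q <= q_window[2]
  if (sum(usable) < min_points)
    stop(sprintf("Guinier fit needs >= %d usable points with I > 0 (have %d)",
                 min_points, sum(usable)))
  q <- curve$q[usable]; I <- curve$I[usable]; s <- curve$sigma_I[usable]

  do_fit <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx]); sy <- s[idx] / I[idx]
    ft <- wls_fit(cbind(1, x), y, sy)
    ## reweight against the model intensity: weights built from the noisy
    ## measured I correlate with the residuals and bias the intercept
    for (k in 1:2) {
      I_model <- exp(ft$coef[1] + ft$coef[2] * x)
      ft <- wls_fit(cbind(1, x), y, s[idx] / I_model)
    }
    ft
  }
  result_from <- function(fit, idx) {
    slope <- fit$coef[2]; intercept <- fit$coef[1]
    I0 <- exp(intercept)
    I0_err <- I0 * sqrt(fit$cov[1, 1])
    flags <- character(0)
    if (slope < 0) {
      Rg <- sqrt(-3 * slope)
      Rg_err <- 3 / (2 * Rg) * sqrt(fit$cov[2, 2])
    } else {
      Rg <- NA_real_; Rg_err <- NA_real_
      flags <- c(flags, "positive_slope")
    }
    qmax <- max(q[idx])
    qRg_max <- if (is.na(Rg)) NA_real_ else qmax * Rg
    if (!is.na(qRg_max) && qRg_max > qrg_limit * 1.05)
      flags <- c(flags, "qRg_exceeds_limit")
    structure(list(I0 = I0, I0_err = I0_err, Rg = Rg, Rg_err = Rg_err,
                   q_window = c(min(q[idx]), qmax), qRg_max = qRg_max,
                   n_points = sum(idx), chi2_red = fit$chi2_red,
                   runs_z = runs_test_z(fit$residuals),
                   valid = slope < 0 && !("qRg_exceeds_limit" %in% flags),
                   flags = flags),
              class = "guinier_result")
  }

  if (window_policy == "fixed") {
    idx <- rep(TRUE, length(q))
    return(result_from(do_fit(idx), idx))
  }

  ## self-consistent q*Rg window: start from the strongly-scattering region
  ## (top decade of intensity, where decay guarantees a negative slope) and
  ## shrink the upper edge until q_max * Rg <= qrg_limit is stable
  drop1 <- which(I < max(I) / 10)
  idx <- if (length(drop1)) seq_along(q) < min(drop1) else rep(TRUE, length(q))
  if (sum(idx) < min_points) idx <- seq_along(q) <= min_points
  seen_qmax <- numeric(0)
  for (iter in 1:50) {
    fit <- do_fit(idx)
    slope <- fit$coef[2]
    if (slope >= 0) break  # flat/rising curve: flag on the current window
    Rg <- sqrt(-3 * slope)
    qmax <- qrg_limit / Rg
    new_idx <- q <= qmax
    if (sum(new_idx) < min_points)
      new_idx <- seq_along(q) <= min_points
    if (identical(new_idx, idx)) break
    if (any(abs(qmax - seen_qmax) < 1e-12)) { idx <- new_idx; break }
    seen_qmax <- c(seen_qmax, qmax)
    idx <- new_idx
  }
  ## trim the upper edge while the residuals show a systematic run (the
  ## onset of form-factor curvature inside the nominal q*Rg window)
  if (is.finite(runs_z_limit)) {
    repeat {
      fit <- do_fit(idx)
      z <- runs_test_z(fit$residuals)
      if (is.na(z) || abs(z) <= runs_z_limit || sum(idx) <= min_points) break
      idx[max(which(idx))] <- FALSE
    }
  }
  result_from(do_fit(idx), idx)
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "<guinier: I0 = %.4g +/- %.2g 1/cm, Rg = %.4g +/- %.2g A, qRg<=%.3g, %d pts%s>\n",
    x$I0, x$I0_err, x$Rg, x$Rg_err, x$qRg_max, x$n_points,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Guinier analysis of a contrast series
#'
#' Applies [guinier_fit()] to every curve of a contrast-variation series.
#' Curves whose solvent lies close to a supplied component match point are
#' flagged `near_match_point` (their contrast, and hence I(0), is near zero
#' and errors blow up); curves whose fitted I(0) is not significant are
#' flagged `low_contrast`.
#'
#' @param curves list of [scattering_curve()]; each must carry `d2o_pct`
#'   metadata unless `d2o_pct` is given.
#' @param d2o_pct optional numeric vector of solvent percent D2O per curve.
#' @param match_points optional numeric vector of component match points
#'   (percent D2O) used for the proximity flag.
#' @param flag_window half-width (percent D2O) of the proximity flag.
#' @param ... passed to [guinier_fit()].
#' @return data.frame with one row per curve: `d2o_pct`, `I0`, `I0_err`,
#'   `Rg`, `Rg_err`, `qRg_max`, `chi2_red`, `flags`.
#' @export
contrast_series_guinier <- function(curves, d2o_pct = NULL,
                                    match_points = NULL, flag_window = 3,
                                    ...) {
  if (is.null(d2o_pct)) {
    d2o_pct <- vapply(curves, function(cv) {
      v <- cv$metadata$d2o_pct
      if (is.null(v)) stop("curve lacks d2o_pct metadata")
      as.numeric(v)
    }, numeric(1))
  }
  stopifnot(length(d2o_pct) == length(curves))
  rows <- lapply(seq_along(curves), function(i) {
    g <- guinier_fit(curves[[i]], ...)
    flags <- g$flags
    if (!is.null(match_points) &&
        any(abs(d2o_pct[i] - match_points) <= flag_window))
      flags <- c(flags, "near_match_point")
    if (g$I0 < 5 * g$I0_err) flags <- c(flags, "low_contrast")
    data.frame(d2o_pct = d2o_pct[i], I0 = g$I0, I0_err = g$I0_err,
               Rg = g$Rg, Rg_err = g$Rg_err, qRg_max = g$qRg_max,
               chi2_red = g$chi2_red,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
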