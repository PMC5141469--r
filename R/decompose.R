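## accept a component, a number (match point in % D2O) or list(cmp=, err=)
cmp_of <- function(x, xm) {
  if (inherits(x, "sans_component")) {
    mp <- match_point(x, xm)
    list(cmp = mp$value, err = (mp$high - mp$low) / 2)
  } else if (is.list(x)) {
    list(cmp = x$cmp, err = if (is.null(x$err)) 0 else x$err)
  } else {
    list(cmp = as.numeric(x), err = 0)
  }
}

#' Protein / lipid / detergent volume fractions from match points
#'
#' Inverts volume-weighted match-point mixing twice: the complex match point
#' against the protein and non-protein match points gives the protein volume
#' fraction; the non-protein match point against the lipid and detergent
#' match points splits the remainder. The particle volume follows from the
#' protein volume (sequence-derived, times copy number) divided by the
#' protein fraction. Uncertainties are propagated numerically (first order)
#' from the supplied match-point errors, which include the labile-H exchange
#' bands when components are given.
#'
#' @param cmp_total match point of the whole particle, percent D2O.
#' @param cmp_nonprotein match point of the non-protein moiety, percent D2O.
#' @param protein the protein `sans_component`, or its match point (number),
#'   or `list(cmp=, err=)`; when not a component, `V_P` must be given.
#' @param n_copies protein copies per particle.
#' @param lipid,detergent lipid and detergent components (or match points).
#' @param cmp_total_err,cmp_nonprotein_err,n_copies_err uncertainties.
#' @param V_P protein volume per copy, cubic Angstroms (derived from the
#'   component when omitted).
#' @param xm exchange model for component match points.
#' @return An object of class `sans_decomposition`: volume fractions `v_P`,
#'   `v_L`, `v_D` with errors, volumes `V_total`, `V_P`, `V_lipid`,
#'   `V_detergent`, `V_nonprotein` (cubic Angstroms) with errors, the match
#'   points used, and `n_copies`.
#' @export
solve_volume_fractions <- function(cmp_total, cmp_nonprotein, protein,
                                   n_copies = 1, lipid = 13.1,
                                   detergent = 21.7,
                                   cmp_total_err = 0, cmp_nonprotein_err = 0,
                                   n_copies_err = 0, V_P = NULL,
                                   xm = exchange_model()) {
  p <- cmp_of(protein, xm); l <- cmp_of(lipid, xm); d <- cmp_of(detergent, xm)
  if (is.null(V_P)) {
    if (!inherits(protein, "sans_component"))
      stop("V_P must be given when protein is not a component")
    V_P <- protein$dry_volume
  }
  if (abs(p$cmp - cmp_nonprotein) < 1e-9 || abs(l$cmp - d$cmp) < 1e-9)
    stop("degenerate match-point pair: fractions are undetermined")

  calc <- function(th) {
    ## th = c(cmp_total, cmp_np, cmp_P, cmp_L, cmp_D, n_copies)
    vP <- (th[1] - th[2]) / (th[3] - th[2])
    vP <- min(max(vP, 1e-9), 1)
    gL <- (th[2] - th[5]) / (th[4] - th[5])
    gL <- min(max(gL, 0), 1)
    vL <- (1 - vP) * gL
    vD <- 1 - vP - vL
    Vp <- V_P * th[6]
    Vt <- Vp / vP
    c(v_P = vP, v_L = vL, v_D = vD, V_total = Vt,
      V_lipid = vL * Vt, V_detergent = vD * Vt,
      V_nonprotein = (1 - vP) * Vt)
  }
  th0 <- c(cmp_total, cmp_nonprotein, p$cmp, l$cmp, d$cmp, n_copies)
  sig <- c(cmp_total_err, cmp_nonprotein_err, p$err, l$err, d$err, n_copies_err)
  v0 <- calc(th0)
  ## numeric first-order propagation
  var <- numeric(length(v0))
  for (i in seq_along(th0)) {
    if (sig[i] <= 0) next
    h <- max(abs(th0[i]) * 1e-6, 1e-8)
    thp <- th0; thp[i] <- thp[i] + h
    thm <- th0; thm[i] <- thm[i] - h
    grad <- (calc(thp) - calc(thm)) / (2 * h)
    var <- var + (grad * sig[i])^2
  }
  err <- sqrt(var)
  raw_vP <- (cmp_total - cmp_nonprotein) / (p$cmp - cmp_nonprotein)
  if (raw_vP < 0 || raw_vP > 1)
    warning(sprintf("protein fraction %.3f outside [0, 1]; clamped", raw_vP))
  structure(list(
    v_P = v0[["v_P"]], v_P_err = err[[1]],
    v_L = v0[["v_L"]], v_L_err = err[[2]],
    v_D = v0[["v_D"]], v_D_err = err[[3]],
    V_total = v0[["V_total"]], V_total_err = err[[4]],
    V_P = V_P * n_copies,
    V_lipid = v0[["V_lipid"]], V_lipid_err = err[[5]],
    V_detergent = v0[["V_detergent"]], V_detergent_err = err[[6]],
    V_nonprotein = v0[["V_nonprotein"]], V_nonprotein_err = err[[7]],
    cmp_total = cmp_total, cmp_nonprotein = cmp_nonprotein,
    cmp_protein = p$cmp, cmp_lipid = l$cmp, cmp_detergent = d$cmp,
    n_copies = n_copies),
    class = "sans_decomposition")
}

#' @export
print.sans_decomposition <- function(x, ...) {
  cat(sprintf(
    paste0("<decomposition: protein %.1f +/- %.1f%%, lipid %.1f +/- %.1f%%, ",
           "detergent %.1f +/- %.1f%% v/v; V_total = %.3g A^3>\n"),
    100 * x$v_P, 100 * x$v_P_err, 100 * x$v_L, 100 * x$v_L_err,
    100 * x$v_D, 100 * x$v_D_err, x$V_total))
  invisible(x)
}

#' Lipid copies per particle
#'
#' Divides the lipid volume of a decomposition by the molecular volume of
#' one lipid; the returned range spans the propagated error on the lipid
#' volume and, if given, a low/high molecular-volume range.
#'
#' @param decomp a `sans_decomposition` (or a number: lipid volume in cubic
#'   Angstroms).
#' @param lipid_mol_volume molecular volume of one lipid, cubic Angstroms;
#'   default is the volume of the built-in E. coli inner-membrane lipid
#'   average formula unit.
#' @param volume_range optional length-2 low/high molecular volume.
#' @param V_lipid_err error on the lipid volume (taken from `decomp` when it
#'   is a decomposition).
#' @return list with `count`, `low`, `high`.
#' @export
lipid_count <- function(decomp, lipid_mol_volume = NULL, volume_range = NULL,
                        V_lipid_err = 0) {
  if (inherits(decomp, "sans_decomposition")) {
    V_L <- decomp$V_lipid
    V_lipid_err <- decomp$V_lipid_err
  } else {
    V_L <- as.numeric(decomp)
  }
  if (is.null(lipid_mol_volume))
    lipid_mol_volume <- preset_component("ecoli_inner_membrane_lipid")$dry_volume
  if (lipid_mol_volume <= 0) stop("lipid_mol_volume must be > 0")
  if (is.null(volume_range)) volume_range <- rep(lipid_mol_volume, 2)
  stopifnot(length(volume_range) == 2, all(volume_range > 0))
  list(count = V_L / lipid_mol_volume,
       low = max(0, (V_L - V_lipid_err) / max(volume_range)),
       high = (V_L + V_lipid_err) / min(volume_range))
}
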