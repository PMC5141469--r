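#' Average component of a mixture
#'
#' Collapses several components into a single pseudo formula unit whose
#' composition, labile-H count, volume and mass are mole-fraction weighted
#' means. Such a composite behaves exactly like the mixture in every SLD and
#' match-point formula.
#'
#' @param components list of `sans_component`.
#' @param weight_fractions mass fractions (used to derive mole fractions);
#'   give either this or `mole_fractions`.
#' @param mole_fractions mole fractions.
#' @param name,role passed to [component()].
#' @return A `sans_component`.
#' @export
mixture_component <- function(components, weight_fractions = NULL,
                              mole_fractions = NULL, name = "mixture",
                              role = "other") {
  stopifnot(length(components) >= 1)
  if (is.null(mole_fractions)) {
    if (is.null(weight_fractions))
      stop("give weight_fractions or mole_fractions")
    mm <- vapply(components, function(x) x$molar_mass, numeric(1))
    mole_fractions <- weight_fractions / mm
  }
  mole_fractions <- mole_fractions / sum(mole_fractions)
  counts <- numeric(0)
  n_ex <- 0
  vol <- 0
  for (i in seq_along(components)) {
    cc <- components[[i]]$composition
    for (el in names(cc$counts))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
        mole_fractions[i] * cc$counts[[el]]
    n_ex <- n_ex + mole_fractions[i] * cc$n_exchangeable_H
    vol <- vol + mole_fractions[i] * components[[i]]$dry_volume
  }
  component(name, atomic_composition(counts, n_ex), dry_volume = vol,
            role = role)
}

#' Built-in component presets
#'
#' * `"ddm"` — n-dodecyl-beta-D-maltoside, C24H46O11, 7 hydroxyl (labile)
#'   hydrogens, partial specific volume 0.82 ml/g.
#' * `"popc_like_pe"` / `"pope"` — 16:0/18:1 phosphatidylethanolamine,
#'   C39H76NO8P, 3 labile H (ammonium headgroup).
#' * `"popg"` — 16:0/18:1 phosphatidylglycerol, C40H77O10P, 2 labile H
#'   (glycerol hydroxyls).
#' * `"cardiolipin"` — tetraoleoyl cardiolipin, C81H142O17P2, 1 labile H.
#' * `"ecoli_inner_membrane_lipid"` — PE:PG:cardiolipin 75:20:5 by weight,
#'   collapsed to one average formula unit; this is the default lipid model
#'   for inner-membrane protein preparations.
#' * `"htl_protein"` — a 250 kDa membrane-protein component built from the
#'   average amino-acid residue composition at partial specific volume
#'   0.73 ml/g, standing in for the SecYEG-SecDF-YajC-YidC holo-translocon
#'   protein moiety (sequence-accurate compositions can be supplied with
#'   [protein_component()] instead).
#'
#' @param name preset name.
#' @return A `sans_component`.
#' @export
preset_component <- function(name) {
  switch(tolower(name),
    ddm = component("DDM", "C24H46O11", n_exchangeable_H = 7,
                    specific_volume = 0.82, role = "detergent"),
    pope = component("POPE", "C39H76NO8P", n_exchangeable_H = 3,
                     specific_volume = 0.99, role = "lipid"),
    popg = component("POPG", "C40H77O10P", n_exchangeable_H = 2,
                     specific_volume = 0.98, role = "lipid"),
    cardiolipin = component("cardiolipin", "C81H142O17P2",
                            n_exchangeable_H = 1,
                            specific_volume = 0.99, role = "lipid"),
    ecoli_inner_membrane_lipid = {
      m <- mixture_component(
        list(preset_component("pope"), preset_component("popg"),
             preset_component("cardiolipin")),
        weight_fractions = c(0.75, 0.20, 0.05),
        name = "E. coli inner-membrane lipid", role = "lipid")
      m
    },
    htl_protein = {
      ## average residue (Cohn-Edsall style composition), ~111.1 g/mol;
      ## 1.35 labile H per residue (backbone amide + average side chain)
      res <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
      m_res <- sum(res * .atomic_mass[names(res)])
      n_res <- 250000 / m_res
      component("HTL protein (250 kDa average-residue model)",
                atomic_composition(res * n_res, 1.35 * n_res),
                specific_volume = 0.73, role = "protein")
    },
    stop("unknown preset: ", name)
  )
}
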