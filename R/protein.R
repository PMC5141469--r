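## Per-residue data for the 20 standard amino acids.
## Formulas are for the free amino acid; one water is removed per peptide
## bond when summing a chain. Labile side-chain hydrogens counted for the
## dominant protonation state near neutral pH (Lys as NH3+, Arg guanidinium,
## Asp/Glu carboxyl counted as 1). Residue volumes in A^3 from Zamyatnin
## (Prog. Biophys. Mol. Biol. 24, 107 (1972)).
.aa_table <- local({
  tab <- rbind(
    ##        C   H   N  O  S  side_labile_H  volume
    A = c(3,  7, 1, 2, 0, 0,  88.6),
    R = c(6, 14, 4, 2, 0, 5, 173.4),
    N = c(4,  8, 2, 3, 0, 2, 114.1),
    D = c(4,  7, 1, 4, 0, 1, 111.1),
    C = c(3,  7, 1, 2, 1, 1, 108.5),
    E = c(5,  9, 1, 4, 0, 1, 138.4),
    Q = c(5, 10, 2, 3, 0, 2, 143.8),
    G = c(2,  5, 1, 2, 0, 0,  60.1),
    H = c(6,  9, 3, 2, 0, 1, 153.2),
    I = c(6, 13, 1, 2, 0, 0, 166.7),
    L = c(6, 13, 1, 2, 0, 0, 166.7),
    K = c(6, 14, 2, 2, 0, 3, 168.6),
    M = c(5, 11, 1, 2, 1, 0, 162.9),
    F = c(9, 11, 1, 2, 0, 0, 189.9),
    P = c(5,  9, 1, 2, 0, 0, 112.7),
    S = c(3,  7, 1, 3, 0, 1,  89.0),
    T = c(4,  9, 1, 3, 0, 1, 116.1),
    W = c(11, 12, 2, 2, 0, 1, 227.8),
    Y = c(9, 11, 1, 3, 0, 1, 193.6),
    V = c(5, 11, 1, 2, 0, 0, 140.0))
  colnames(tab) <- c("C", "H", "N", "O", "S", "side_labile_H", "volume")
  tab
})

#' Atomic composition of a protein from its sequence(s)
#'
#' Sums free amino-acid formulas and removes one water per peptide bond.
#' Labile hydrogens are the backbone amide hydrogens (one per peptide bond,
#' none for proline), the side-chain labile hydrogens, plus the terminal
#' NH3+ and COOH protons of each chain.
#'
#' @param sequences character vector of one-letter amino-acid sequences, one
#'   per polypeptide chain.
#' @return An `atomic_composition`.
#' @export
protein_composition_from_sequence <- function(sequences) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  n_ex <- 0
  for (s in sequences) {
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, rownames(.aa_table))
    if (length(bad))
      stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
    n <- length(aa)
    sub <- .aa_table[aa, , drop = FALSE]
    counts <- counts + colSums(sub[, c("C", "H", "N", "O", "S"), drop = FALSE])
    ## remove one H2O per peptide bond
    counts[["H"]] <- counts[["H"]] - 2 * (n - 1)
    counts[["O"]] <- counts[["O"]] - (n - 1)
    ## backbone amides: one per bond except when the C-side residue is Pro
    amide_H <- if (n > 1) sum(aa[-1] != "P") else 0
    ## termini: alpha-NH3+ (3 H, minus the 1 amide already absent at the
    ## N-terminus) and COOH (1 H)
    n_ex <- n_ex + sum(sub[, "side_labile_H"]) + amide_H + 3 + 1
  }
  if (any(counts < 0)) stop("invalid sequence: negative element count")
  atomic_composition(counts[counts > 0], min(n_ex, counts[["H"]]))
}

#' Protein component from sequence(s)
#'
#' Builds a `sans_component` for a (multi-chain) protein. The dry volume is
#' the sum of residue volumes from a standard table; pass `specific_volume`
#' to override (0.73 ml/g is the usual globular-protein fallback).
#'
#' @inheritParams protein_composition_from_sequence
#' @param name label.
#' @param specific_volume optional partial specific volume, ml/g.
#' @return A `sans_component` with role `"protein"`.
#' @export
protein_component <- function(sequences, name = "protein",
                              specific_volume = NULL) {
  comp <- protein_composition_from_sequence(sequences)
  if (is.null(specific_volume)) {
    vol <- 0
    for (s in sequences) {
      aa <- strsplit(toupper(s), "")[[1]]
      vol <- vol + sum(.aa_table[aa, "volume"])
    }
    component(name, comp, dry_volume = vol, role = "protein")
  } else {
    component(name, comp, specific_volume = specific_volume, role = "protein")
  }
}

#' Protein partial specific volume from sequence
#'
#' Residue-volume sum divided by molar mass, in ml/g.
#' @inheritParams protein_composition_from_sequence
#' @return Partial specific volume in ml/g.
#' @export
protein_specific_volume <- function(sequences) {
  p <- protein_component(sequences)
  p$dry_volume / p$molar_mass * .N_AVOGADRO * 1e-24
}
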