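#' @keywords internal
"_PACKAGE"

## Coherent neutron scattering lengths, fm (Sears, Neutron News 3, 26 (1992)).
## Only elements that occur in proteins, lipids, detergents and common buffers.
.neutron_b <- c(
  H  = -3.7406,
  D  =  6.671,
  C  =  6.6511,
  N  =  9.36,
  O  =  5.803,
  P  =  5.13,
  S  =  2.847,
  Na =  3.63,
  Cl =  9.577,
  K  =  3.67,
  Mg =  5.375,
  Ca =  4.70,
  Fe =  9.45,
  Zn =  5.68,
  Se =  7.97
)

## Atomic masses, g/mol (IUPAC 2021 conventional values).
.atomic_mass <- c(
  H  = 1.008,
  D  = 2.014,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  P  = 30.974,
  S  = 32.06,
  Na = 22.990,
  Cl = 35.45,
  K  = 39.098,
  Mg = 24.305,
  Ca = 40.078,
  Fe = 55.845,
  Zn = 65.38,
  Se = 78.971
)

## Solvent scattering-length densities at the endpoints of the H2O/D2O series,
## in 1/A^2 (Jacrot, Rep. Prog. Phys. 39, 911 (1976) tabulation).
.SLD_H2O <- -0.561e-6
.SLD_D2O <- 6.37e-6

.N_AVOGADRO <- 6.02214076e23

## 1 fm = 1e-5 A = 1e-13 cm; SLD [1/A^2] = b[fm] * 1e-5 / V[A^3]
.FM_PER_A <- 1e-5
.CM_PER_FM <- 1e-13
## rhoV [cm] = SLD [1/A^2] * V [A^3] * 1e-8
.A_TO_CM <- 1e-8

#' Solvent scattering-length density
#'
#' Neutron scattering-length density of an H2O/D2O mixture, linear in the D2O
#' volume fraction between the pure-water endpoints (-0.561e-6 and
#' +6.37e-6 per square Angstrom).
#'
#' @param f_d2o D2O volume fraction, between 0 and 1.
#' @return Scattering-length density in inverse square Angstroms.
#' @examples
#' solvent_sld(0)     # pure H2O, negative
#' solvent_sld(1)     # pure D2O, positive
#' @export
solvent_sld <- function(f_d2o) {
  if (any(!is.finite(f_d2o)) || any(f_d2o < 0) || any(f_d2o > 1))
    stop("f_d2o must lie in [0, 1]")
  .SLD_H2O + f_d2o * (.SLD_D2O - .SLD_H2O)
}

#' D2O fraction at which the solvent scattering-length density vanishes
#' @return D2O volume fraction (0-1 scale) where solvent SLD crosses zero.
#' @export
solvent_zero_sld_fraction <- function() {
  -.SLD_H2O / (.SLD_D2O - .SLD_H2O)
}

## percent <-> fraction conversion, centralised. External interfaces use
## percent D2O (0-100); internal maths uses fractions (0-1).
pct_to_frac <- function(x) x / 100
frac_to_pct <- function(x) 100 * x
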