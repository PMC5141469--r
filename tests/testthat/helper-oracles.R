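## Independent closed-form oracles used across the test files. These stay
## deliberately separate from the package implementation: plain arithmetic,
## no package internals.

## coherent scattering lengths (fm) and masses, re-entered from standard
## tables rather than taken from the package
orc_b <- c(H = -3.7406, D = 6.671, C = 6.6511, N = 9.36, O = 5.803,
           P = 5.13, S = 2.847)
orc_sld_h2o <- -0.561e-6
orc_sld_d2o <- 6.37e-6

## sphere form-factor amplitude
orc_sphere_amp <- function(x) ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)

## Rg^2 of a two-phase concentric sphere with contrasts dr1 (core, radius
## R1) and dr2 (shell, R1..R2): contrast-weighted <r^2>
orc_rg2_two_phase <- function(dr1, R1, dr2, R2) {
  num <- dr1 * R1^5 + dr2 * (R2^5 - R1^5)
  den <- dr1 * R1^3 + dr2 * (R2^3 - R1^3)
  3 / 5 * num / den
}

## Rg of a uniform spherical shell R1..R2
orc_rg_shell <- function(R1, R2) sqrt(3 / 5 * (R2^5 - R1^5) / (R2^3 - R1^3))

## match point (% D2O) of a composition by direct linear solve:
## b0 [fm], n_ex labile H, fex exchange fraction, V [A^3]
orc_match_point <- function(b0, n_ex, fex, V) {
  sld0 <- b0 * 1e-5 / V
  ex_slope <- n_ex * fex * (orc_b[["D"]] - orc_b[["H"]]) * 1e-5 / V
  100 * (sld0 - orc_sld_h2o) / ((orc_sld_d2o - orc_sld_h2o) - ex_slope)
}

## exact Guinier-form curve
orc_guinier_curve <- function(I0, Rg, q = seq(0.003, 0.08, by = 0.001),
                              sigma_rel = 0.01) {
  I <- I0 * exp(-q^2 * Rg^2 / 3)
  scattering_curve(q, I, sigma_rel * I)
}

## exact homogeneous-sphere curve
orc_sphere_curve <- function(R, q = seq(0.002, 0.2, by = 0.001),
                             scale = 1, sigma = NULL) {
  I <- scale * orc_sphere_amp(q * R)^2
  if (is.null(sigma)) sigma <- pmax(0.01 * I, 1e-12 * scale)
  scattering_curve(q, I, sigma)
}

## parallel-axis law evaluated directly
orc_parallel_axis_rg2 <- function(X, Rp, Rl, D = 0) {
  X * Rp^2 + (1 - X) * Rl^2 + X * (1 - X) * D^2
}
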