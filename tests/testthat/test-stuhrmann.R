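xm <- exchange_model()

## two-phase concentric particle used throughout: low-SLD core, protein shell
two_phase_fixture <- function(core_comp, shell_comp, V_core, V_shell,
                              d2o_grid = c(0, 10, 20, 30, 40, 60, 80, 100)) {
  model <- particle_model(
    list(list(component = core_comp, volume = V_core),
         list(component = shell_comp, volume = V_shell)),
    M_W = shell_comp$molar_mass)
  R1 <- (3 * V_core / (4 * pi))^(1 / 3)
  R2 <- (3 * (V_core + V_shell) / (4 * pi))^(1 / 3)
  ## exact contrast-weighted Rg at each solvent, from the closed form
  rg <- vapply(d2o_grid, function(p) {
    f <- p / 100
    dr1 <- component_sld(core_comp, f, xm) - solvent_sld(f)
    dr2 <- component_sld(shell_comp, f, xm) - solvent_sld(f)
    r2 <- orc_rg2_two_phase(dr1, R1, dr2, R2)
    if (is.finite(r2) && r2 > 0) sqrt(r2) else NA_real_
  }, numeric(1))
  drho <- mean_contrast(list(core_comp, shell_comp),
                        c(V_core, V_shell), d2o_grid, xm)
  list(model = model, R1 = R1, R2 = R2, d2o_grid = d2o_grid,
       Rg = rg, drho = drho)
}

test_that("contrast fraction X hits 1 and 0 at the component match points", {
  pro <- preset_component("htl_protein")
  np <- preset_component("ecoli_inner_membrane_lipid")
  cmp_np <- match_point(np, xm)$value
  cmp_p <- match_point(pro, xm)$value
  X1 <- contrast_fraction_X(pro, np, 3e5, 2e5, cmp_np, xm)
  expect_equal(X1$value, 1, tolerance = 1e-9)
  X0 <- contrast_fraction_X(pro, np, 3e5, 2e5, cmp_p, xm)
  expect_equal(X0$value, 0, tolerance = 1e-9)
  ## symmetric two-component toy, checked against direct drho*V arithmetic
  a <- component("a", "C100H100", dry_volume = 1000)   # no exchange
  b <- component("b", "C100H60N40", dry_volume = 1000)
  at <- function(comp, pct)
    (component_sld(comp, pct / 100, xm) - solvent_sld(pct / 100)) * 1000
  mid <- mixture_match_point(list(a, b), c(1, 1), xm)
  expect_equal(at(a, mid) + at(b, mid), 0, tolerance = 1e-12)
  pct <- mid * 0.8
  Xm <- contrast_fraction_X(a, b, 1000, 1000, pct, xm)
  expect_equal(Xm$value, at(a, pct) / (at(a, pct) + at(b, pct)),
               tolerance = 1e-12)
  expect_error(contrast_fraction_X(pro, np, 3e5, 2e5,
                                   mixture_match_point(list(pro, np),
                                                       c(3, 2), xm), xm),
               "match point")
})

test_that("homogeneous particle gives alpha = 0 and constant Rg^2", {
  R <- 40
  rg <- rep(sqrt(3 / 5) * R, 6)
  drho <- c(-2, -1.2, -0.6, 0.8, 1.5, 2.5) * 1e-6
  s <- stuhrmann_fit(seq(0, 100, length.out = 6), rg, rep(0.05, 6), drho)
  expect_equal(s$alpha, 0, tolerance = 1e-9)
  expect_equal(s$beta, 0)
  expect_equal(s$Rc2, 3 / 5 * R^2, tolerance = 1e-6)
  expect_equal(s$model, "linear")
})

test_that("core-shell Stuhrmann slope sign tracks which phase is peripheral", {
  lipddm <- mixture_component(list(preset_component("ecoli_inner_membrane_lipid"),
                                   preset_component("ddm")),
                              mole_fractions = c(0.6, 0.4), name = "core")
  pro <- preset_component("htl_protein")
  V1 <- 4 / 3 * pi * 30^3
  V2 <- 4 / 3 * pi * (50^3 - 30^3)
  ## high-SLD (protein) shell around low-SLD core: alpha > 0
  fx <- two_phase_fixture(lipddm, pro, V1, V2)
  keep <- abs(fx$drho$value) > 0.1 * max(abs(fx$drho$value))
  s <- stuhrmann_fit(fx$d2o_grid, fx$Rg, rep(0.02, 8), fx$drho$value,
                     model = "linear")
  expect_gt(s$alpha, 0)
  ## Rc^2 at infinite contrast equals the homogeneous-particle value
  expect_equal(s$Rc2, 3 / 5 * fx$R2^2, tolerance = 0.02 * 3 / 5 * fx$R2^2)
  ## swapped arrangement (protein core, lipid shell): alpha < 0, same size
  fx2 <- two_phase_fixture(pro, lipddm,
                           V1 * 0 + 4 / 3 * pi * 30^3,
                           4 / 3 * pi * (50^3 - 30^3))
  s2 <- stuhrmann_fit(fx2$d2o_grid, fx2$Rg, rep(0.02, 8), fx2$drho$value,
                      model = "linear")
  expect_lt(s2$alpha, 0)
})

test_that("parallel-axis fit recovers exact generating parameters", {
  ## echo of the reported component radii: protein 52 A, lipid/detergent 22 A
  X <- seq(0.05, 0.95, length.out = 7)
  rg <- sqrt(orc_parallel_axis_rg2(X, 52, 22, 0))
  p <- parallel_axis_fit(X, rg, rep(0.05, 7))
  expect_equal(p$Rg_P, 52, tolerance = 1e-6)
  expect_equal(p$Rg_L, 22, tolerance = 1e-6)
  expect_equal(p$D, 0)
  ## displaced centres: quadratic model recovers D at zero noise
  rgD <- sqrt(orc_parallel_axis_rg2(X, 52, 22, 35))
  pD <- parallel_axis_fit(X, rgD, rep(0.05, 7), model = "quadratic")
  expect_equal(pD$D, 35, tolerance = 0.1 * 35)
  expect_equal(pD$Rg_P, 52, tolerance = 1e-6)
  ## narrow X range is flagged
  pn <- parallel_axis_fit(c(0.4, 0.45, 0.5, 0.55),
                          sqrt(orc_parallel_axis_rg2(c(0.4, 0.45, 0.5, 0.55),
                                                     52, 22, 0)),
                          rep(0.05, 4))
  expect_true("narrow_X_range_extrapolation" %in% pn$flags)
})

test_that("X = 1 / X = 0 intercepts match analytic shell and core radii", {
  lipddm <- mixture_component(list(preset_component("ecoli_inner_membrane_lipid"),
                                   preset_component("ddm")),
                              mole_fractions = c(0.6, 0.4), name = "core")
  pro <- preset_component("htl_protein")
  V1 <- 4 / 3 * pi * 30^3
  V2 <- 4 / 3 * pi * (50^3 - 30^3)
  fx <- two_phase_fixture(lipddm, pro, V1, V2)
  X <- contrast_fraction_X(pro, lipddm, V2, V1, fx$d2o_grid, xm)
  usable <- is.finite(X$value) & abs(X$value) < 5
  p <- parallel_axis_fit(X$value[usable], fx$Rg[usable],
                         rep(0.02, sum(usable)))
  expect_lt(abs(p$Rg_P / orc_rg_shell(30, 50) - 1), 0.05)
  expect_lt(abs(p$Rg_L / (sqrt(3 / 5) * 30) - 1), 0.05)
})

test_that("Stuhrmann and parallel-axis views of the same series agree", {
  lipddm <- mixture_component(list(preset_component("ecoli_inner_membrane_lipid"),
                                   preset_component("ddm")),
                              mole_fractions = c(0.6, 0.4), name = "core")
  pro <- preset_component("htl_protein")
  V1 <- 4 / 3 * pi * 35^3
  V2 <- 4 / 3 * pi * (55^3 - 35^3)
  fx <- two_phase_fixture(lipddm, pro, V1, V2)
  X <- contrast_fraction_X(pro, lipddm, V2, V1, fx$d2o_grid, xm)
  usable <- is.finite(X$value) & abs(fx$drho$value) >
    0.1 * max(abs(fx$drho$value))
  p <- parallel_axis_fit(X$value[usable], fx$Rg[usable],
                         rep(0.02, sum(usable)))
  s <- stuhrmann_fit(fx$d2o_grid[usable], fx$Rg[usable],
                     rep(0.02, sum(usable)), fx$drho$value[usable],
                     model = "linear")
  ## component radii implied by the Stuhrmann line: evaluate Rg^2 at the
  ## contrasts where only one component scatters
  cmp_p <- match_point(pro, xm)$value
  cmp_np <- match_point(lipddm, xm)$value
  dr_at <- function(pct) mean_contrast(list(lipddm, pro), c(V1, V2),
                                       pct, xm)$value
  rg2_p <- s$Rc2 + s$alpha / dr_at(cmp_np)
  rg2_l <- s$Rc2 + s$alpha / dr_at(cmp_p)
  expect_equal(sqrt(rg2_p), p$Rg_P, tolerance = 0.02 * p$Rg_P)
  expect_equal(sqrt(rg2_l), p$Rg_L, tolerance = 0.02 * p$Rg_L)
})

test_that("low-contrast points are excluded per threshold", {
  rg <- c(40, 41, 39, 40, 400)          # wild Rg at near-zero contrast
  drho <- c(2, 1.5, -1.5, -2, 0.05) * 1e-6
  s <- stuhrmann_fit(1:5, rg, rep(0.5, 5), drho)
  expect_equal(s$n_used, 4)
  expect_equal(s$excluded, 5L)
  expect_error(stuhrmann_fit(1:3, c(40, 41, NA), rep(0.5, 3),
                             c(1, 0.01, 0.02) * 1e-6), "3 usable")
})
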