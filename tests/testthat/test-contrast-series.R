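xm <- exchange_model()

test_that("per-particle scattering length normalises concentration away", {
  ## doubling c doubles I(0); the recovered rhoV is unchanged
  rv1 <- scattering_length_from_I0(0.8, 0.01, 2, 250000)
  rv2 <- scattering_length_from_I0(1.6, 0.02, 4, 250000)
  expect_equal(rv1$rhoV, rv2$rhoV, tolerance = 1e-12)
  expect_equal(scattering_length_from_I0(0, 0.01, 2, 250000)$rhoV, 0)
  expect_error(scattering_length_from_I0(-1, 0.01, 2, 250000), ">= 0")
})

test_that("water calibration bracket converts count ratios to 1/cm", {
  calib <- water_calibration()   # T_w 0.53, f(6A) 0.8, 1 mm cell
  I0_abs <- 0.45
  ## invert the bracket by hand, then convert back
  ratio <- I0_abs / ((calib$T_water * calib$t_water) / (0.85 * 0.2) *
                       (1 - calib$T_water) /
                       (4 * pi * calib$t_water * calib$f_lambda))
  expect_equal(absolute_I0_from_water(ratio, 0.85, 0.2, calib), I0_abs,
               tolerance = 1e-12)
})

test_that("simulator roundtrip recovers the generating excess scattering length", {
  pro <- preset_component("htl_protein")
  model <- particle_model(list(list(component = pro,
                                    volume = pro$dry_volume)),
                          M_W = pro$molar_mass)
  cfg <- simulation_config(seed = 11, noise_rel = 0)
  cv <- simulate_curve(model, 0, cfg, add_noise = FALSE)
  g <- guinier_fit(cv)
  rv <- scattering_length_from_I0(g$I0, g$I0_err, cfg$concentration,
                                  pro$molar_mass)
  truth <- (component_sld(pro, 0, xm) - solvent_sld(0)) *
    pro$dry_volume * 1e-8
  expect_equal(rv$rhoV, abs(truth), tolerance = 0.005)
})

test_that("contrast-variation line finds the exact root of exact data", {
  x <- c(0, 10, 20, 30, 50, 70, 90, 100)
  y <- 2e-9 * (24 - x)              # root at 24% D2O
  ln <- fit_cv_line(x, abs(y), rep(1e-11, 8))
  expect_equal(ln$cmp, 24, tolerance = 1e-9)
  expect_lt(ln$chi2_red, 1e-10)
  expect_lt(ln$slope, 0)
  ## two-point minimal input: exact interpolation with a warning
  expect_warning(ln2 <- fit_cv_line(c(0, 50), abs(2e-9 * (24 - c(0, 50))),
                                    rep(1e-11, 2)), "2 contrast points")
  expect_equal(ln2$cmp, 24, tolerance = 1e-9)
})

test_that("native-like synthetic series reproduces its mixture match point", {
  fx <- make_fixture_suite("htl_native_like", seed = 5, noise_rel = 0.05)
  g <- contrast_series_guinier(fx$curves, d2o_pct = fx$config$d2o_grid)
  sl <- scattering_length_from_I0(g$I0, g$I0_err, fx$config$concentration,
                                  fx$model$M_W)
  ln <- fit_cv_line(fx$sample_sheet$d2o_pct, sl$rhoV, sl$rhoV_err)
  expect_lt(abs(ln$cmp - fx$manifest$cmp_total), 0.25)
})

test_that("oligomeric state is linear in copy number and zero for protein-free", {
  pro <- preset_component("htl_protein")
  lip <- preset_component("ecoli_inner_membrane_lipid")
  ddm <- preset_component("ddm")
  series_for <- function(n_copies, with_protein = TRUE) {
    V_P <- pro$dry_volume * n_copies
    regions <- list(list(component = lip, volume = 2e5),
                    list(component = ddm, volume = 1e5))
    if (with_protein)
      regions <- c(regions, list(list(component = pro, volume = V_P)))
    model <- particle_model(regions, M_W = pro$molar_mass)
    cfg <- simulation_config(seed = 9, noise_rel = 0)
    curves <- simulate_series(model, cfg, add_noise = FALSE)
    g <- contrast_series_guinier(curves, d2o_pct = cfg$d2o_grid)
    sl <- scattering_length_from_I0(g$I0, g$I0_err, cfg$concentration,
                                    pro$molar_mass)
    fit_cv_line(cfg$d2o_grid, sl$rhoV, sl$rhoV_err)
  }
  cmp_np <- mixture_match_point(list(lip, ddm), c(2, 1), xm)
  o1 <- oligomeric_state(series_for(1), pro, cmp_np, xm)
  o2 <- oligomeric_state(series_for(2), pro, cmp_np, xm)
  expect_equal(o1$n_copies, 1, tolerance = 0.03)
  expect_equal(o2$n_copies / o1$n_copies, 2, tolerance = 0.03)
  o0 <- oligomeric_state(series_for(1, with_protein = FALSE), pro, cmp_np, xm)
  expect_lt(abs(o0$n_copies), 0.05)
})

test_that("protein subtraction yields the non-protein line and match point", {
  fx <- make_fixture_suite("htl_native_like", seed = 3, noise_rel = 0)
  g <- contrast_series_guinier(fx$curves, d2o_pct = fx$config$d2o_grid)
  sl <- scattering_length_from_I0(g$I0, g$I0_err, fx$config$concentration,
                                  fx$model$M_W)
  ln <- fit_cv_line(fx$sample_sheet$d2o_pct, sl$rhoV, sl$rhoV_err)
  np <- subtract_protein(ln, fx$components$protein, 1, xm)
  expect_lt(abs(np$cmp - fx$manifest$cmp_nonprotein), 0.1)
  expect_true(np$cmp_err_total >= np$cmp_err)
  ## subtracting zero copies is the identity
  same <- subtract_protein(ln, fx$components$protein, 0, xm)
  expect_equal(same$cmp, ln$cmp, tolerance = 1e-12)
  expect_equal(same$slope, ln$slope, tolerance = 1e-15)
  ## pure-protein particle: residual indistinguishable from zero
  pro <- preset_component("htl_protein")
  model <- particle_model(list(list(component = pro,
                                    volume = pro$dry_volume)),
                          M_W = pro$molar_mass)
  cfg <- simulation_config(seed = 2, noise_rel = 0.02)
  curves <- simulate_series(model, cfg)
  g2 <- contrast_series_guinier(curves, d2o_pct = cfg$d2o_grid)
  keep <- !grepl("positive_slope|low_contrast", g2$flags)
  sl2 <- scattering_length_from_I0(g2$I0[keep], g2$I0_err[keep],
                                   cfg$concentration, pro$molar_mass)
  ln2 <- fit_cv_line(cfg$d2o_grid[keep], sl2$rhoV, sl2$rhoV_err)
  expect_warning(subtract_protein(ln2, pro, 1, xm), "indistinguishable")
})

test_that("volume-fraction solver reproduces the printed decompositions", {
  pro <- list(cmp = 39.0, err = 0)
  d <- solve_volume_fractions(24, 16.5, pro, n_copies = 1,
                              lipid = 13.1, detergent = 21.7,
                              cmp_total_err = 0.2, cmp_nonprotein_err = 0.3,
                              V_P = 3e5)
  expect_equal(d$v_P, 1 / 3, tolerance = 1e-3)
  expect_gt(d$v_P_err, 0)
  ## match-point mixing roundtrip at machine precision on exact inputs
  set.seed(7)
  for (i in 1:10) {
    fr <- runif(3); fr <- fr / sum(fr)
    cmps <- c(39.0, 13.1, 21.7)
    cmp_np <- mixture_match_point(cmps[2:3], fr[2:3])
    cmp_tot <- mixture_match_point(c(cmps[1], cmp_np),
                                   c(fr[1], fr[2] + fr[3]))
    d2 <- solve_volume_fractions(cmp_tot, cmp_np, list(cmp = 39.0),
                                 lipid = 13.1, detergent = 21.7, V_P = 1e5)
    expect_equal(c(d2$v_P, d2$v_L, d2$v_D), fr, tolerance = 1e-9)
  }
  ## degenerate input: all protein
  d3 <- solve_volume_fractions(39.0, 16.5, list(cmp = 39.0),
                               lipid = 13.1, detergent = 21.7, V_P = 1e5)
  expect_equal(d3$v_P, 1, tolerance = 1e-9)
  expect_equal(d3$v_L + d3$v_D, 0, tolerance = 1e-9)
  expect_error(solve_volume_fractions(20, 16.5, list(cmp = 16.5),
                                      lipid = 13.1, detergent = 21.7,
                                      V_P = 1e5), "degenerate")
})

test_that("cross-linked split reproduces the printed lipid fraction", {
  g <- solve_mixing_fraction(18, 13.1, 21.7)
  expect_equal(g * 0.59, 0.254, tolerance = 0.002)
})

test_that("lipid count follows the volume arithmetic", {
  expect_equal(lipid_count(0, lipid_mol_volume = 1200)$count, 0)
  expect_equal(lipid_count(2400, lipid_mol_volume = 1200)$count, 2)
  ## native-like decomposition, hand-computed oracle:
  ## V_P = MW vbar / NA, V_total = V_P / v_P, V_L = v_L V_total
  V_P <- 250000 * 0.73 / 6.02214076e23 * 1e24
  V_total <- V_P / 0.33
  V_L <- 0.41 * V_total
  lc <- lipid_count(V_L, lipid_mol_volume = 1218)
  expect_equal(lc$count, V_L / 1218, tolerance = 1e-9)
  expect_gt(lc$count, 200); expect_lt(lc$count, 400)  # low hundreds
  ## the range spans the volume range and the error
  lc2 <- lipid_count(V_L, lipid_mol_volume = 1218,
                     volume_range = c(1000, 1400), V_lipid_err = 2e4)
  expect_lt(lc2$low, lc$count)
  expect_gt(lc2$high, lc$count)
})

test_that("concentration from absorbance matches the 0.5 A factor", {
  expect_equal(concentration_from_absorbance(1.0), 0.5)
  expect_equal(concentration_from_absorbance(0), 0)
  ## general form with the measured extinction coefficient
  expect_equal(concentration_from_absorbance(1.0, epsilon = 497000,
                                             M_W = 250000), 0.5,
               tolerance = 0.01)
})
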