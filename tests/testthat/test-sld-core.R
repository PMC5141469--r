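test_that("solvent SLD is the standard linear H2O/D2O interpolation", {
  expect_lt(solvent_sld(0), 0)          # pure H2O is negative
  expect_gt(solvent_sld(1), 0)          # pure D2O is positive
  ## root of the line, solved independently from the endpoint constants
  root <- (0 - orc_sld_h2o) / (orc_sld_d2o - orc_sld_h2o)
  expect_equal(solvent_zero_sld_fraction(), root, tolerance = 1e-12)
  expect_equal(solvent_sld(solvent_zero_sld_fraction()), 0,
               tolerance = 1e-18)
  expect_error(solvent_sld(1.2), "0, 1")
  expect_error(solvent_sld(-0.1), "0, 1")
})

test_that("formula parsing and composition invariants", {
  cc <- parse_formula("C24H46O11", n_exchangeable_H = 7)
  expect_equal(unname(cc$counts[c("C", "H", "O")]), c(24, 46, 11))
  expect_error(parse_formula("C2Qx4"), "unknown element|parse")
  expect_error(atomic_composition(c(H = 2), n_exchangeable_H = 3), "H count")
  expect_error(atomic_composition(c(C = -1)), ">= 0")
})

test_that("component scattering length matches per-atom summation", {
  xm <- exchange_model()
  ## pure H2O formula unit at 0% D2O: 2 b_H + b_O
  w <- component("water", "H2O", n_exchangeable_H = 2, dry_volume = 30)
  expect_equal(component_scattering_length(w, 0, xm)$value,
               (2 * orc_b[["H"]] + orc_b[["O"]]) * 1e-13, tolerance = 1e-12)
  ## dipeptide AG = A + G - H2O = C5H10N2O3, independent per-atom sum
  ag <- component("AG", protein_composition_from_sequence("AG"),
                  specific_volume = 0.73)
  b_orc <- (5 * orc_b[["C"]] + 10 * orc_b[["H"]] + 2 * orc_b[["N"]] +
              3 * orc_b[["O"]]) * 1e-13
  expect_equal(component_scattering_length(ag, 0, xm)$value, b_orc,
               tolerance = 1e-10)
  ## no exchangeable H: value independent of f_D2O
  alk <- component("alkane", "C10H22", n_exchangeable_H = 0,
                   specific_volume = 1.2)
  expect_equal(component_scattering_length(alk, 0, xm)$value,
               component_scattering_length(alk, 1, xm)$value)
  ## affine in f_D2O
  b <- vapply(c(0, 0.5, 1),
              function(f) component_scattering_length(w, f, xm)$value,
              numeric(1))
  expect_equal(b[2], mean(b[c(1, 3)]), tolerance = 1e-12)
})

test_that("protein composition from sequence follows the residue table", {
  g <- protein_composition_from_sequence("G")
  expect_equal(unname(g$counts[c("C", "H", "N", "O")]), c(2, 5, 1, 2))
  gg <- protein_composition_from_sequence("GG")
  expect_equal(unname(gg$counts[c("C", "H", "N", "O")]), c(4, 8, 2, 3))
  ## 10-residue peptide vs an independent free-amino-acid sum minus 9 H2O
  free <- rbind(A = c(3, 7, 1, 2, 0), C = c(3, 7, 1, 2, 1),
                D = c(4, 7, 1, 4, 0), E = c(5, 9, 1, 4, 0),
                F = c(9, 11, 1, 2, 0), G = c(2, 5, 1, 2, 0),
                H = c(6, 9, 3, 2, 0), I = c(6, 13, 1, 2, 0),
                K = c(6, 14, 2, 2, 0), L = c(6, 13, 1, 2, 0))
  tot <- colSums(free) - c(0, 2 * 9, 0, 9, 0)
  p <- protein_composition_from_sequence("ACDEFGHIKL")
  expect_equal(unname(p$counts[c("C", "H", "N", "O", "S")]), unname(tot))
  expect_error(protein_composition_from_sequence("ACDEFGHIKZ"), "unknown")
})

test_that("DDM and E. coli lipid match points agree with a linear-solve oracle", {
  xm <- exchange_model()
  ddm <- preset_component("ddm")
  ## independent spreadsheet-style solve from composition and volume
  b0 <- 24 * orc_b[["C"]] + 46 * orc_b[["H"]] + 11 * orc_b[["O"]]
  mp_orc <- orc_match_point(b0, 7, 0.80, ddm$dry_volume)
  mp <- match_point(ddm, xm)
  expect_equal(mp$value, mp_orc, tolerance = 1e-10)
  expect_gt(mp$value, 20)          # low-20s % D2O
  expect_lt(mp$value, 23)
  expect_true(mp$in_range)
  ## the measured DDM value 21.7 lies within the exchange band
  expect_lt(mp$low, 21.8)
  expect_gt(mp$high, 21.3)
  lip <- preset_component("ecoli_inner_membrane_lipid")
  expect_equal(match_point(lip, xm)$value, 13.1, tolerance = 0.02)
})

test_that("raising the exchange fraction raises a protein's match point", {
  pro <- preset_component("htl_protein")
  mps <- vapply(c(0.7, 0.8, 0.9),
                function(fx) match_point(pro, exchange_model(fx, 0.5, 1))$value,
                numeric(1))
  expect_true(all(diff(mps) > 0))
})

test_that("mixture match points are bounded, monotone and invert exactly", {
  expect_equal(mixture_match_point(c(13.1, 21.7), c(41, 26)), 16.4373134,
               tolerance = 1e-6)
  expect_equal(mixture_match_point(c(39.0, 13.1, 21.7), c(33, 41, 26)),
               23.883, tolerance = 1e-6)
  expect_equal(mixture_match_point(17.3, 1), 17.3)
  set.seed(42)
  for (i in 1:25) {
    cmps <- sort(runif(2, 5, 45))
    v <- runif(1)
    mix <- mixture_match_point(cmps, c(v, 1 - v))
    expect_gte(mix, cmps[1]); expect_lte(mix, cmps[2])
    ## solve_mixing_fraction is the exact algebraic inverse
    expect_equal(solve_mixing_fraction(mix, cmps[1], cmps[2]), v,
                 tolerance = 1e-12)
  }
  ## monotone in the first fraction
  m1 <- mixture_match_point(c(10, 30), c(0.2, 0.8))
  m2 <- mixture_match_point(c(10, 30), c(0.4, 0.6))
  expect_lt(m2, m1)
  expect_error(mixture_match_point(numeric(0), numeric(0)), "empty")
  expect_error(solve_mixing_fraction(20, 15, 15), "undetermined")
  expect_warning(f <- solve_mixing_fraction(50, 39, 16.5), "clamped")
  expect_equal(f, 1)
  expect_equal(solve_mixing_fraction(39, 39, 16.5), 1)
})

test_that("exact mixture root deviates from the weighted mean only via exchange slopes", {
  xm <- exchange_model()
  pro <- preset_component("htl_protein")
  lip <- preset_component("ecoli_inner_membrane_lipid")
  ddm <- preset_component("ddm")
  fr <- c(0.33, 0.41, 0.26)
  exact <- mixture_match_point(list(pro, lip, ddm), fr, xm)
  approx <- mixture_match_point(c(match_point(pro, xm)$value,
                                  match_point(lip, xm)$value,
                                  match_point(ddm, xm)$value), fr)
  expect_lt(abs(exact - approx), 0.6)   # small but nonzero discrepancy
  expect_gt(abs(exact - approx), 1e-3)
  ## with no exchangeable hydrogens the two coincide exactly
  a <- component("a", "C10H22", dry_volume = 300)
  b <- component("b", "C5H5N5", dry_volume = 200)
  expect_equal(mixture_match_point(list(a, b), c(0.3, 0.7), xm),
               mixture_match_point(c(match_point(a, xm)$value,
                                     match_point(b, xm)$value), c(0.3, 0.7)),
               tolerance = 1e-9)
})
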