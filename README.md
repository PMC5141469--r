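# tricontrast

Contrast-variation SANS decomposition of detergent-solubilised
membrane-protein complexes into their protein, lipid and detergent parts.

Membrane proteins are extracted from the bilayer inside a detergent belt,
usually dragging co-purified lipids along. Small-angle neutron scattering
(SANS) measured in a series of H2O/D2O buffers can dissect such a
three-component particle without any structural model, because protein,
detergent and lipid have well-separated **contrast match points** (CMPs) —
the solvent %D2O at which a component's neutron scattering-length density
equals the solvent's and it stops scattering. With intensities on absolute
scale (cm⁻¹), the forward scattering I(0) also reports the particle's total
excess scattering length ρV, and hence the protein stoichiometry.

`tricontrast` implements the full analysis chain:

* **SLD layer** — neutron scattering lengths, SLDs and match points for
  formulas, protein sequences and mixtures, with labile-H/D exchange
  (default 80%, uncertainty band 70–90%) propagated into every error bar.
* **Guinier analysis** — I(0) and R_g from reduced 1D curves, with a
  self-consistent q·R_g ≤ 1.3 window, residual-runs trimming, and errors
  propagated from the measurement sigmas.
* **Contrast-variation line** — signed ρV = √(I(0)·M_W/(c·N_A)) versus
  %D2O; its root is the complex match point. Subtracting the theoretical
  protein line gives the non-protein (lipid/detergent) line, its match
  point, the lipid:detergent volume split, the protein/lipid/detergent
  volume fractions (v/v), the lipid copy number, and the oligomeric state
  from extrapolation to 0% D2O.
* **Stuhrmann and parallel-axis analysis** —
  R_g² = R_c² + α/Δρ̄ − β/Δρ̄² and
  R_g² = X·R_P² + (1−X)·R_L² + X(1−X)·D²: the radial arrangement
  (α > 0 ⇒ high-SLD protein peripheral) and the component radii of
  gyration.
* **Forward simulator** — absolute-scale core–shell contrast series with
  counting noise and a ground-truth manifest, so the whole pipeline is
  verifiable without external data.

## Worked example

Match point of the detergent DDM (C24H46O11, 7 labile H, 0.82 ml/g) and of
a 41:26 lipid:DDM mixture:

```r
library(tricontrast)
match_point(preset_component("ddm"))
#> $value
#> [1] 21.34044
#> $low
#> [1] 20.97948
#> $high
#> [1] 21.71404
#> $in_range
#> [1] TRUE

mixture_match_point(c(13.1, 21.7), c(41, 26))
#> [1] 16.43731
```

The calculated DDM CMP is 21.3% D2O with the measured literature value
(21.7%) inside the exchange band; a 41:26 lipid:DDM mixture matches out at
16.4% D2O. The full pipeline on a simulated native-like complex (250 kDa
protein shell, lipid/DDM core, 33/41/26 v/v, 8 contrast points, 5%
counting noise):

```r
fx <- make_fixture_suite("htl_native_like", seed = 7, noise_rel = 0.05)
rep <- suppressWarnings(run_full(fx$sample_sheet, fx$components,
                                 analysis_config(), curves = fx$curves))
rep
#> == contrast-variation SANS analysis ==
#> complex match point:      23.63 +/- 0.02 % D2O
#> non-protein match point:  16.11 +/- 0.13 % D2O
#> oligomeric state:         1.00 +/- 0.00 protein copies
#> volume fractions (v/v):   protein 33.0 +/- 1.0%, lipid 40.9 +/- 1.6%, detergent 26.2 +/- 1.7%
#> lipids per particle:      308 (292 - 325)
#> Stuhrmann (parabolic):       Rc = 46.2 A, alpha = 0.000544 (high-SLD component peripheral)
#> parallel axis:            Rg_protein = 57.1 +/- 0.91 A, Rg_nonprotein = 41.7 +/- 0.5 A
```

The generating fractions (33/41/26) are recovered within error, the copy
number comes back as 1.00, the positive Stuhrmann slope identifies the
protein as peripheral, and the component radii match the manifest's
shell/core values (56.7 / 40.9 Å). `write_report()` saves the same results
as JSON (machine) and TSV (human summary); `make_fixture_suite(dir = ...)`
writes curves, sample sheet, component definitions and manifest as plain
text files that `run_full()` consumes.

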