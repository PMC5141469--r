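## sphere form-factor amplitude, Phi(0) = 1; series expansion below
## x = 0.02 avoids catastrophic cancellation in sin(x) - x cos(x)
sphere_amp <- function(x) {
  out <- 1 - x^2 / 10 + x^4 / 280
  nz <- x >= 0.02
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

#' Particle model for the forward simulator
#'
#' Concentric spheres: each region is a component occupying a given volume,
#' innermost first (the classic low-SLD lipid/detergent core wrapped in a
#' higher-SLD protein shell). `"displaced"` places the first two regions as
#' separate spheres with centres `separation` apart, for scenarios where the
#' component centres of mass do not coincide.
#'
#' @param regions list of `list(component = <sans_component>, volume = <A^3>)`,
#'   innermost region first.
#' @param M_W molar mass of the protein moiety per particle, g/mol (converts
#'   mass concentration to particle number density, as in the analysis).
#' @param n_copies protein copies per particle (bookkeeping for the
#'   manifest).
#' @param geometry `"concentric"` or `"displaced"`.
#' @param separation centre-to-centre distance, Angstroms (displaced only).
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(regions, M_W, n_copies = 1,
                           geometry = c("concentric", "displaced"),
                           separation = 0) {
  geometry <- match.arg(geometry)
  stopifnot(length(regions) >= 1, M_W > 0)
  for (r in regions) {
    stopifnot(inherits(r$component, "sans_component"), r$volume > 0)
  }
  if (geometry == "displaced" && length(regions) != 2)
    stop("displaced geometry needs exactly 2 regions")
  if (separation < 0) stop("separation must be >= 0")
  structure(list(regions = regions, M_W = M_W, n_copies = n_copies,
                 geometry = geometry, separation = separation),
            class = "particle_model")
}

#' Simulation configuration
#'
#' @param d2o_grid percent D2O values of the contrast series.
#' @param q momentum-transfer grid, 1/Angstrom.
#' @param concentration protein concentration, mg/ml.
#' @param noise_rel relative counting noise at I(0); sigma scales with
#'   sqrt(I(q) I(0)) so that the relative error grows towards high q as in
#'   counting statistics.
#' @param noise_floor additive uncertainty floor, 1/cm (residual background
#'   subtraction error, keeps near-match-point curves from having zero
#'   sigma).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param exchange [exchange_model()] applied to component SLDs (the same
#'   model the analysis uses).
#' @param transmission,path_length,wavelength instrument metadata carried
#'   into the sample sheet.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(d2o_grid = c(0, 10, 20, 30, 40, 60, 80, 100),
                              q = exp(seq(log(0.004), log(0.3),
                                          length.out = 150)),
                              concentration = 2, noise_rel = 0.05,
                              noise_floor = 5e-4, seed = 1,
                              exchange = exchange_model(),
                              transmission = 0.9, path_length = 0.1,
                              wavelength = 6) {
  stopifnot(noise_rel >= 0, noise_floor >= 0, concentration > 0)
  structure(list(d2o_grid = d2o_grid, q = q, concentration = concentration,
                 noise_rel = noise_rel, noise_floor = noise_floor,
                 seed = seed, exchange = exchange,
                 transmission = transmission, path_length = path_length,
                 wavelength = wavelength),
            class = "simulation_config")
}

## per-region contrasts (1/A^2) at solvent percent D2O
region_contrasts <- function(model, d2o_pct, xm) {
  f <- pct_to_frac(d2o_pct)
  vapply(model$regions, function(r) {
    component_sld(r$component, f, xm) - solvent_sld(f)
  }, numeric(1))
}

## coherent forward amplitude sum, cm: sum_i drho_i V_i
model_rhoV <- function(model, d2o_pct, xm) {
  dr <- region_contrasts(model, d2o_pct, xm)
  vols <- vapply(model$regions, function(r) r$volume, numeric(1))
  sum(dr * vols) * .A_TO_CM
}

## noise-free I(q) in 1/cm for one solvent
model_intensity <- function(model, d2o_pct, cfg) {
  xm <- cfg$exchange
  q <- cfg$q
  dr <- region_contrasts(model, d2o_pct, xm)
  vols <- vapply(model$regions, function(r) r$volume, numeric(1))
  n_dens <- cfg$concentration * 1e-3 * .N_AVOGADRO / model$M_W
  if (model$geometry == "concentric") {
    Vcum <- cumsum(vols)
    Rcum <- (3 * Vcum / (4 * pi))^(1 / 3)
    A <- 0
    Vprev <- 0; Rprev <- 0
    for (i in seq_along(vols)) {
      shell <- Vcum[i] * sphere_amp(q * Rcum[i]) -
        (if (i > 1) Vprev * sphere_amp(q * Rprev) else 0)
      A <- A + dr[i] * shell
      Vprev <- Vcum[i]; Rprev <- Rcum[i]
    }
    I <- n_dens * (A * .A_TO_CM)^2
  } else {
    R <- (3 * vols / (4 * pi))^(1 / 3)
    A1 <- dr[1] * vols[1] * sphere_amp(q * R[1]) * .A_TO_CM
    A2 <- dr[2] * vols[2] * sphere_amp(q * R[2]) * .A_TO_CM
    qd <- q * model$separation
    sinc <- ifelse(qd < 1e-8, 1, sin(qd) / qd)
    I <- n_dens * (A1^2 + A2^2 + 2 * A1 * A2 * sinc)
  }
  I
}

#' Simulate one absolute-scale SANS curve
#'
#' Sphere/shell form-factor intensity `I(q) = n [sum_i drho_i V_i F_i(q)]^2`
#' on absolute scale, with Gaussian counting noise.
#'
#' @param model a [particle_model()].
#' @param d2o_pct solvent percent D2O.
#' @param cfg a [simulation_config()]; its seed is NOT set here -- seed once
#'   per series (see [simulate_series()]) or set it yourself for a single
#'   reproducible curve.
#' @param add_noise logical.
#' @return A [scattering_curve()] with solvent and sample metadata.
#' @export
simulate_curve <- function(model, d2o_pct, cfg = simulation_config(),
                           add_noise = TRUE) {
  I_clean <- model_intensity(model, d2o_pct, cfg)
  I0 <- I_clean[1]
  sigma <- cfg$noise_rel * sqrt(pmax(I_clean, 0) * max(I0, 0)) + cfg$noise_floor
  sigma <- pmax(sigma, 1e-12)
  I <- if (add_noise && cfg$noise_rel > 0)
    I_clean + stats::rnorm(length(I_clean), 0, sigma) else I_clean
  scattering_curve(cfg$q, I, sigma,
                   metadata = list(d2o_pct = d2o_pct,
                                   concentration = cfg$concentration,
                                   transmission = cfg$transmission,
                                   path_length = cfg$path_length,
                                   wavelength = cfg$wavelength))
}

#' Simulate a full contrast series
#'
#' @inheritParams simulate_curve
#' @return list of [scattering_curve()], one per entry of `cfg$d2o_grid`.
#' @export
simulate_series <- function(model, cfg = simulation_config(),
                            add_noise = TRUE) {
  set.seed(cfg$seed)
  lapply(cfg$d2o_grid, function(p) simulate_curve(model, p, cfg, add_noise))
}

#' Ready-made simulation scenarios with ground-truth manifest
#'
#' Builds a complete synthetic contrast-variation dataset: curves, a sample
#' sheet, component definitions and a manifest of the true match points,
#' volume fractions, copy number and component radii of gyration. Scenarios:
#'
#' * `"htl_native_like"` -- 250 kDa protein shell around a lipid/DDM core,
#'   protein/lipid/detergent 33/41/26 v/v (the composition reported for a
#'   native detergent-solubilised holo-translocon).
#' * `"htl_crosslinked_like"` -- same components at 41/25/33 v/v.
#' * `"homogeneous"` -- a uniform single-component sphere (alpha = 0).
#' * `"displaced_centres"` -- protein and lipid spheres with separated
#'   centres (beta > 0, D > 0).
#' * `"protein_only"` -- pure protein particle, no non-protein moiety.
#'
#' @param scenario scenario name.
#' @param seed RNG seed.
#' @param noise_rel relative counting noise at I(0).
#' @param dir optional directory; when given, curves (`*.dat`), the sample
#'   sheet (`samples.tsv`), component definitions (`components.yaml`) and
#'   the manifest (`manifest.json`) are written there.
#' @param cfg optional [simulation_config()] overriding the defaults (its
#'   seed/noise are replaced by the `seed`/`noise_rel` arguments).
#' @return list with `curves`, `sample_sheet` (data.frame), `components`
#'   (list of `sans_component`), `manifest` (list), `model`, `config`, and
#'   `paths` when `dir` was given.
#' @export
make_fixture_suite <- function(scenario = c("htl_native_like",
                                            "htl_crosslinked_like",
                                            "homogeneous",
                                            "displaced_centres",
                                            "protein_only"),
                               seed = 1, noise_rel = 0.05, dir = NULL,
                               cfg = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(cfg)) cfg <- simulation_config()
  cfg$seed <- seed
  cfg$noise_rel <- noise_rel
  xm <- cfg$exchange

  protein <- preset_component("htl_protein")
  lipid <- preset_component("ecoli_inner_membrane_lipid")
  ddm <- preset_component("ddm")

  build_three <- function(fr) {   # fr = c(protein, lipid, detergent) v/v
    V_P <- protein$dry_volume
    V_total <- V_P / fr[1]
    v_np <- fr[2] + fr[3]
    nonprotein <- mixture_component(
      list(lipid, ddm),
      mole_fractions = c(fr[2] / lipid$dry_volume, fr[3] / ddm$dry_volume),
      name = "lipid/DDM", role = "other")
    model <- particle_model(
      list(list(component = nonprotein, volume = v_np * V_total),
           list(component = protein, volume = fr[1] * V_total)),
      M_W = protein$molar_mass, n_copies = 1)
    R1 <- (3 * v_np * V_total / (4 * pi))^(1 / 3)
    R2 <- (3 * V_total / (4 * pi))^(1 / 3)
    cmps <- c(protein = match_point(protein, xm)$value,
              lipid = match_point(lipid, xm)$value,
              detergent = match_point(ddm, xm)$value)
    ## exact roots of the simulated particle's excess scattering length
    cmp_np <- mixture_match_point(list(lipid, ddm), fr[2:3], xm)
    list(model = model, nonprotein = nonprotein,
         manifest = list(
           scenario = scenario,
           fractions = c(protein = fr[1], lipid = fr[2], detergent = fr[3]),
           cmp_protein = unname(cmps["protein"]),
           cmp_lipid = unname(cmps["lipid"]),
           cmp_detergent = unname(cmps["detergent"]),
           cmp_nonprotein = cmp_np,
           cmp_total = mixture_match_point(list(protein, lipid, ddm), fr, xm),
           n_copies = 1,
           V_total = V_total, V_P = V_P,
           R_core = R1, R_outer = R2,
           Rg_core = sqrt(3 / 5) * R1,
           Rg_shell = sqrt(3 / 5 * (R2^5 - R1^5) / (R2^3 - R1^3)),
           Rg_infinite_contrast = sqrt(3 / 5) * R2))
  }

  out <- switch(scenario,
    htl_native_like = build_three(c(0.33, 0.41, 0.26)),
    htl_crosslinked_like = build_three(c(0.41, 0.25, 0.33)),
    homogeneous = {
      V_P <- protein$dry_volume
      R <- (3 * V_P / (4 * pi))^(1 / 3)
      model <- particle_model(
        list(list(component = protein, volume = V_P)),
        M_W = protein$molar_mass)
      list(model = model, nonprotein = NULL,
           manifest = list(
             scenario = scenario,
             fractions = c(protein = 1, lipid = 0, detergent = 0),
             cmp_protein = match_point(protein, xm)$value,
             cmp_total = match_point(protein, xm)$value,
             n_copies = 1, V_total = V_P, V_P = V_P,
             Rg_all_contrasts = sqrt(3 / 5) * R,
             Rg_infinite_contrast = sqrt(3 / 5) * R))
    },
    protein_only = {
      V_P <- protein$dry_volume
      R <- (3 * V_P / (4 * pi))^(1 / 3)
      model <- particle_model(
        list(list(component = protein, volume = V_P)),
        M_W = protein$molar_mass)
      list(model = model, nonprotein = NULL,
           manifest = list(
             scenario = scenario,
             fractions = c(protein = 1, lipid = 0, detergent = 0),
             cmp_protein = match_point(protein, xm)$value,
             cmp_total = match_point(protein, xm)$value,
             n_copies = 1, V_total = V_P, V_P = V_P,
             Rg_infinite_contrast = sqrt(3 / 5) * R))
    },
    displaced_centres = {
      V_P <- protein$dry_volume
      V_L <- 0.8 * V_P
      sep <- 60
      nonprotein <- mixture_component(
        list(lipid, ddm),
        mole_fractions = c(0.6 / lipid$dry_volume, 0.4 / ddm$dry_volume),
        name = "lipid/DDM", role = "other")
      model <- particle_model(
        list(list(component = nonprotein, volume = V_L),
             list(component = protein, volume = V_P)),
        M_W = protein$molar_mass, geometry = "displaced", separation = sep)
      RP <- (3 * V_P / (4 * pi))^(1 / 3)
      RL <- (3 * V_L / (4 * pi))^(1 / 3)
      list(model = model, nonprotein = nonprotein,
           manifest = list(
             scenario = scenario,
             cmp_protein = match_point(protein, xm)$value,
             cmp_nonprotein = match_point(nonprotein, xm)$value,
             n_copies = 1, V_P = V_P, V_nonprotein = V_L,
             separation = sep,
             Rg_protein = sqrt(3 / 5) * RP,
             Rg_nonprotein = sqrt(3 / 5) * RL))
    })

  curves <- simulate_series(out$model, cfg)
  sheet <- data.frame(
    file = sprintf("curve_d2o%03d.dat", round(cfg$d2o_grid)),
    d2o_pct = cfg$d2o_grid,
    concentration = cfg$concentration,
    transmission = cfg$transmission,
    path_length = cfg$path_length,
    wavelength = cfg$wavelength)
  components <- list(protein = protein, lipid = lipid, detergent = ddm)
  if (!is.null(out$nonprotein)) components$nonprotein <- out$nonprotein
  res <- list(curves = curves, sample_sheet = sheet, components = components,
              manifest = out$manifest, model = out$model, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(curves))
      write_curve(curves[[i]], file.path(dir, sheet$file[i]))
    utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_components_yaml(components, file.path(dir, "components.yaml"))
    res$paths <- list(dir = dir,
                      samples = file.path(dir, "samples.tsv"),
                      manifest = file.path(dir, "manifest.json"),
                      components = file.path(dir, "components.yaml"))
  }
  res
}
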