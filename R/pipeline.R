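#' Analysis configuration
#'
#' One object holding every tunable policy of the pipeline, echoed into the
#' report's provenance.
#'
#' @param qrg_limit Guinier validity limit for q*Rg (default 1.3).
#' @param window_policy Guinier window policy, `"qrg"` or `"fixed"`.
#' @param sign_policy sign assignment for the contrast-variation line.
#' @param stuhrmann_model `"auto"`, `"linear"` or `"parabolic"`.
#' @param parallel_axis_model `"linear"` or `"quadratic"`.
#' @param exclude_frac low-contrast exclusion threshold (fraction of max
#'   |drho|) for the Stuhrmann fit.
#' @param exchange an [exchange_model()].
#' @param flag_window half-width (percent D2O) for near-match-point flags.
#' @param M_W molar mass of the protein moiety, g/mol; NULL takes it from
#'   the protein component.
#' @param n_copies_hypothesis integer copy numbers to test when subtracting
#'   the protein contribution (NULL = scan 0..6; give a single integer to
#'   fix it).
#' @param lipid_volume_range optional low/high lipid molecular volume for
#'   [lipid_count()].
#' @param seed seed recorded in provenance (analysis itself is
#'   deterministic).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(qrg_limit = 1.3, window_policy = "qrg",
                            sign_policy = "auto", stuhrmann_model = "auto",
                            parallel_axis_model = "linear",
                            exclude_frac = 0.10,
                            exchange = exchange_model(), flag_window = 3,
                            M_W = NULL, n_copies_hypothesis = NULL,
                            lipid_volume_range = NULL,
                            seed = NULL) {
  structure(list(qrg_limit = qrg_limit, window_policy = window_policy,
                 sign_policy = sign_policy,
                 stuhrmann_model = stuhrmann_model,
                 parallel_axis_model = parallel_axis_model,
                 exclude_frac = exclude_frac, exchange = exchange,
                 flag_window = flag_window, M_W = M_W,
                 n_copies_hypothesis = n_copies_hypothesis,
                 lipid_volume_range = lipid_volume_range, seed = seed),
            class = "analysis_config")
}

#' Read a contrast-series sample sheet
#'
#' Tab-separated table, one row per contrast point, with columns `file`,
#' `d2o_pct`, `concentration` (mg/ml), `transmission`, `path_length` (cm),
#' `wavelength` (Angstrom). Curve paths are resolved relative to the sheet.
#'
#' @param path TSV file path.
#' @return data.frame with an extra `path` column of resolved curve paths.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("file", "d2o_pct", "concentration", "transmission",
            "path_length", "wavelength")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$transmission <= 0 | df$transmission > 1))
    stop("transmission must lie in (0, 1]")
  if (any(df$concentration <= 0)) stop("concentration must be > 0")
  if (any(df$path_length <= 0)) stop("path_length must be > 0")
  df$path <- file.path(dirname(path), df$file)
  df
}

component_to_spec <- function(comp) {
  cc <- comp$composition
  list(formula = paste0(names(cc$counts),
                        ifelse(abs(cc$counts - round(cc$counts)) < 1e-9,
                               as.character(round(cc$counts)),
                               sprintf("%.6g", cc$counts)), collapse = ""),
       counts = as.list(cc$counts),
       n_exchangeable_H = cc$n_exchangeable_H,
       dry_volume = comp$dry_volume,
       molar_mass = comp$molar_mass,
       role = comp$role)
}

#' Write component definitions to YAML
#' @param components named list of `sans_component`.
#' @param path output path.
#' @export
write_components_yaml <- function(components, path) {
  out <- lapply(components, component_to_spec)
  yaml::write_yaml(out, path)
}

#' Read component definitions (YAML or JSON)
#'
#' Each named entry is one of: `preset: <name>` (see [preset_component()]);
#' `formula`/`counts` with `n_exchangeable_H` and `specific_volume` or
#' `dry_volume`; or `sequences` (list of one-letter chains). A `role` field
#' may override the default.
#'
#' @param path YAML or JSON file.
#' @return named list of `sans_component`.
#' @export
read_components <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  out <- list()
  for (nm in names(spec)) {
    e <- spec[[nm]]
    comp <- if (!is.null(e$preset)) {
      preset_component(e$preset)
    } else if (!is.null(e$sequences)) {
      protein_component(unlist(e$sequences), name = nm,
                        specific_volume = e$specific_volume)
    } else {
      cc <- if (!is.null(e$counts))
        atomic_composition(unlist(e$counts),
                           if (is.null(e$n_exchangeable_H)) 0
                           else e$n_exchangeable_H)
      else parse_formula(e$formula,
                         if (is.null(e$n_exchangeable_H)) 0
                         else e$n_exchangeable_H)
      component(nm, cc,
                specific_volume = e$specific_volume,
                dry_volume = e$dry_volume,
                role = if (is.null(e$role)) "other" else e$role)
    }
    if (!is.null(e$role)) comp$role <- e$role
    out[[nm]] <- comp
  }
  out
}

pick_component <- function(components, role, name) {
  if (name %in% names(components)) return(components[[name]])
  hit <- Filter(function(x) identical(x$role, role), components)
  if (length(hit) < 1) stop("no component with role '", role, "'")
  hit[[1]]
}

#' Run the full contrast-variation analysis
#'
#' Guinier analysis of every curve, per-particle excess scattering lengths
#' from absolute-scale I(0), the contrast-variation line and complex match
#' point, oligomeric state, protein subtraction and non-protein match
#' point, protein/lipid/detergent volume fractions, lipid copy number, and
#' Stuhrmann + parallel-axis radii of gyration.
#'
#' The copy number and the non-protein match point cannot be fitted
#' simultaneously from the (two-parameter) contrast line, so the pipeline
#' subtracts the theoretical protein line for each integer copy-number
#' hypothesis, solves the lipid/detergent volumes exactly from the residual
#' line, and keeps the hypothesis whose residual is a physical mixture
#' (non-negative volumes). The reported real-valued oligomeric state is the
#' extrapolation-to-0-percent-D2O consistency estimate evaluated at the
#' resulting non-protein match point.
#'
#' @param samples path to a sample sheet (TSV) or a data.frame as returned
#'   by [read_sample_sheet()]; when `curves` is NULL they are read from the
#'   `path`/`file` column.
#' @param components path to a components file or a named list of
#'   `sans_component` containing (at least) a protein, a lipid and a
#'   detergent entry.
#' @param config an [analysis_config()].
#' @param curves optional list of [scattering_curve()] matching the sheet
#'   rows (bypasses file reading).
#' @return An object of class `analysis_report`.
#' @export
run_full <- function(samples, components, config = analysis_config(),
                     curves = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  prov_files <- character(0)
  if (is.character(samples)) {
    prov_files <- c(prov_files, samples)
    samples <- stage("samples", read_sample_sheet(samples))
  }
  if (is.character(components)) {
    prov_files <- c(prov_files, components)
    components <- stage("components", read_components(components))
  }
  if (is.null(curves)) {
    paths <- if (!is.null(samples$path)) samples$path else samples$file
    prov_files <- c(prov_files, paths)
    curves <- stage("read_curves", lapply(paths, read_curve))
  }
  if (nrow(samples) < 3) stop("[samples] need >= 3 contrast points")
  xm <- config$exchange
  protein <- pick_component(components, "protein", "protein")
  lipid <- pick_component(components, "lipid", "lipid")
  detergent <- pick_component(components, "detergent", "detergent")
  M_W <- if (is.null(config$M_W)) protein$molar_mass else config$M_W

  cmp_P <- match_point(protein, xm)
  cmp_L <- match_point(lipid, xm)
  cmp_D <- match_point(detergent, xm)

  guinier_tab <- stage("guinier", contrast_series_guinier(
    curves, d2o_pct = samples$d2o_pct,
    match_points = c(cmp_P$value, cmp_L$value, cmp_D$value),
    flag_window = config$flag_window,
    qrg_limit = config$qrg_limit, window_policy = config$window_policy))

  ## points whose Guinier fit is invalid (rising low-q slope) or whose
  ## forward intensity is not significant carry no usable |rhoV|; near the
  ## particle match point the log-intensity fit of a noise-dominated curve
  ## is biased upward, so such points are dropped from the line fit
  usable_pt <- !grepl("positive_slope|low_contrast", guinier_tab$flags)
  if (sum(usable_pt) < 3) usable_pt <- rep(TRUE, nrow(guinier_tab))

  sl <- stage("scattering_length", {
    res <- Map(function(I0, err, conc) scattering_length_from_I0(I0, err, conc, M_W),
               guinier_tab$I0, guinier_tab$I0_err, samples$concentration)
    list(rhoV = vapply(res, `[[`, numeric(1), "rhoV"),
         rhoV_err = vapply(res, `[[`, numeric(1), "rhoV_err"))
  })

  line <- stage("cv_line", fit_cv_line(samples$d2o_pct[usable_pt],
                                       sl$rhoV[usable_pt],
                                       sl$rhoV_err[usable_pt],
                                       sign_policy = config$sign_policy))

  ## The copy number and the non-protein match point cannot both be read off
  ## the (two-parameter) line simultaneously: subtract the theoretical
  ## protein line for each integer copy-number hypothesis and keep the one
  ## whose residual is a physical (non-negative) lipid/detergent mixture.
  scan <- stage("subtract_protein", {
    hyps <- if (is.null(config$n_copies_hypothesis)) 0:6
            else config$n_copies_hypothesis
    cand <- lapply(hyps, function(n) {
      np <- suppressWarnings(subtract_protein(line, protein, n, xm))
      vols <- tryCatch(
        suppressWarnings(nonprotein_volumes_from_line(
          np, lipid, detergent, xm, clamp = FALSE,
          tol_volume = 0.01 * protein$dry_volume * max(n, 1))),
        error = function(e) NULL)
      list(n = n, np_line = np, vols = vols)
    })
    ok <- Filter(function(cd) !is.null(cd$vols) && cd$vols$feasible, cand)
    if (!length(ok))
      stop("no copy-number hypothesis yields a physical lipid/detergent residual")
    score <- vapply(ok, function(cd) min(cd$vols$raw), numeric(1))
    ok[[which.max(score)]]
  })
  np_line <- scan$np_line
  vols <- suppressWarnings(
    nonprotein_volumes_from_line(np_line, lipid, detergent, xm,
                                 tol_volume = 0.01 * protein$dry_volume))
  has_nonprotein <- (vols$V_lipid + vols$V_detergent) >
    0.01 * protein$dry_volume * max(scan$n, 1)
  olig <- stage("oligomeric_state", oligomeric_state(
    line, protein,
    if (has_nonprotein) np_line$cmp else cmp_P$value - 10, xm))

  decomp <- stage("volume_fractions", {
    if (has_nonprotein) {
      ## self-consistent match points on the mixing-rule scale: the
      ## residual-line volumes fix the lipid:detergent split exactly, and
      ## the volume-weighted means feed the match-point algebra
      cmp_np_eq <- vols$cmp_nonprotein_eq
      V_P_tot <- protein$dry_volume * scan$n
      cmp_tot_eq <- mixture_match_point(
        c(cmp_P$value, cmp_L$value, cmp_D$value),
        c(V_P_tot, vols$V_lipid, vols$V_detergent))
      solve_volume_fractions(
        cmp_tot_eq, cmp_np_eq, protein,
        n_copies = scan$n, lipid = lipid, detergent = detergent,
        cmp_total_err = line$cmp_err,
        cmp_nonprotein_err = np_line$cmp_err_total,
        n_copies_err = olig$n_copies_err, xm = xm)
    } else {
      solve_volume_fractions(cmp_P$value, cmp_L$value, protein,
                             n_copies = max(scan$n, 1), lipid = lipid,
                             detergent = detergent, xm = xm)
    }
  })

  lipids <- stage("lipid_count", lipid_count(
    decomp, lipid_mol_volume = lipid$dry_volume,
    volume_range = config$lipid_volume_range))

  ## contrast coordinates from the recovered composition
  nonprotein <- if (decomp$v_L + decomp$v_D > 0)
    mixture_component(list(lipid, detergent),
                      mole_fractions = c(decomp$v_L / lipid$dry_volume,
                                         decomp$v_D / detergent$dry_volume),
                      name = "lipid/detergent")
  else NULL
  stuhr <- stage("stuhrmann", {
    dr <- mean_contrast(list(protein, lipid, detergent),
                        c(decomp$v_P, decomp$v_L, decomp$v_D),
                        samples$d2o_pct, xm)
    stuhrmann_fit(samples$d2o_pct, guinier_tab$Rg, guinier_tab$Rg_err,
                  dr$value, drho_err = (dr$high - dr$low) / 2,
                  model = config$stuhrmann_model,
                  exclude_frac = config$exclude_frac)
  })
  paxis <- stage("parallel_axis", {
    if (is.null(nonprotein)) NULL else {
      Xv <- contrast_fraction_X(protein, nonprotein,
                                decomp$V_P, decomp$V_nonprotein,
                                samples$d2o_pct, xm)
      keep <- abs(samples$d2o_pct - line$cmp) > config$flag_window
      parallel_axis_fit(Xv$value[keep], guinier_tab$Rg[keep],
                        guinier_tab$Rg_err[keep],
                        X_err = ((Xv$high - Xv$low) / 2)[keep],
                        model = config$parallel_axis_model)
    }
  })

  warnings_list <- character(0)
  if (!is.na(line$chi2_red) && line$chi2_red > 3)
    warnings_list <- c(warnings_list,
      "contrast-variation line chi2/dof > 3: possible polydispersity or composition change")
  hashes <- tryCatch(as.list(tools::md5sum(prov_files[file.exists(prov_files)])),
                     error = function(e) list())
  structure(list(
    guinier = guinier_tab,
    cv_line = line,
    nonprotein_line = np_line,
    oligomeric = olig,
    decomposition = decomp,
    lipid_count = lipids,
    stuhrmann = stuhr,
    parallel_axis = paxis,
    components = list(protein = cmp_P, lipid = cmp_L, detergent = cmp_D),
    warnings = warnings_list,
    provenance = list(package = "tricontrast",
                      version = as.character(utils::packageVersion("tricontrast")),
                      config = unclass(config)[setdiff(names(config), "exchange")],
                      exchange = unclass(config$exchange),
                      input_hashes = hashes,
                      seed = config$seed)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== contrast-variation SANS analysis ==\n")
  cat(sprintf("complex match point:      %.2f +/- %.2f %% D2O\n",
              x$cv_line$cmp, x$cv_line$cmp_err))
  cat(sprintf("non-protein match point:  %.2f +/- %.2f %% D2O\n",
              x$nonprotein_line$cmp, x$nonprotein_line$cmp_err_total))
  cat(sprintf("oligomeric state:         %.2f +/- %.2f protein copies\n",
              x$oligomeric$n_copies, x$oligomeric$n_copies_err))
  d <- x$decomposition
  cat(sprintf("volume fractions (v/v):   protein %.1f +/- %.1f%%, lipid %.1f +/- %.1f%%, detergent %.1f +/- %.1f%%\n",
              100 * d$v_P, 100 * d$v_P_err, 100 * d$v_L, 100 * d$v_L_err,
              100 * d$v_D, 100 * d$v_D_err))
  cat(sprintf("lipids per particle:      %.0f (%.0f - %.0f)\n",
              x$lipid_count$count, x$lipid_count$low, x$lipid_count$high))
  s <- x$stuhrmann
  cat(sprintf("Stuhrmann (%s):       Rc = %.1f A, alpha = %.3g (%s)\n",
              s$model, sqrt(max(s$Rc2, 0)), s$alpha,
              if (s$alpha > 0) "high-SLD component peripheral" else "high-SLD component central"))
  if (!is.null(x$parallel_axis))
    cat(sprintf("parallel axis:            Rg_protein = %.1f +/- %.2g A, Rg_nonprotein = %.1f +/- %.2g A\n",
                x$parallel_axis$Rg_P, x$parallel_axis$Rg_P_err,
                x$parallel_axis$Rg_L, x$parallel_axis$Rg_L_err))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write an analysis report to JSON and/or TSV
#'
#' The JSON file is a lossless machine-readable dump (every numeric result
#' with its error and the full provenance block); the TSV is a short
#' human-readable key/value summary with units.
#'
#' @param report an `analysis_report`.
#' @param json path for the JSON report (NULL to skip).
#' @param tsv path for the TSV summary (NULL to skip).
#' @export
write_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(json)) {
    out <- strip_classes(unclass(report))
    out$guinier <- report$guinier
    jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE, na = "null")
  }
  if (!is.null(tsv)) {
    d <- report$decomposition
    rows <- rbind(
      c("cmp_total_pct_d2o", report$cv_line$cmp, report$cv_line$cmp_err),
      c("cmp_nonprotein_pct_d2o", report$nonprotein_line$cmp,
        report$nonprotein_line$cmp_err_total),
      c("oligomeric_state_copies", report$oligomeric$n_copies,
        report$oligomeric$n_copies_err),
      c("protein_fraction_vv", d$v_P, d$v_P_err),
      c("lipid_fraction_vv", d$v_L, d$v_L_err),
      c("detergent_fraction_vv", d$v_D, d$v_D_err),
      c("particle_volume_A3", d$V_total, d$V_total_err),
      c("lipids_per_particle", report$lipid_count$count, NA),
      c("stuhrmann_alpha", report$stuhrmann$alpha, report$stuhrmann$alpha_err),
      c("Rc_infinite_contrast_A", sqrt(max(report$stuhrmann$Rc2, 0)), NA),
      if (!is.null(report$parallel_axis))
        rbind(c("Rg_protein_A", report$parallel_axis$Rg_P,
                report$parallel_axis$Rg_P_err),
              c("Rg_nonprotein_A", report$parallel_axis$Rg_L,
                report$parallel_axis$Rg_L_err)))
    df <- data.frame(quantity = rows[, 1],
                     value = as.numeric(rows[, 2]),
                     error = as.numeric(rows[, 3]))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
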