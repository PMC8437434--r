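.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

.settings_from_config <- function(config) {
  f <- config$fit
  fit_settings(max_iterations = f$max_iterations %||% 80L,
               pop_size = f$pop_size,
               rng_seed = f$rng_seed %||% 1L,
               tolerance = f$tolerance %||% 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full chaperone-kinetics analysis from a config
#'
#' Executes the enabled stages in dependency order: trace preparation
#' (baseline subtraction optional, binning, signal-to-mass conversion,
#' half-times and scaling exponent), the unseeded global fit, the seeded
#' global fit, the per-chaperone mechanism fits with hypothesis ranking, and
#' independently the DLS seed sizing and the binding analyses. All outputs
#' and a provenance-stamped report are written under `config$out_dir`.
#'
#' Config fields (JSON file or R list): `inputs` (paths: `unseeded_csv`,
#' optional `seeded_csv`, `chaperone_csvs` named list, `dls_csv`,
#' `titration_csvs` named list, `nmr_csv`), `stages` (character vector among
#' `prep`, `baseline_fit`, `seeded_fit`, `chaperone_fit`, `seed_sizing`,
#' `binding`), `fit` (`max_iterations`, `pop_size`, `rng_seed`,
#' `tolerance`), `prep` (`bin_size`, `plateau_fraction`), `instrument`
#' (`lambda0_m`, `theta_deg`, `n`, `T_K`, `eta_Pas`), `seed_geometry`
#' (`b_nm`, `spacing_nm`), `out_dir`.
#'
#' @param config Path to a JSON config or an equivalent named list.
#' @return The run report (list), invisibly; also written to
#'   `out_dir/report.json`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$out_dir))
  stages <- config$stages %||% c("prep", "baseline_fit", "seeded_fit",
                                 "chaperone_fit", "seed_sizing", "binding")
  on_stage <- function(s) s %in% stages
  # dependency check before any computation
  if (on_stage("seeded_fit") && !on_stage("baseline_fit"))
    stop("stage 'seeded_fit' requires 'baseline_fit'", call. = FALSE)
  if (on_stage("chaperone_fit") &&
      !(on_stage("baseline_fit") && on_stage("seeded_fit")))
    stop("stage 'chaperone_fit' requires 'baseline_fit' and 'seeded_fit'",
         call. = FALSE)
  needed <- c(if (on_stage("prep") || on_stage("baseline_fit"))
                config$inputs$unseeded_csv,
              if (on_stage("seeded_fit")) config$inputs$seeded_csv,
              if (on_stage("chaperone_fit"))
                unlist(config$inputs$chaperone_csvs),
              if (on_stage("seed_sizing")) config$inputs$dls_csv,
              if (on_stage("binding"))
                c(unlist(config$inputs$titration_csvs), config$inputs$nmr_csv))
  missing <- needed[!file.exists(needed)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- .settings_from_config(config)
  bin_size <- config$prep$bin_size %||% 2L
  report <- list(provenance = list(
    config_hash = .config_hash(config), rng_seed = settings$rng_seed,
    package_version = as.character(utils::packageVersion("tauchaperone")),
    stages = stages))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  load_mass <- function(path) {
    traces <- read_traces_csv(path)
    if (inherits(traces[[1]], "raw_trace")) {
      traces <- signal_to_mass(traces)
    }
    lapply(traces, bin_trace, bin_size = bin_size)
  }

  unseeded <- NULL
  if (on_stage("prep") || on_stage("baseline_fit")) {
    t0 <- tic()
    unseeded <- load_mass(config$inputs$unseeded_csv)
    ht <- list()
    warnings_prep <- character(0)
    for (tr in unseeded) {
      h <- try(extract_half_time(
        tr, plateau_fraction = config$prep$plateau_fraction %||% 0.1),
        silent = TRUE)
      if (inherits(h, "try-error")) {
        warnings_prep <- c(warnings_prep, sprintf(
          "unsaturated trace excluded from half-time analysis (m0=%g uM)",
          tr$condition$m0))
      } else {
        ht[[length(ht) + 1L]] <- data.frame(m0 = tr$condition$m0,
                                            t_half = h$t_half)
      }
    }
    ht <- do.call(rbind, ht)
    scaling <- if (!is.null(ht) && length(unique(ht$m0)) >= 3L)
      fit_scaling_exponent(ht) else NULL
    utils::write.csv(ht, file.path(config$out_dir, "half_times.csv"),
                     row.names = FALSE)
    report$prep <- list(n_traces = length(unseeded), half_times = ht,
                        scaling = scaling, warnings = warnings_prep)
    timings["prep"] <- tic() - t0
  }

  baseline_fit <- NULL
  if (on_stage("baseline_fit")) {
    t0 <- tic()
    baseline_fit <- fit_unseeded_global(kinetic_dataset(unseeded),
                                        settings = settings)
    report$baseline_fit <- list(
      kn_prime = baseline_fit$rates$kn_prime,
      km_prime = baseline_fit$rates$km_prime,
      KE_uM = baseline_fit$rates$KE, rmse_uM = baseline_fit$rmse,
      converged = baseline_fit$converged)
    timings["baseline_fit"] <- tic() - t0
  }

  seed_sizing <- NULL
  if (on_stage("seed_sizing")) {
    t0 <- tic()
    dls <- utils::read.csv(config$inputs$dls_csv)
    curve <- autocorrelation_curve(dls$lag_s, dls$g2)
    inst <- instrument_params(
      lambda0 = config$instrument$lambda0_m,
      theta = config$instrument$theta_deg,
      n = config$instrument$n %||% 1.334,
      T = config$instrument$T_K %||% 298,
      eta = config$instrument$eta_Pas %||% 0.89e-3)
    seed_sizing <- dls_seed_length(curve, inst,
                                   b = config$seed_geometry$b_nm %||% 10,
                                   spacing =
                                     config$seed_geometry$spacing_nm %||% 2)
    report$seed_sizing <- seed_sizing
    timings["seed_sizing"] <- tic() - t0
  }

  absolute <- NULL
  if (on_stage("seeded_fit")) {
    t0 <- tic()
    seeded <- load_mass(config$inputs$seeded_csv)
    L <- if (!is.null(seed_sizing)) seed_sizing$L_monomers
         else config$seed_geometry$L_monomers %||% 100
    absolute <- fit_seeded_global(kinetic_dataset(c(unseeded, seeded)),
                                  baseline_fit$rates, L = L,
                                  settings = settings)
    report$seeded_fit <- list(kn = absolute$rates$kn, kp = absolute$rates$kp,
                              km = absolute$rates$km, KE = absolute$rates$KE,
                              L = L, rmse_uM = absolute$rmse)
    timings["seeded_fit"] <- tic() - t0
  }

  if (on_stage("chaperone_fit")) {
    t0 <- tic()
    report$chaperone_fit <- list()
    for (chap in names(config$inputs$chaperone_csvs)) {
      traces <- load_mass(config$inputs$chaperone_csvs[[chap]])
      ds <- kinetic_dataset(traces)
      L <- report$seeded_fit$L
      eff_kn <- fit_chaperone_single_rate(ds, absolute$rates, "kn", L = L,
                                          settings = settings)
      eff_kp <- fit_chaperone_single_rate(ds, absolute$rates, "kp", L = L,
                                          settings = settings)
      effs <- list(eff_kn, eff_kp)
      has_seeded <- any(vapply(traces, function(tr) tr$condition$seeded,
                               TRUE))
      if (has_seeded)
        effs <- c(effs, list(fit_chaperone_joint(ds, absolute$rates, L = L,
                                                 settings = settings)))
      ranking <- compare_rate_hypotheses(effs)
      report$chaperone_fit[[chap]] <- list(
        ranking = ranking,
        effects = lapply(effs, function(e)
          list(hypothesis = e$hypothesis, table = e$effects)))
      utils::write.csv(ranking,
                       file.path(config$out_dir,
                                 paste0("hypotheses_", chap, ".csv")),
                       row.names = FALSE)
    }
    timings["chaperone_fit"] <- tic() - t0
  }

  if (on_stage("binding")) {
    t0 <- tic()
    binding <- list()
    for (nm in names(config$inputs$titration_csvs)) {
      tt <- utils::read.csv(config$inputs$titration_csvs[[nm]])
      fit <- fit_one_site(titration_curve(tt$conc_uM, tt$anisotropy))
      binding[[nm]] <- fit[c("KD", "KD_stderr", "identifiable", "rmse")]
    }
    nmr <- utils::read.csv(config$inputs$nmr_csv)
    pt <- peak_table(nmr$residue, nmr$ddH_ppm, nmr$ddN_ppm, nmr$I, nmr$I0)
    profile <- intensity_ratio_profile(pt)
    regions <- call_binding_regions(profile)
    csp <- compute_csp(pt)
    csp$significant <- flag_significant_csp(csp)
    utils::write.csv(merge(profile, csp, by = "residue", all = TRUE),
                     file.path(config$out_dir, "binding_profile.csv"),
                     row.names = FALSE)
    report$binding <- list(titrations = binding, regions = regions)
    timings["binding"] <- tic() - t0
  }

  report$timings_s <- as.list(timings)
  jsonlite::write_json(.unclass_deep(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", force = TRUE)
  invisible(report)
}

#' Emit a complete synthetic demo bundle
#'
#' Writes a self-contained synthetic dataset (chaperone-free concentration
#' series, seeded series, three chaperone dose series with distinct
#' ground-truth mechanisms, a DLS autocorrelation curve, anisotropy
#' titrations, an NMR peak table), the generating truth, and a ready-to-run
#' JSON config for [run_analysis()].
#'
#' @param seed Integer RNG seed for all generators.
#' @param out_dir Output directory (created if absent).
#' @param replicates Replicates per kinetic condition.
#' @param optimizer_budget Differential-evolution generations recorded in
#'   the emitted config.
#' @return Path of the config file, invisibly.
#' @export
demo_bundle <- function(seed, out_dir, replicates = 3L,
                        optimizer_budget = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path
  base <- default_baseline_params()
  ns <- function(off) noise_spec(0.01, "relative", rng_seed = seed + off)

  unseeded <- generate_aggregation_dataset(
    scenario_spec(baseline = base, replicates = replicates), ns(0))
  write_traces_csv(unseeded$traces, p(out_dir, "unseeded.csv"))

  seeded <- generate_aggregation_dataset(
    scenario_spec(baseline = base, m0_series = 10,
                  seed_spec = list(M0 = 1, L = 100),
                  sampling = list(dt = 2, duration = 400),
                  replicates = replicates), ns(1))
  seeded_only <- kinetic_dataset(Filter(function(tr) tr$condition$seeded,
                                        seeded$traces))
  write_traces_csv(seeded_only$traces, p(out_dir, "seeded.csv"))

  # three dose series with distinct ground-truth mechanisms
  doses <- c(0, 1, 2.5, 5)
  mech <- list(
    HSPB1 = data.frame(chaperone_uM = doses, fn = 1,
                       fp = c(1, 0.5, 0.2, 0.1), fm = 1),
    DNAJB1 = data.frame(chaperone_uM = doses, fn = c(1, 0.3, 0.1, 0.03),
                        fp = 1, fm = 1),
    DNAJA2 = data.frame(chaperone_uM = doses, fn = c(1, 0.4, 0.25, 0.2),
                        fp = c(1, 0.6, 0.4, 0.3), fm = 1))
  chaperone_csvs <- list()
  truth_effects <- list()
  for (i in seq_along(mech)) {
    chap <- names(mech)[i]
    ds <- generate_aggregation_dataset(
      scenario_spec(baseline = base, chaperone = chap,
                    chaperone_effects = mech[[i]],
                    seed_spec = if (chap == "DNAJA2")
                      list(M0 = 1, L = 100) else NULL,
                    sampling = list(dt = 5, duration = 2000),
                    replicates = replicates), ns(10 + i))
    f <- p(out_dir, paste0("chaperone_", chap, ".csv"))
    write_traces_csv(ds$traces, f)
    chaperone_csvs[[chap]] <- f
    truth_effects[[chap]] <- mech[[i]]
  }

  inst <- list(lambda0_m = 633e-9, theta_deg = 158, n = 1.334, T_K = 298,
               eta_Pas = 0.89e-3)
  q <- scattering_vector(instrument_params(inst$lambda0_m, inst$theta_deg,
                                           inst$n, inst$T_K, inst$eta_Pas))
  D_true <- diffusion_from_radius(55e-9, inst$T_K, inst$eta_Pas)
  curve <- generate_autocorrelation(beta = 0.9, D = D_true, q = q,
                                    noise = noise_spec(0.01, "relative",
                                                       seed + 20))
  utils::write.csv(data.frame(lag_s = curve$lags, g2 = curve$g2),
                   p(out_dir, "dls.csv"), row.names = FALSE)

  kds <- c(DNAJB1_fiber = 1.7, DNAJA2_fiber = 7.6, DNAJA2_monomer = 43)
  titration_csvs <- list()
  for (i in seq_along(kds)) {
    tc <- generate_titration(kds[[i]],
                             noise = noise_spec(0.02, "relative",
                                                seed + 30 + i))
    f <- p(out_dir, paste0("titration_", names(kds)[i], ".csv"))
    utils::write.csv(data.frame(conc_uM = tc$ligand_conc,
                                anisotropy = tc$anisotropy),
                     f, row.names = FALSE)
    titration_csvs[[names(kds)[i]]] <- f
  }

  nmr <- generate_nmr_table(noise = noise_spec(0.02, "relative", seed + 40))
  utils::write.csv(data.frame(residue = nmr$residue, ddH_ppm = nmr$delta_H,
                              ddN_ppm = nmr$delta_N, I = nmr$I, I0 = nmr$I0),
                   p(out_dir, "nmr_peaks.csv"), row.names = FALSE)

  truth <- list(baseline = unclass(base),
                kn_prime = base$kn * base$kp, km_prime = base$km * base$kp,
                seed = list(M0_uM = 1, L = 100, Rs_nm = 55, b_nm = 10),
                chaperone_effects = truth_effects, KDs_uM = as.list(kds),
                dls = list(beta = 0.9, D_m2s = D_true),
                nmr_footprints = list(c(275, 280), c(306, 311)))
  jsonlite::write_json(truth, p(out_dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)

  config <- list(
    inputs = list(unseeded_csv = p(out_dir, "unseeded.csv"),
                  seeded_csv = p(out_dir, "seeded.csv"),
                  chaperone_csvs = chaperone_csvs,
                  dls_csv = p(out_dir, "dls.csv"),
                  titration_csvs = titration_csvs,
                  nmr_csv = p(out_dir, "nmr_peaks.csv")),
    stages = c("prep", "baseline_fit", "seeded_fit", "chaperone_fit",
               "seed_sizing", "binding"),
    fit = list(max_iterations = optimizer_budget, rng_seed = seed),
    prep = list(bin_size = 2, plateau_fraction = 0.1),
    instrument = inst,
    seed_geometry = list(b_nm = 10, spacing_nm = 2),
    out_dir = p(out_dir, "results"))
  cfg_path <- p(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}
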