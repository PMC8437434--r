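#' Noise specification for synthetic data
#'
#' Independent additive Gaussian noise per point. `"relative"` scales sigma
#' by the trace amplitude (total tau mass for kinetic traces);
#' `"heteroscedastic"` scales it by the instantaneous signal, for robustness
#' checks. Identical seed and spec always reproduce the same draw.
#'
#' @param sigma Noise level: absolute units, or a fraction for the relative
#'   kinds. Instrument noise of 1-2 percent of the signal amplitude is
#'   typical of plate readers.
#' @param kind `"absolute"`, `"relative"` or `"heteroscedastic"`.
#' @param rng_seed Integer seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(sigma = 0.01, kind = c("relative", "absolute",
                                              "heteroscedastic"),
                       rng_seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), sigma >= 0)
  structure(list(sigma = sigma, kind = kind,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

.add_noise <- function(values, noise, amplitude) {
  if (noise$sigma == 0) return(values)
  sd <- switch(noise$kind,
               absolute = rep(noise$sigma, length(values)),
               relative = rep(noise$sigma * amplitude, length(values)),
               heteroscedastic = noise$sigma * pmax(abs(values),
                                                    0.01 * amplitude))
  values + stats::rnorm(length(values), 0, sd)
}

#' Default baseline kinetics of tau aggregation
#'
#' The generator's reference parameter set: `kn = 1.64e-8` uM^-1 min^-1,
#' `kp = 50` uM^-1 min^-1, `km = 8.2e-6` min^-1, `KE = 2` uM, `nc = 2`
#' (composites `k'n = kn * kp = 8.2e-7`, `k'm = km * kp = 4.1e-4`).
#' Calibrated once so that the simulated chaperone-free system reproduces
#' the observed behavior of heparin-induced tau aggregation: a half-time
#' near 110 min at 10 uM monomer, a shallow half-time concentration scaling
#' (exponent about -0.34 over 2.5-40 uM, the signature of primary
#' nucleation with a fragmentation contribution) and positive curvature of
#' the double-logarithmic half-time plot (elongation saturation).
#'
#' @return A [kinetic_parameters()] object.
#' @export
default_baseline_params <- function() {
  kinetic_parameters(kn = 1.64e-8, kp = 50, km = 8.2e-6, KE = 2, nc = 2L)
}

#' Scenario specification for synthetic aggregation datasets
#'
#' Encodes the study design the generator emulates: an unseeded monomer
#' concentration series (2.5-40 uM) for the chaperone-free baseline, or a
#' chaperone dose series (0-10 uM chaperone against 10 uM tau) in which
#' chosen microscopic rates are scaled down, optionally with seeded
#' companions of known seed mass and length.
#'
#' @param baseline [kinetic_parameters()] of the chaperone-free system.
#' @param m0_series Monomer concentrations, uM (chaperone-free series).
#' @param chaperone Chaperone name, or `"none"` for the baseline series.
#' @param chaperone_effects data.frame with columns `chaperone_uM`, `fn`,
#'   `fp`, `fm`: per-concentration scale factors on kn, kp, km. Must include
#'   the 0 uM row with unit factors.
#' @param dose_m0 Monomer concentration of the dose series, uM (10 in the
#'   assay design).
#' @param seed_spec `NULL`, or `list(M0 = , L = )` to add seeded traces
#'   (seed mass in uM, length in monomers).
#' @param sampling `list(dt = , duration = )` in minutes.
#' @param replicates Replicates per condition.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(baseline = default_baseline_params(),
                          m0_series = c(2.5, 5, 10, 20, 40),
                          chaperone = "none",
                          chaperone_effects = data.frame(
                            chaperone_uM = 0, fn = 1, fp = 1, fm = 1),
                          dose_m0 = 10,
                          seed_spec = NULL,
                          sampling = list(dt = 5, duration = 2000),
                          replicates = 3L) {
  stopifnot(inherits(baseline, "kinetic_parameters"),
            all(m0_series > 0), dose_m0 > 0, replicates >= 1,
            is.data.frame(chaperone_effects),
            all(c("chaperone_uM", "fn", "fp", "fm") %in%
                  names(chaperone_effects)))
  if (any(chaperone_effects[, c("fn", "fp", "fm")] <= 0))
    stop("rate scale factors must be > 0", call. = FALSE)
  if (chaperone != "none") {
    z <- chaperone_effects[chaperone_effects$chaperone_uM == 0, ]
    if (nrow(z) == 0L || any(abs(unlist(z[, c("fn", "fp", "fm")]) - 1) > 0))
      stop("chaperone_effects must include the 0 uM row with unit factors",
           call. = FALSE)
  }
  if (!is.null(seed_spec))
    stopifnot(seed_spec$M0 > 0, seed_spec$L >= 1)
  structure(list(baseline = baseline, m0_series = m0_series,
                 chaperone = chaperone,
                 chaperone_effects = chaperone_effects, dose_m0 = dose_m0,
                 seed_spec = seed_spec, sampling = sampling,
                 replicates = as.integer(replicates)),
            class = "scenario_spec")
}

.scaled_params <- function(baseline, fn, fp, fm) {
  kinetic_parameters(kn = baseline$kn * fn, kp = baseline$kp * fp,
                     km = baseline$km * fm, KE = baseline$KE,
                     nc = baseline$nc)
}

#' Generate a synthetic aggregation dataset
#'
#' Simulates every condition of the scenario with the kinetic model (rates
#' scaled per the chaperone effects), adds noise, and returns the traces
#' together with the generating ground truth for recovery tests. With
#' `as_raw = TRUE` the fibril mass is converted back to a ThT signal
#' (`S = M * Smax_inf / mmax`, the inverse of the signal-to-mass anchor) so
#' the raw-trace readers and converters can be exercised end to end.
#'
#' @param spec [scenario_spec()].
#' @param noise [noise_spec()].
#' @param as_raw Emit [raw_trace()] objects instead of [mass_trace()].
#' @param Smax_inf Plateau signal used for the raw-signal emission, a.u.
#' @return A [kinetic_dataset()]; the attribute `"truth"` records the
#'   generating parameters, per-concentration factors, seed geometry, noise
#'   spec and conditions flagged unsaturated by design.
#' @export
generate_aggregation_dataset <- function(spec, noise = noise_spec(),
                                         as_raw = FALSE, Smax_inf = 1000) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(noise, "noise_spec"))
  times <- seq(0, spec$sampling$duration, by = spec$sampling$dt)
  conditions <- list()
  if (spec$chaperone == "none") {
    for (m0 in spec$m0_series)
      conditions[[length(conditions) + 1L]] <-
        list(m0 = m0, conc = 0, fn = 1, fp = 1, fm = 1, seeded = FALSE)
  } else {
    for (i in seq_len(nrow(spec$chaperone_effects))) {
      e <- spec$chaperone_effects[i, ]
      conditions[[length(conditions) + 1L]] <-
        list(m0 = spec$dose_m0, conc = e$chaperone_uM, fn = e$fn,
             fp = e$fp, fm = e$fm, seeded = FALSE)
    }
  }
  if (!is.null(spec$seed_spec)) {
    for (cond in conditions[vapply(conditions, function(x) !x$seeded, TRUE)])
      conditions[[length(conditions) + 1L]] <-
        utils::modifyList(cond, list(seeded = TRUE))
  }
  mmax <- max(vapply(conditions, `[[`, numeric(1), "m0"))
  traces <- list()
  unsaturated <- character(0)
  withr::with_seed(noise$rng_seed, {
    for (cond in conditions) {
      params <- .scaled_params(spec$baseline, cond$fn, cond$fp, cond$fm)
      init <- if (cond$seeded)
        seeded_initial_conditions(spec$seed_spec$M0, spec$seed_spec$L,
                                  cond$m0)
      else initial_conditions(cond$m0)
      sim <- simulate_mass_curve(params, init, times)
      total <- cond$m0 + init$M0
      if (sim$M_uM[length(times)] < 0.95 * total)
        unsaturated <- c(unsaturated,
                         sprintf("m0=%g chap=%g seeded=%d", cond$m0,
                                 cond$conc, cond$seeded))
      for (rep_i in seq_len(spec$replicates)) {
        M <- pmax(0, .add_noise(sim$M_uM, noise, total))
        tc <- trace_condition(m0 = cond$m0, chaperone = spec$chaperone,
                              chaperone_conc = cond$conc,
                              seeded = cond$seeded,
                              seed_mass = init$M0, replicate = rep_i)
        traces[[length(traces) + 1L]] <- if (as_raw)
          raw_trace(times, M * Smax_inf / mmax, tc)
        else suppressWarnings(mass_trace(times, M, tc))
      }
    }
  })
  ds <- kinetic_dataset(traces,
                        replicate_sets = vapply(traces, function(tr)
                          tr$condition$replicate, FUN.VALUE = 1L))
  attr(ds, "truth") <- list(
    baseline = unclass(spec$baseline),
    kn_prime = spec$baseline$kn * spec$baseline$kp,
    km_prime = spec$baseline$km * spec$baseline$kp,
    chaperone = spec$chaperone,
    chaperone_effects = spec$chaperone_effects,
    seed_spec = spec$seed_spec, noise = unclass(noise),
    Smax_inf = if (as_raw) Smax_inf else NULL, mmax = mmax,
    unsaturated_by_design = unsaturated)
  ds
}

#' Generate a one-site binding titration
#'
#' @param KD Dissociation constant, uM (the assay suite spans about 1.7 to
#'   250 uM).
#' @param r_free,r_bound Anisotropy of the free and saturated species.
#' @param conc_grid Titrant concentrations, uM.
#' @param noise [noise_spec()]; relative noise scales with the amplitude
#'   `r_bound - r_free`.
#' @param labeled_conc Labeled-species concentration, uM.
#' @return A [titration_curve()] with attribute `"truth"`.
#' @export
generate_titration <- function(KD, r_free = 0.05, r_bound = 0.20,
                               conc_grid = c(0, 0.25, 0.5, 1, 2, 5, 10, 20,
                                             35, 50),
                               noise = noise_spec(0.02), labeled_conc = 0.1) {
  stopifnot(KD > 0)
  r <- r_free + (r_bound - r_free) * conc_grid / (KD + conc_grid)
  r <- withr::with_seed(noise$rng_seed,
                        .add_noise(r, noise, abs(r_bound - r_free)))
  out <- titration_curve(conc_grid, r, labeled_conc)
  attr(out, "truth") <- list(KD = KD, r_free = r_free, r_bound = r_bound,
                             noise = unclass(noise))
  out
}

#' Generate a DLS autocorrelation curve
#'
#' Single-exponential model `g2 = 1 + beta * exp(-2 D q^2 tau)` with
#' additive noise, averaged over `replicates` independent acquisitions
#' (20 acquisitions per well in the assay design).
#'
#' @param beta Coherence factor in (0, 1].
#' @param D Diffusion coefficient, m^2/s.
#' @param q Scattering vector, m^-1.
#' @param lag_grid Lag times, s.
#' @param noise [noise_spec()]; relative noise scales with `beta`.
#' @param replicates Acquisitions averaged.
#' @return An [autocorrelation_curve()] with attribute `"truth"`.
#' @export
generate_autocorrelation <- function(beta, D, q,
                                     lag_grid = 10^seq(-5, 0, length.out = 60),
                                     noise = noise_spec(0.01),
                                     replicates = 20L) {
  stopifnot(beta > 0, beta <= 1, D > 0, q > 0, replicates >= 1)
  model <- 1 + beta * exp(-2 * D * q^2 * lag_grid)
  g2 <- withr::with_seed(noise$rng_seed, {
    acq <- replicate(replicates, .add_noise(model, noise, beta))
    rowMeans(matrix(acq, nrow = length(lag_grid)))
  })
  out <- autocorrelation_curve(lag_grid, g2,
                               replicates_averaged = replicates)
  attr(out, "truth") <- list(beta = beta, D = D, q = q,
                             noise = unclass(noise))
  out
}

#' Generate a per-residue NMR peak table
#'
#' Emulates an HSQC peak table for the tau four-repeat construct (residues
#' 244-372 by default): intensity ratios near 1 with noise everywhere except
#' over rectangular binding footprints, which are attenuated to a stated
#' depth. By default the footprints are the two aggregation-driving
#' hexapeptide motifs, residues 275-280 (VQIINK) and 306-311 (VQIVYK). Shift
#' differences follow the same footprint structure so CSP mapping can be
#' exercised on the same table.
#'
#' @param residues Integer residue numbers.
#' @param footprints List of `list(interval = c(start, end), depth = )`
#'   entries; `depth` is the attenuated I/I0 ratio inside the footprint.
#' @param csp_spec `list(base_H, base_N, footprint_H, footprint_N)`: Gaussian
#'   scales (ppm) of the background and footprint shift differences.
#' @param noise [noise_spec()] for the intensity ratios.
#' @param I0 Free-state intensity, a.u.
#' @return A [peak_table()] with attribute `"truth"`.
#' @export
generate_nmr_table <- function(residues = 244:372,
                               footprints = list(
                                 list(interval = c(275, 280), depth = 0.3),
                                 list(interval = c(306, 311), depth = 0.3)),
                               csp_spec = list(base_H = 0.003, base_N = 0.015,
                                               footprint_H = 0.05,
                                               footprint_N = 0.25),
                               noise = noise_spec(0.02), I0 = 1000) {
  stopifnot(length(residues) >= 5L)
  for (fp in footprints)
    if (fp$interval[1] < min(residues) || fp$interval[2] > max(residues))
      stop("footprint outside the residue range", call. = FALSE)
  n <- length(residues)
  in_fp <- rep(FALSE, n)
  ratio <- rep(1, n)
  for (fp in footprints) {
    idx <- residues >= fp$interval[1] & residues <= fp$interval[2]
    in_fp <- in_fp | idx
    ratio[idx] <- fp$depth
  }
  tab <- withr::with_seed(noise$rng_seed, {
    r <- pmax(0, .add_noise(ratio, noise, 1))
    dH <- abs(stats::rnorm(n, 0, csp_spec$base_H))
    dN <- abs(stats::rnorm(n, 0, csp_spec$base_N))
    dH[in_fp] <- csp_spec$footprint_H *
      (1 + 0.1 * stats::rnorm(sum(in_fp)))
    dN[in_fp] <- csp_spec$footprint_N *
      (1 + 0.1 * stats::rnorm(sum(in_fp)))
    peak_table(residues, delta_H = dH, delta_N = dN,
               I = r * I0, I0 = I0)
  })
  attr(tab, "truth") <- list(footprints = footprints, csp_spec = csp_spec,
                             noise = unclass(noise))
  tab
}
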