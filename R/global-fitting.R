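#' Settings shared by all kinetic fits
#'
#' Fits search log10 parameter space within finite positive bounds, using a
#' differential-evolution-style global search when two or more parameters are
#' free and a deterministic golden-section scan for single-parameter refits.
#'
#' @param bounds Named list of `c(lower, upper)` intervals on the natural
#'   scale (positive, finite); entries override the per-fit defaults.
#' @param max_iterations Maximum optimizer generations.
#' @param pop_size Differential-evolution population size (`NULL` = 10 per
#'   free dimension, minimum 15).
#' @param rng_seed Integer seed recorded in every report; with a fixed seed
#'   every fit is bit-reproducible.
#' @param tolerance Convergence tolerance on the objective spread.
#' @return A `fit_settings` object.
#' @export
fit_settings <- function(bounds = list(), max_iterations = 100L,
                         pop_size = NULL, rng_seed = 1L, tolerance = 1e-9) {
  stopifnot(is.list(bounds), max_iterations >= 1)
  for (b in bounds)
    if (length(b) != 2L || any(!is.finite(b)) || any(b <= 0) || b[1] >= b[2])
      stop("each bound must be a finite positive c(lower, upper)",
           call. = FALSE)
  structure(list(bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 pop_size = pop_size, rng_seed = as.integer(rng_seed),
                 tolerance = tolerance),
            class = "fit_settings")
}

#' Reduced (composite) rates from an unseeded fit
#'
#' Unseeded fibril-mass data determine only the products `k'n = kn * kp` and
#' `k'm = km * kp` together with `KE`; `kp` itself is unidentifiable and is
#' fixed at 1 during the unseeded global fit.
#'
#' @param kn_prime Composite nucleation rate `kn * kp`.
#' @param km_prime Composite fragmentation rate `km * kp`.
#' @param KE Elongation saturation constant, uM.
#' @return A `reduced_rates` object.
#' @export
reduced_rates <- function(kn_prime, km_prime, KE) {
  stopifnot(kn_prime >= 0, km_prime >= 0, KE > 0)
  structure(list(kn_prime = kn_prime, km_prime = km_prime, KE = KE),
            class = "reduced_rates")
}

#' @export
print.reduced_rates <- function(x, ...) {
  cat("Reduced rates (kp = 1 convention):\n")
  cat(sprintf("  k'n = kn*kp = %g\n  k'm = km*kp = %g\n  KE  = %g uM\n",
              x$kn_prime, x$km_prime, x$KE))
  invisible(x)
}

.bound_or <- function(settings, name, default) {
  b <- settings$bounds[[name]]
  if (is.null(b)) default else b
}

# Sum of squared residuals of simulated fibril mass against a set of traces.
# Traces sharing initial conditions and time grid are simulated once.
.traces_ssr <- function(traces, param_fn) {
  keys <- vapply(traces, function(tr) {
    cond <- tr$condition
    paste(cond$m0, cond$seeded, cond$seed_mass,
          paste(range(tr$times), length(tr$times), collapse = ","),
          sep = "|")
  }, "")
  ssr <- 0
  npts <- 0L
  for (key in unique(keys)) {
    members <- traces[keys == key]
    tr0 <- members[[1]]
    pr <- param_fn(tr0$condition)
    sim <- try(simulate_mass_curve(pr$params, pr$init, tr0$times),
               silent = TRUE)
    if (inherits(sim, "try-error")) return(list(ssr = Inf, n = 0L))
    for (tr in members) {
      ssr <- ssr + sum((sim$M_uM - tr$M)^2)
      npts <- npts + length(tr$M)
    }
  }
  list(ssr = ssr, n = npts)
}

.check_mass_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (!all(vapply(dataset$traces, inherits, TRUE, "mass_trace")))
    stop("fit requires mass traces; run signal_to_mass() first",
         call. = FALSE)
}

#' Global fit of unseeded aggregation kinetics (step one)
#'
#' Fits the reduced rates `(k'n, k'm, KE)` to all unseeded traces
#' simultaneously with `kp` fixed at 1, minimizing the unweighted sum of
#' squared mass residuals over every point of every trace. The amplitude of
#' each trace is not a free parameter: it is fixed by that trace's monomer
#' concentration through mass conservation.
#'
#' @param dataset [kinetic_dataset()] of unseeded [mass_trace()] objects at
#'   three or more distinct monomer concentrations.
#' @param nc Critical nucleus size (fixed, default 2).
#' @param settings [fit_settings()]. Default search bounds (overridable via
#'   `bounds`): `kn_prime` and `km_prime` in `[1e-8, 1e-2]`, `KE` in
#'   `[0.1, 1e3]` uM — six decades around the coarse mid-range
#'   initialization.
#' @return List with `rates` ([reduced_rates()]), `rmse` (uM), `n_points`,
#'   `settings`, `converged`.
#' @export
fit_unseeded_global <- function(dataset, nc = 2L, settings = fit_settings()) {
  .check_mass_dataset(dataset)
  traces <- dataset$traces
  if (any(vapply(traces, function(tr) tr$condition$seeded, TRUE)))
    stop("fit_unseeded_global expects unseeded traces only", call. = FALSE)
  m0s <- vapply(traces, function(tr) tr$condition$m0, numeric(1))
  if (length(unique(m0s)) < 3L)
    stop("underdetermined: need >= 3 distinct monomer concentrations",
         call. = FALSE)
  lb <- log10(c(.bound_or(settings, "kn_prime", c(1e-8, 1e-2))[1],
                .bound_or(settings, "km_prime", c(1e-8, 1e-2))[1],
                .bound_or(settings, "KE", c(0.1, 1e3))[1]))
  ub <- log10(c(.bound_or(settings, "kn_prime", c(1e-8, 1e-2))[2],
                .bound_or(settings, "km_prime", c(1e-8, 1e-2))[2],
                .bound_or(settings, "KE", c(0.1, 1e3))[2]))
  obj <- function(theta) {
    p <- 10^theta
    params <- kinetic_parameters(kn = p[1], kp = 1, km = p[2], KE = p[3],
                                 nc = nc)
    .traces_ssr(traces, function(cond)
      list(params = params, init = initial_conditions(cond$m0)))$ssr
  }
  res <- withr::with_seed(settings$rng_seed,
    .de_optimize(obj, lb, ub, pop_size = settings$pop_size,
                 max_iter = settings$max_iterations,
                 tol = settings$tolerance))
  if (!is.finite(res$value))
    stop("unseeded global fit failed to converge; best objective non-finite",
         call. = FALSE)
  p <- 10^res$par
  n <- sum(vapply(traces, function(tr) length(tr$M), integer(1)))
  list(rates = reduced_rates(kn_prime = p[1], km_prime = p[2], KE = p[3]),
       rmse = sqrt(res$value / n), n_points = n, nc = as.integer(nc),
       settings = settings, converged = res$converged)
}

#' Global fit of seeded kinetics for the absolute elongation rate (step two)
#'
#' Seeding with preformed fibrils of known length breaks the unseeded
#' degeneracy: with the composites `k'n` and `k'm` held at their step-one
#' values, the seeded traces determine `kp` (and hence `kn = k'n / kp`,
#' `km = k'm / kp`). Initial conditions per trace are `M(0) = M0` and
#' `P(0) = M0 / L`.
#'
#' @param dataset [kinetic_dataset()] containing seeded [mass_trace()]
#'   objects (unseeded companions may be present and are included in the
#'   objective).
#' @param reduced [reduced_rates()] from [fit_unseeded_global()].
#' @param L Seed length in monomers (from [dls_seed_length()]; the study
#'   default is 100).
#' @param nc Critical nucleus size.
#' @param settings [fit_settings()]; default `kp` bounds `[1e-2, 1e4]`.
#' @return List with `rates` ([kinetic_parameters()] holding the absolute
#'   kn, kp, km, KE), `rmse`, `settings`.
#' @export
fit_seeded_global <- function(dataset, reduced, L, nc = 2L,
                              settings = fit_settings()) {
  .check_mass_dataset(dataset)
  stopifnot(inherits(reduced, "reduced_rates"))
  if (L <= 0) stop("seed length L must be positive", call. = FALSE)
  traces <- dataset$traces
  seeded <- vapply(traces, function(tr) tr$condition$seeded, TRUE)
  if (!any(seeded))
    stop("dataset has no seeded traces; kp is not identifiable", call. = FALSE)
  if (any(vapply(traces[seeded], function(tr) tr$condition$seed_mass,
                 numeric(1)) <= 0))
    stop("seeded traces must carry seed_mass > 0", call. = FALSE)
  kp_b <- .bound_or(settings, "kp", c(1e-2, 1e4))
  obj <- function(lkp) {
    kp <- 10^lkp
    params <- kinetic_parameters(kn = reduced$kn_prime / kp, kp = kp,
                                 km = reduced$km_prime / kp,
                                 KE = reduced$KE, nc = nc)
    .traces_ssr(traces, function(cond) {
      init <- if (cond$seeded)
        seeded_initial_conditions(M0 = cond$seed_mass, L = L, m0 = cond$m0)
      else initial_conditions(cond$m0)
      list(params = params, init = init)
    })$ssr
  }
  res <- .scan_optimize(obj, log10(kp_b[1]), log10(kp_b[2]))
  kp <- 10^res$par
  n <- sum(vapply(traces, function(tr) length(tr$M), integer(1)))
  list(rates = kinetic_parameters(kn = reduced$kn_prime / kp, kp = kp,
                                  km = reduced$km_prime / kp,
                                  KE = reduced$KE, nc = nc),
       rmse = sqrt(res$value / n), L = L, settings = settings)
}

.effect_row <- function(conc, fn, fp, fm, rmse, n) {
  data.frame(chaperone_uM = conc, fn = fn, fp = fp, fm = fm,
             rmse_uM = rmse, n_points = n)
}

#' Chaperone mechanism fit: one microscopic rate at a time
#'
#' For each chaperone concentration, all kinetic rates are fixed at the
#' chaperone-free baseline and only the chosen rate (`kn` or `kp`) is scaled
#' by a free factor fitted to that concentration's traces (a deterministic
#' single-parameter scan). Fragmentation is held fixed throughout, reflecting
#' the observation that chaperones leave fibril length distributions, and
#' hence `km`, unchanged. The per-concentration residual (RMSE) is the
#' evidence used to discriminate mechanisms.
#'
#' @param dataset [kinetic_dataset()] of [mass_trace()] objects for one
#'   chaperone dose series (a 0 uM condition, if present, is fitted too and
#'   should recover a factor of 1).
#' @param baseline [kinetic_parameters()] for tau alone.
#' @param which_rate `"kn"` or `"kp"`.
#' @param L Seed length for any seeded traces.
#' @param settings [fit_settings()]; default factor bounds `[1e-4, 10]`.
#' @return A `chaperone_effect` object: the hypothesis label, the number of
#'   free parameters per concentration, and a data.frame with columns
#'   `chaperone_uM, fn, fp, fm, rmse_uM, n_points` (the untouched factors are
#'   reported as 1).
#' @export
fit_chaperone_single_rate <- function(dataset, baseline,
                                      which_rate = c("kn", "kp"),
                                      L = 100, settings = fit_settings()) {
  .check_mass_dataset(dataset)
  stopifnot(inherits(baseline, "kinetic_parameters"))
  which_rate <- match.arg(which_rate)
  traces <- dataset$traces
  chap <- unique(vapply(traces, function(tr) tr$condition$chaperone, ""))
  chap <- setdiff(chap, "none")
  if (length(chap) > 1L)
    stop("dataset mixes chaperones: ", paste(chap, collapse = ", "),
         call. = FALSE)
  f_b <- .bound_or(settings, "factor", c(1e-4, 10))
  concs <- sort(unique(vapply(traces, function(tr) tr$condition$chaperone_conc,
                              numeric(1))))
  rows <- lapply(concs, function(cc) {
    sub <- traces[vapply(traces, function(tr)
      tr$condition$chaperone_conc == cc, TRUE)]
    if (length(sub) == 0L) {
      warning("no trace at chaperone concentration ", cc, " uM; skipped",
              call. = FALSE)
      return(NULL)
    }
    obj <- function(lf) {
      f <- 10^lf
      params <- kinetic_parameters(
        kn = baseline$kn * if (which_rate == "kn") f else 1,
        kp = baseline$kp * if (which_rate == "kp") f else 1,
        km = baseline$km, KE = baseline$KE, nc = baseline$nc)
      .traces_ssr(sub, function(cond) {
        init <- if (cond$seeded)
          seeded_initial_conditions(cond$seed_mass, L, cond$m0)
        else initial_conditions(cond$m0)
        list(params = params, init = init)
      })$ssr
    }
    res <- .scan_optimize(obj, log10(f_b[1]), log10(f_b[2]))
    f <- 10^res$par
    n <- sum(vapply(sub, function(tr) length(tr$M), integer(1)))
    .effect_row(cc, fn = if (which_rate == "kn") f else 1,
                fp = if (which_rate == "kp") f else 1, fm = 1,
                rmse = sqrt(res$value / n), n = n)
  })
  effects <- do.call(rbind, rows)
  structure(list(chaperone = if (length(chap)) chap else "none",
                 hypothesis = paste0(which_rate, "-only"),
                 n_free = 1L, effects = effects, settings = settings),
            class = "chaperone_effect")
}

#' Chaperone mechanism fit: joint scaling of several rates
#'
#' Per chaperone concentration, fits simultaneous scale factors on `kn` and
#' `kp` (and on `km` when seeded traces are available to constrain it) with a
#' differential-evolution search, using unseeded and seeded traces together.
#' This is the analysis used when neither single-rate hypothesis describes
#' the dose series (the DNAJA2 case).
#'
#' @inheritParams fit_chaperone_single_rate
#' @param fit_km Fit a fragmentation factor as well; requires seeded traces
#'   (defaults to `TRUE` exactly when seeded traces are present).
#' @return A `chaperone_effect` object (see [fit_chaperone_single_rate()]).
#' @export
fit_chaperone_joint <- function(dataset, baseline, L = 100,
                                fit_km = NULL, settings = fit_settings()) {
  .check_mass_dataset(dataset)
  stopifnot(inherits(baseline, "kinetic_parameters"))
  traces <- dataset$traces
  chap <- setdiff(unique(vapply(traces, function(tr) tr$condition$chaperone,
                                "")), "none")
  any_seeded <- any(vapply(traces, function(tr) tr$condition$seeded, TRUE))
  if (is.null(fit_km)) fit_km <- any_seeded
  if (fit_km && !any_seeded)
    stop("fitting a fragmentation factor requires seeded traces",
         call. = FALSE)
  if (!any_seeded)
    warning("no seeded traces: joint (kn, kp) fit on unseeded data only; ",
            "factors are identifiable only through their products with kp",
            call. = FALSE)
  f_b <- .bound_or(settings, "factor", c(1e-4, 10))
  d <- if (fit_km) 3L else 2L
  concs <- sort(unique(vapply(traces, function(tr) tr$condition$chaperone_conc,
                              numeric(1))))
  rows <- lapply(concs, function(cc) {
    sub <- traces[vapply(traces, function(tr)
      tr$condition$chaperone_conc == cc, TRUE)]
    obj <- function(theta) {
      f <- 10^theta
      params <- kinetic_parameters(kn = baseline$kn * f[1],
                                   kp = baseline$kp * f[2],
                                   km = baseline$km *
                                     if (fit_km) f[3] else 1,
                                   KE = baseline$KE, nc = baseline$nc)
      .traces_ssr(sub, function(cond) {
        init <- if (cond$seeded)
          seeded_initial_conditions(cond$seed_mass, L, cond$m0)
        else initial_conditions(cond$m0)
        list(params = params, init = init)
      })$ssr
    }
    res <- withr::with_seed(settings$rng_seed,
      .de_optimize(obj, rep(log10(f_b[1]), d), rep(log10(f_b[2]), d),
                   pop_size = settings$pop_size,
                   max_iter = settings$max_iterations,
                   tol = settings$tolerance))
    f <- 10^res$par
    n <- sum(vapply(sub, function(tr) length(tr$M), integer(1)))
    .effect_row(cc, fn = f[1], fp = f[2], fm = if (fit_km) f[3] else 1,
                rmse = sqrt(res$value / n), n = n)
  })
  structure(list(chaperone = if (length(chap)) chap else "none",
                 hypothesis = if (fit_km) "joint-kn-kp-km" else "joint-kn-kp",
                 n_free = d, effects = do.call(rbind, rows),
                 settings = settings),
            class = "chaperone_effect")
}

#' @export
print.chaperone_effect <- function(x, ...) {
  cat(sprintf("Chaperone effect fit: %s, hypothesis %s (%d free rate%s per concentration)\n",
              x$chaperone, x$hypothesis, x$n_free,
              if (x$n_free > 1) "s" else ""))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Rank mechanistic hypotheses by fit residual
#'
#' Pools each hypothesis' per-concentration residuals into one RMSE over the
#' common trace set and ranks ascending; at (numerically) equal RMSE the
#' hypothesis with fewer free parameters wins (parsimony).
#'
#' @param effects List of `chaperone_effect` objects fitted to the same
#'   traces.
#' @return data.frame ranked best-first with columns `hypothesis`, `rmse_uM`,
#'   `n_free`, `rmse_ratio` (relative to the best), `tied_with_best`.
#' @export
compare_rate_hypotheses <- function(effects) {
  stopifnot(length(effects) >= 2L,
            all(vapply(effects, inherits, TRUE, "chaperone_effect")))
  key <- lapply(effects, function(e)
    e$effects[, c("chaperone_uM", "n_points")])
  for (k in key[-1])
    if (!isTRUE(all.equal(k, key[[1]], check.attributes = FALSE)))
      stop("hypotheses were not fitted to the same trace sets", call. = FALSE)
  pooled <- vapply(effects, function(e)
    sqrt(sum(e$effects$rmse_uM^2 * e$effects$n_points) /
           sum(e$effects$n_points)), numeric(1))
  nfree <- vapply(effects, `[[`, integer(1), "n_free")
  hyp <- vapply(effects, `[[`, character(1), "hypothesis")
  ord <- order(pooled, nfree)
  out <- data.frame(hypothesis = hyp[ord], rmse_uM = pooled[ord],
                    n_free = nfree[ord],
                    rmse_ratio = pooled[ord] / pooled[ord][1])
  out$tied_with_best <- abs(out$rmse_uM - out$rmse_uM[1]) <=
    1e-9 * (out$rmse_uM[1] + 1e-30)
  rownames(out) <- NULL
  out
}

#' Replicate-set error estimates for fitted rates
#'
#' Re-runs a fit on each independent replicate set; with two sets the
#' uncertainty per rate is half the absolute difference, with more it is the
#' standard deviation across sets.
#'
#' @param dataset [kinetic_dataset()] whose `replicate_sets` labels partition
#'   the traces into at least two independent sets.
#' @param fit_fn Function taking a [kinetic_dataset()] and returning a named
#'   numeric vector of rates (e.g. wrap [fit_unseeded_global()]).
#' @return List with `per_set` (matrix of rates by set) and `uncertainty`
#'   (named vector).
#' @export
estimate_rate_errors <- function(dataset, fit_fn) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  sets <- dataset$replicate_sets
  if (is.null(sets) || length(unique(sets)) < 2L)
    stop("need >= 2 replicate sets for error estimation", call. = FALSE)
  labs <- unique(sets)
  fits <- lapply(labs, function(lb)
    fit_fn(kinetic_dataset(dataset$traces[sets == lb])))
  per_set <- do.call(cbind, fits)
  colnames(per_set) <- as.character(labs)
  unc <- if (length(labs) == 2L) abs(per_set[, 1] - per_set[, 2]) / 2
         else apply(per_set, 1, stats::sd)
  list(per_set = per_set, uncertainty = unc)
}

#' Serialize a fit report to JSON
#'
#' Records rates with units, residuals, optimizer settings and the RNG seed
#' so every number is traceable to its run.
#'
#' @param fit Result of one of the `fit_*` functions.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(.unclass_deep(fit), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .unclass_deep)
  } else x
}
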