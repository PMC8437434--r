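#' Experimental condition metadata for a kinetic trace
#'
#' @param m0 Initial monomer concentration, uM.
#' @param chaperone Chaperone name or `"none"`.
#' @param chaperone_conc Chaperone concentration, uM.
#' @param seeded Logical; whether preformed seeds were added.
#' @param seed_mass Seed mass concentration, uM.
#' @param replicate Replicate identifier.
#' @return A `trace_condition` list.
#' @export
trace_condition <- function(m0, chaperone = "none", chaperone_conc = 0,
                            seeded = FALSE, seed_mass = 0, replicate = 1L) {
  stopifnot(is.numeric(m0), m0 > 0, is.numeric(chaperone_conc),
            chaperone_conc >= 0, is.logical(seeded), seed_mass >= 0)
  if (seeded && seed_mass <= 0)
    stop("seeded traces need seed_mass > 0", call. = FALSE)
  structure(list(m0 = as.numeric(m0), chaperone = as.character(chaperone),
                 chaperone_conc = as.numeric(chaperone_conc),
                 seeded = isTRUE(seeded), seed_mass = as.numeric(seed_mass),
                 replicate = replicate),
            class = "trace_condition")
}

#' Raw ThT fluorescence trace
#'
#' A plate-reader time course of Thioflavin-T fluorescence, which reports
#' total fibril mass (not number or length), together with its condition.
#'
#' @param times Strictly increasing times, min.
#' @param signal ThT fluorescence, arbitrary units; finite, same length as
#'   `times` (length >= 4).
#' @param condition A [trace_condition()].
#' @return A `raw_trace` object.
#' @export
raw_trace <- function(times, signal, condition) {
  times <- as.numeric(times); signal <- as.numeric(signal)
  if (length(times) != length(signal) || length(times) < 4L)
    stop("times and signal must have equal length >= 4", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  stopifnot(inherits(condition, "trace_condition"))
  structure(list(times = times, signal = signal, condition = condition),
            class = "raw_trace")
}

#' Fibril mass-concentration trace
#'
#' @param times Strictly increasing times, min.
#' @param M Fibril mass concentration, uM.
#' @param condition A [trace_condition()].
#' @return A `mass_trace` object; values above
#'   `1.05 * (m0 + seed_mass)` (5 percent noise headroom) are flagged in the
#'   attribute `headroom_violation`.
#' @export
mass_trace <- function(times, M, condition) {
  times <- as.numeric(times); M <- as.numeric(M)
  if (length(times) != length(M) || length(times) < 4L)
    stop("times and M must have equal length >= 4", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  stopifnot(inherits(condition, "trace_condition"))
  cap <- 1.05 * (condition$m0 + condition$seed_mass)
  viol <- any(M > cap, na.rm = TRUE)
  if (viol)
    warning("mass trace exceeds 1.05 * (m0 + seed_mass); flagged",
            call. = FALSE)
  structure(list(times = times, M = M, condition = condition),
            class = "mass_trace", headroom_violation = viol)
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf(
    "ThT trace: %d points over [0, %g] min; m0 = %g uM, chaperone = %s (%g uM)%s\n",
    length(x$times), max(x$times), x$condition$m0, x$condition$chaperone,
    x$condition$chaperone_conc,
    if (x$condition$seeded) sprintf(", seeded (M0 = %g uM)",
                                    x$condition$seed_mass) else ""))
  invisible(x)
}

#' @export
print.mass_trace <- function(x, ...) {
  cat(sprintf(
    "Fibril mass trace: %d points over [0, %g] min; m0 = %g uM, chaperone = %s (%g uM)%s\n",
    length(x$times), max(x$times), x$condition$m0, x$condition$chaperone,
    x$condition$chaperone_conc,
    if (x$condition$seeded) sprintf(", seeded (M0 = %g uM)",
                                    x$condition$seed_mass) else ""))
  invisible(x)
}

#' ThT signal-to-mass conversion settings
#'
#' The signal of the long-term plateau of the trace with the highest monomer
#' concentration anchors the conversion: `M_i(t) = mmax * S_i(t) / Smax_inf`.
#'
#' @param mmax Highest monomer concentration in the series, uM.
#' @param Smax_inf Long-term plateau signal of that trace, a.u.
#' @param plateau_fraction Fraction of trailing points used to estimate
#'   plateaus (0 < plateau_fraction <= 0.5).
#' @return A `conversion_spec` object.
#' @export
conversion_spec <- function(mmax, Smax_inf, plateau_fraction = 0.1) {
  stopifnot(is.numeric(mmax), is.numeric(Smax_inf),
            is.numeric(plateau_fraction))
  if (mmax <= 0) stop("mmax must be > 0", call. = FALSE)
  if (Smax_inf <= 0) stop("Smax_inf must be > 0", call. = FALSE)
  if (plateau_fraction <= 0 || plateau_fraction > 0.5)
    stop("plateau_fraction must be in (0, 0.5]", call. = FALSE)
  structure(list(mmax = mmax, Smax_inf = Smax_inf,
                 plateau_fraction = plateau_fraction),
            class = "conversion_spec")
}

#' Estimate a conversion spec from the highest-concentration trace
#'
#' `Smax_inf` is the mean signal over the trailing `plateau_fraction` of the
#' trace with the highest `m0` in the collection.
#'
#' @param traces List of [raw_trace()] objects.
#' @param plateau_fraction Trailing window share for the plateau estimate.
#' @return A [conversion_spec()].
#' @export
estimate_conversion_spec <- function(traces, plateau_fraction = 0.1) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "raw_trace")))
  m0s <- vapply(traces, function(tr) tr$condition$m0, numeric(1))
  top <- traces[[which.max(m0s)]]
  n <- length(top$signal)
  k <- max(2L, ceiling(plateau_fraction * n))
  conversion_spec(mmax = max(m0s),
                  Smax_inf = mean(utils::tail(top$signal, k)),
                  plateau_fraction = plateau_fraction)
}

#' Subtract a no-trigger baseline trace
#'
#' Baseline wells (same conditions but without the aggregation trigger) are
#' interpolated linearly onto the trace's time grid and subtracted.
#'
#' @param trace,baseline [raw_trace()] objects; the baseline must cover the
#'   trace's time range.
#' @return A [raw_trace()] with the residual signal and the trace's metadata.
#' @export
subtract_baseline <- function(trace, baseline) {
  stopifnot(inherits(trace, "raw_trace"), inherits(baseline, "raw_trace"))
  if (min(baseline$times) > min(trace$times) ||
      max(baseline$times) < max(trace$times))
    stop("baseline does not cover the trace time range; cannot align",
         call. = FALSE)
  base_on_grid <- stats::approx(baseline$times, baseline$signal,
                                xout = trace$times)$y
  raw_trace(trace$times, trace$signal - base_on_grid, trace$condition)
}

#' Bin a trace by block averaging
#'
#' Non-overlapping consecutive windows of `bin_size` points are replaced by
#' their mean time and mean value; a trailing partial window is averaged
#' as-is. Smoothing by binning 2-5 points reduces noise prior to fitting.
#'
#' @param trace A [raw_trace()] or [mass_trace()].
#' @param bin_size Integer in 1..5.
#' @return Object of the same class with `ceiling(n / bin_size)` points.
#' @export
bin_trace <- function(trace, bin_size) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L ||
      bin_size != round(bin_size) || bin_size < 1 || bin_size > 5)
    stop("bin_size must be an integer between 1 and 5", call. = FALSE)
  bin_size <- as.integer(bin_size)
  if (bin_size == 1L) return(trace)
  vfield <- if (inherits(trace, "raw_trace")) "signal"
            else if (inherits(trace, "mass_trace")) "M"
            else stop("trace must be a raw_trace or mass_trace", call. = FALSE)
  n <- length(trace$times)
  grp <- rep(seq_len(ceiling(n / bin_size)), each = bin_size)[seq_len(n)]
  t_new <- as.numeric(tapply(trace$times, grp, mean))
  v_new <- as.numeric(tapply(trace[[vfield]], grp, mean))
  out <- trace
  out$times <- t_new
  out[[vfield]] <- v_new
  out
}

#' Convert ThT signals to fibril mass concentrations
#'
#' Applies `M_i(t) = mmax * S_i(t) / Smax_inf` to every trace, anchoring the
#' mass scale to the full-conversion plateau of the highest-concentration
#' trace.
#'
#' @param traces List of [raw_trace()] objects.
#' @param spec A [conversion_spec()]; if missing, estimated from the traces
#'   via [estimate_conversion_spec()].
#' @return List of [mass_trace()] objects.
#' @export
signal_to_mass <- function(traces, spec = NULL) {
  stopifnot(all(vapply(traces, inherits, TRUE, "raw_trace")))
  if (is.null(spec)) spec <- estimate_conversion_spec(traces)
  stopifnot(inherits(spec, "conversion_spec"))
  lapply(traces, function(tr)
    mass_trace(tr$times, spec$mmax * tr$signal / spec$Smax_inf,
               tr$condition))
}

#' Extract the half-saturation time of a mass trace
#'
#' The plateau is the mean of the trailing `plateau_fraction` of points; the
#' half-time is the linearly interpolated first upward crossing of half that
#' plateau. Traces that have not saturated (the trailing-window slope exceeds
#' `slope_tol` times the peak rate, e.g. fully inhibited chaperone conditions
#' with no ThT signal) are rejected.
#'
#' @param trace A [mass_trace()].
#' @param plateau_fraction Trailing window share defining the plateau.
#' @param slope_tol Saturation criterion: mean trailing slope must be below
#'   `slope_tol * max slope`.
#' @return List with `t_half` (min), `plateau` (uM), `crossing_index`.
#' @export
extract_half_time <- function(trace, plateau_fraction = 0.1,
                              slope_tol = 0.01) {
  stopifnot(inherits(trace, "mass_trace"))
  n <- length(trace$times)
  k <- max(2L, ceiling(plateau_fraction * n))
  tail_idx <- seq.int(n - k + 1L, n)
  plateau <- mean(trace$M[tail_idx])
  slopes <- diff(trace$M) / diff(trace$times)
  peak_rate <- max(abs(slopes))
  tail_rate <- abs(mean(slopes[seq.int(n - k + 1L, n - 1L)]))
  if (peak_rate <= 0 || plateau <= 0 || tail_rate > slope_tol * peak_rate)
    stop("trace has not saturated: no plateau detected", call. = FALSE)
  half <- plateau / 2
  above <- which(trace$M >= half)
  if (length(above) == 0L)
    stop("trace never reaches half its plateau", call. = FALSE)
  i <- above[1]
  if (i == 1L) {
    t_half <- trace$times[1]
  } else {
    # linear interpolation between the bracketing samples
    t0 <- trace$times[i - 1L]; t1 <- trace$times[i]
    M0 <- trace$M[i - 1L]; M1 <- trace$M[i]
    t_half <- t0 + (half - M0) / (M1 - M0) * (t1 - t0)
  }
  list(t_half = t_half, plateau = plateau, crossing_index = i)
}

#' Scaling exponent of half-times versus monomer concentration
#'
#' Ordinary least squares of `log10(t_half)` on `log10(m0)` gives the scaling
#' exponent gamma, a diagnostic of the dominant microscopic mechanism
#' (approximately -nc/2 for pure nucleation-elongation; shallower with
#' fragmentation). A second-degree fit supplies the curvature coefficient;
#' positive curvature indicates saturation of the dominant process. The
#' curvature is flagged significant when its magnitude exceeds twice its
#' standard error.
#'
#' @param half_times data.frame with numeric columns `m0` (uM) and
#'   `t_half` (min); at least 3 distinct positive `m0` values.
#' @return List with `gamma`, `gamma_stderr`, `curvature_coeff`,
#'   `curvature_stderr`, `curvature_significant`.
#' @examples
#' ht <- data.frame(m0 = c(2.5, 5, 10, 20, 40),
#'                  t_half = 100 * c(2.5, 5, 10, 20, 40)^-0.5)
#' fit_scaling_exponent(ht)$gamma
#' @export
fit_scaling_exponent <- function(half_times) {
  stopifnot(is.data.frame(half_times),
            all(c("m0", "t_half") %in% names(half_times)))
  ok <- is.finite(half_times$m0) & is.finite(half_times$t_half)
  half_times <- half_times[ok, , drop = FALSE]
  if (length(unique(half_times$m0)) < 3L)
    stop("need at least 3 distinct monomer concentrations", call. = FALSE)
  if (any(half_times$m0 <= 0) || any(half_times$t_half <= 0))
    stop("m0 and t_half must be positive", call. = FALSE)
  lx <- log10(half_times$m0)
  ly <- log10(half_times$t_half)
  lin <- stats::lm(ly ~ lx)
  quad <- stats::lm(ly ~ lx + I(lx^2))
  # summary.lm warns on zero-residual (exact power-law) input; the
  # coefficients and standard errors are still what we want
  cs <- suppressWarnings(stats::coef(summary(lin)))
  gamma <- cs["lx", "Estimate"]
  gamma_se <- cs["lx", "Std. Error"]
  qs <- suppressWarnings(stats::coef(summary(quad)))
  curv <- qs["I(lx^2)", "Estimate"]
  curv_se <- qs["I(lx^2)", "Std. Error"]
  list(gamma = unname(gamma), gamma_stderr = unname(gamma_se),
       curvature_coeff = unname(curv), curvature_stderr = unname(curv_se),
       curvature_significant = is.finite(curv_se) &&
         abs(curv) > 2 * curv_se)
}
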