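#' Boltzmann constant, J/K
#' @keywords internal
.kB <- 1.38e-23

#' DLS instrument parameters
#'
#' @param lambda0 Laser wavelength, m.
#' @param theta Scattering angle, degrees (0 < theta < 180).
#' @param n Solvent refractive index (1.334 for aqueous buffer).
#' @param T Temperature, K.
#' @param eta Dynamic viscosity, Pa.s. The buffer value is rarely reported;
#'   the default is water at 25 C (8.9e-4 Pa.s).
#' @return An `instrument_params` object.
#' @export
instrument_params <- function(lambda0, theta, n = 1.334, T = 298,
                              eta = 0.89e-3) {
  stopifnot(lambda0 > 0, n > 0, T > 0, eta > 0)
  if (theta <= 0 || theta >= 180)
    stop("scattering angle must be in (0, 180) degrees", call. = FALSE)
  structure(list(lambda0 = lambda0, theta = theta, n = n, T = T, eta = eta),
            class = "instrument_params")
}

#' Scattering wave vector
#'
#' `q = (4 * pi * n / lambda0) * sin(theta / 2)`.
#'
#' @param params [instrument_params()].
#' @return q in m^-1.
#' @examples
#' scattering_vector(instrument_params(lambda0 = 633e-9, theta = 90))
#' @export
scattering_vector <- function(params) {
  stopifnot(inherits(params, "instrument_params"))
  4 * pi * params$n / params$lambda0 * sin(params$theta * pi / 360)
}

#' DLS intensity autocorrelation curve
#'
#' @param lags Lag times, s, strictly increasing.
#' @param g2 Normalized intensity autocorrelation (decays from `1 + beta`
#'   toward 1).
#' @param replicates_averaged Number of acquisitions averaged.
#' @return An `autocorrelation_curve` object.
#' @export
autocorrelation_curve <- function(lags, g2, replicates_averaged = 1L) {
  lags <- as.numeric(lags); g2 <- as.numeric(g2)
  if (length(lags) != length(g2) || length(lags) < 5L)
    stop("need >= 5 (lag, g2) points", call. = FALSE)
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing",
                                 call. = FALSE)
  structure(list(lags = lags, g2 = g2,
                 replicates_averaged = as.integer(replicates_averaged)),
            class = "autocorrelation_curve")
}

#' Fit a single-exponential autocorrelation decay
#'
#' Least-squares fit of `g2(tau) = 1 + beta * exp(-2 * D * q^2 * tau)` with
#' the baseline fixed at exactly 1. Start values come from a log-linear
#' regression of `g2 - 1`; the fit itself is nonlinear least squares on the
#' decay rate `Gamma = 2 * D * q^2`.
#'
#' @param curve [autocorrelation_curve()].
#' @param q Scattering vector, m^-1 (see [scattering_vector()]).
#' @return List with `beta` (coherence factor), `D` (m^2/s), `Gamma` (s^-1),
#'   `rmse`.
#' @export
fit_autocorrelation <- function(curve, q) {
  stopifnot(inherits(curve, "autocorrelation_curve"), q > 0)
  y <- curve$g2 - 1
  pos <- y > 0
  if (sum(pos) < 3L || max(y) < 1e-6 ||
      stats::cor(curve$lags, curve$g2) > -0.1)
    stop("autocorrelation curve does not decay; cannot fit", call. = FALSE)
  lf <- stats::lm(log(y[pos]) ~ curve$lags[pos])
  beta0 <- min(1, exp(stats::coef(lf)[1]))
  Gamma0 <- max(1e-12, -stats::coef(lf)[2])
  fit <- stats::nls(g2 ~ 1 + beta * exp(-Gamma * lags),
                    data = list(g2 = curve$g2, lags = curve$lags),
                    start = list(beta = beta0, Gamma = Gamma0),
                    control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  if (cf[["beta"]] <= 0 || cf[["Gamma"]] <= 0)
    stop("autocorrelation fit returned a non-physical solution",
         call. = FALSE)
  list(beta = unname(cf[["beta"]]), D = unname(cf[["Gamma"]]) / (2 * q^2),
       Gamma = unname(cf[["Gamma"]]),
       rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Stokes radius from the diffusion coefficient
#'
#' Stokes-Einstein: `Rs = kB * T / (6 * pi * eta * D)`.
#'
#' @param D Translational diffusion coefficient, m^2/s.
#' @param T Temperature, K.
#' @param eta Dynamic viscosity, Pa.s.
#' @return Rs in m.
#' @export
stokes_radius <- function(D, T = 298, eta = 0.89e-3) {
  if (D <= 0 || T <= 0 || eta <= 0)
    stop("D, T, eta must all be positive", call. = FALSE)
  .kB * T / (6 * pi * eta * D)
}

#' Diffusion coefficient of a sphere of given Stokes radius
#'
#' Inverse of [stokes_radius()].
#' @param Rs Stokes radius, m.
#' @inheritParams stokes_radius
#' @return D in m^2/s.
#' @export
diffusion_from_radius <- function(Rs, T = 298, eta = 0.89e-3) {
  if (Rs <= 0 || T <= 0 || eta <= 0)
    stop("Rs, T, eta must all be positive", call. = FALSE)
  .kB * T / (6 * pi * eta * Rs)
}

#' Long axis of a prolate ellipsoid with a given Stokes radius
#'
#' A rod-like fibril is modeled as a prolate ellipsoid with long axis `a`
#' (fibril length) and short axis `b` (fibril thickness). Its friction
#' coefficient `6 * pi * eta * a / log(2 * a / b)` must equal that of the
#' sphere actually measured by DLS, `6 * pi * eta * Rs`, so `a` solves
#' `a / log(2 * a / b) = Rs`. The root is found by bracketed bisection
#' (`stats::uniroot`) on `[Rs * (1 + 1e-6), 1000 * Rs]` followed by one
#' Newton polish; `a > Rs` always, because the log factor exceeds 1 on the
#' valid branch.
#'
#' @param Rs Stokes radius, nm.
#' @param b Short axis (fibril thickness), nm; cryo-EM tau fibril structures
#'   give about 10 nm.
#' @return Long axis `a` in nm, with residual
#'   `|a / log(2 a / b) - Rs| < 1e-9 * Rs`.
#' @examples
#' ellipsoid_long_axis(Rs = 55, b = 10) # about 200 nm
#' @export
ellipsoid_long_axis <- function(Rs, b) {
  if (Rs <= 0 || b <= 0) stop("Rs and b must be positive", call. = FALSE)
  f <- function(a) a / log(2 * a / b) - Rs
  # a / log(2a/b) attains its minimum b*e/2 at a = b*e/2; below that no
  # prolate solution exists, and at equality the root is the tangent point
  amin <- b * exp(1) / 2
  if (abs(f(amin)) <= 1e-12 * Rs) return(amin)
  if (f(amin) > 0)
    stop("no solution: fibril thickness b = ", b,
         " nm is too large for Rs = ", Rs, " nm", call. = FALSE)
  lo <- max(Rs * (1 + 1e-6), amin * (1 + 1e-9))
  hi <- 1e3 * Rs
  if (f(lo) >= 0 || f(hi) <= 0)
    stop("no bracketed root for a / log(2a/b) = Rs with Rs = ", Rs,
         " nm, b = ", b, " nm", call. = FALSE)
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-12 * Rs)$root
  # one Newton step to polish below the 1e-9 relative residual contract
  fp <- function(a) (log(2 * a / b) - 1) / log(2 * a / b)^2
  polished <- a - f(a) / fp(a)
  if (is.finite(polished) && abs(f(polished)) < abs(f(a))) a <- polished
  if (abs(f(a)) >= 1e-9 * Rs)
    stop("root polish failed to meet residual tolerance", call. = FALSE)
  a
}

#' Seed length in monomers from the ellipsoid long axis
#'
#' @param a Long axis (fibril length), nm.
#' @param spacing Axial rise per monomer, nm (about 2 nm for tau fibrils).
#' @return Seed length L in monomers (real-valued; rounding is the caller's
#'   choice).
#' @examples
#' seed_length_monomers(a = 200, spacing = 2) # 100 monomers
#' @export
seed_length_monomers <- function(a, spacing = 2) {
  if (a <= 0 || spacing <= 0)
    stop("a and spacing must be positive", call. = FALSE)
  a / spacing
}

#' Full DLS seed-sizing chain
#'
#' Autocorrelation fit, Stokes-Einstein inversion, prolate-ellipsoid friction
#' inversion and monomer-spacing division in one call:
#' curve -> (beta, D) -> Rs -> a -> L.
#'
#' @param curve [autocorrelation_curve()].
#' @param params [instrument_params()].
#' @param b Fibril thickness, nm.
#' @param spacing Axial rise per monomer, nm.
#' @return List with `beta`, `D_m2s`, `Rs_nm`, `a_nm`, `L_monomers` and the
#'   echoed assumptions (`b_nm`, `spacing_nm`, `T_K`, `eta_Pas`).
#' @export
dls_seed_length <- function(curve, params, b = 10, spacing = 2) {
  q <- scattering_vector(params)
  fit <- fit_autocorrelation(curve, q)
  Rs_nm <- stokes_radius(fit$D, params$T, params$eta) * 1e9
  a_nm <- ellipsoid_long_axis(Rs_nm, b)
  list(beta = fit$beta, D_m2s = fit$D, Rs_nm = Rs_nm, a_nm = a_nm,
       L_monomers = seed_length_monomers(a_nm, spacing),
       b_nm = b, spacing_nm = spacing, T_K = params$T, eta_Pas = params$eta)
}
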