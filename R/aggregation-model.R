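#' Kinetic parameters of the tau aggregation model
#'
#' Bundles the rate constants of the nucleation / saturating-elongation /
#' fragmentation model of amyloid formation. Fibril number concentration P
#' grows by primary nucleation (`kn * m^nc`) and fragmentation (`km * M`);
#' fibril mass M grows by saturating elongation
#' (`2 * kp * KE * m / (KE + m) * P`). All concentrations are in uM and all
#' times in minutes.
#'
#' @param kn Primary nucleation rate constant, uM^(1-nc) min^-1.
#' @param kp Elongation rate constant, uM^-1 min^-1.
#' @param km Fragmentation rate constant, min^-1.
#' @param KE Elongation saturation constant (monomer concentration at
#'   half-maximal growth rate), uM. Must be positive.
#' @param nc Critical nucleus size, a fixed model setting (default 2), never a
#'   fitted parameter.
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(kn = 1e-5, kp = 50, km = 1e-4, KE = 10)
#' @export
kinetic_parameters <- function(kn, kp, km, KE, nc = 2L) {
  stopifnot(is.numeric(kn), is.numeric(kp), is.numeric(km), is.numeric(KE),
            length(kn) == 1L, length(kp) == 1L, length(km) == 1L,
            length(KE) == 1L, length(nc) == 1L)
  if (!all(is.finite(c(kn, kp, km, KE, nc))))
    stop("kinetic parameters must be finite", call. = FALSE)
  if (kn < 0 || kp < 0 || km < 0)
    stop("rate constants kn, kp, km must be >= 0", call. = FALSE)
  if (KE <= 0)
    stop("saturation constant KE must be > 0", call. = FALSE)
  if (nc < 1 || nc != round(nc))
    stop("critical nucleus size nc must be an integer >= 1", call. = FALSE)
  structure(
    list(kn = as.numeric(kn), kp = as.numeric(kp), km = as.numeric(km),
         KE = as.numeric(KE), nc = as.integer(nc)),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Aggregation kinetic parameters (uM, min):\n")
  cat(sprintf("  kn = %g uM^(1-nc).min^-1   (primary nucleation)\n", x$kn))
  cat(sprintf("  kp = %g uM^-1.min^-1       (elongation)\n", x$kp))
  cat(sprintf("  km = %g min^-1             (fragmentation)\n", x$km))
  cat(sprintf("  KE = %g uM                 (elongation saturation)\n", x$KE))
  cat(sprintf("  nc = %d                    (critical nucleus size, fixed)\n",
              x$nc))
  invisible(x)
}

#' Initial conditions for an aggregation trajectory
#'
#' @param m0 Initial monomer concentration, uM.
#' @param M0 Initial seed mass concentration, uM (0 for unseeded reactions).
#' @param P0 Initial fibril number concentration, uM (0 for unseeded).
#' @return An object of class `initial_conditions`.
#' @seealso [seeded_initial_conditions()] to derive `P0` from a seed length.
#' @export
initial_conditions <- function(m0, M0 = 0, P0 = 0) {
  stopifnot(is.numeric(m0), is.numeric(M0), is.numeric(P0),
            length(m0) == 1L, length(M0) == 1L, length(P0) == 1L)
  if (!all(is.finite(c(m0, M0, P0))) || m0 < 0 || M0 < 0 || P0 < 0)
    stop("initial conditions must be finite and >= 0", call. = FALSE)
  if (M0 == 0 && P0 > 0)
    stop("P0 > 0 requires seed mass M0 > 0", call. = FALSE)
  structure(list(m0 = as.numeric(m0), M0 = as.numeric(M0),
                 P0 = as.numeric(P0)),
            class = "initial_conditions")
}

#' Seeded initial conditions from seed mass and seed length
#'
#' Seeds of mass concentration `M0` composed of fibrils `L` monomers long
#' contribute a number concentration `P0 = M0 / L`.
#'
#' @param M0 Seed mass concentration, uM.
#' @param L Seed length in monomers (>= 1); typically from the DLS
#'   seed-sizing chain (default in the study design: 100).
#' @param m0 Initial free monomer concentration, uM.
#' @return An [initial_conditions()] object with `P0 = M0 / L`.
#' @examples
#' seeded_initial_conditions(M0 = 1, L = 100, m0 = 10)
#' @export
seeded_initial_conditions <- function(M0, L, m0) {
  stopifnot(is.numeric(M0), is.numeric(L), is.numeric(m0))
  if (L < 1) stop("seed length L must be >= 1 monomer", call. = FALSE)
  if (M0 < 0) stop("seed mass M0 must be >= 0", call. = FALSE)
  if (m0 <= 0) stop("monomer concentration m0 must be > 0", call. = FALSE)
  initial_conditions(m0 = m0, M0 = M0, P0 = if (M0 > 0) M0 / L else 0)
}

#' Instantaneous rates of the aggregation model
#'
#' Evaluates the right-hand side of the kinetic model at one state:
#' `dP/dt = kn * m^nc + km * M` and
#' `dM/dt = 2 * kp * KE * m / (KE + m) * P`, with the free monomer obtained by
#' mass conservation, `m = max(0, total_mass - M)`.
#'
#' @param state List or named vector with components `M` (fibril mass, uM) and
#'   `P` (fibril number, uM).
#' @param params [kinetic_parameters()].
#' @param total_mass Conserved total tau mass `m0 + M0`, uM.
#' @return Named numeric vector `c(dP = , dM = )` in uM min^-1.
#' @export
aggregation_derivatives <- function(state, params, total_mass) {
  stopifnot(inherits(params, "kinetic_parameters"))
  M <- as.numeric(state[["M"]])
  P <- as.numeric(state[["P"]])
  if (!all(is.finite(c(M, P, total_mass))) || M < 0 || P < 0 || total_mass < 0)
    stop("state and total_mass must be finite and >= 0", call. = FALSE)
  m <- max(0, total_mass - M)
  dP <- params$kn * m^params$nc + params$km * M
  dM <- 2 * params$kp * params$KE * m / (params$KE + m) * P
  c(dP = dP, dM = dM)
}

#' Simulate a fibril mass trajectory
#'
#' Integrates the aggregation model with the compiled adaptive Dormand-Prince
#' 5(4) solver. The monomer is eliminated algebraically (`m = total - M`), so
#' `m(t) + M(t)` is conserved exactly and the system reduces to two ODEs.
#'
#' @param params [kinetic_parameters()].
#' @param init [initial_conditions()] (see [seeded_initial_conditions()]).
#' @param times Strictly increasing, non-negative output time grid in
#'   minutes. The initial conditions always refer to t = 0; a grid starting
#'   after 0 (e.g. block-averaged trace times) is integrated from 0 to its
#'   first point.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data.frame of class `aggregation_trajectory` with columns
#'   `t_min`, `m_uM`, `M_uM`, `P_uM`.
#' @examples
#' p <- kinetic_parameters(kn = 1e-5, kp = 50, km = 1e-4, KE = 10)
#' traj <- simulate_mass_curve(p, initial_conditions(m0 = 10), seq(0, 2000, 10))
#' head(traj)
#' @export
simulate_mass_curve <- function(params, init, times, rtol = 1e-8,
                                atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(init, "initial_conditions"))
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with length >= 2", call. = FALSE)
  if (times[1] < 0)
    stop("times must be non-negative", call. = FALSE)
  mat <- .simulate_agg_cpp(params$kn, params$kp, params$km, params$KE,
                           params$nc, init$m0, init$M0, init$P0,
                           times, rtol, atol)
  out <- as.data.frame(mat)
  if (any(!is.finite(out$M_uM)))
    stop("integration failed (non-finite fibril mass) for parameter set: ",
         paste(sprintf("%s=%g", c("kn", "kp", "km", "KE"),
                       c(params$kn, params$kp, params$km, params$KE)),
               collapse = ", "), call. = FALSE)
  attr(out, "params") <- params
  attr(out, "init") <- init
  class(out) <- c("aggregation_trajectory", "data.frame")
  out
}

#' Write a simulated trajectory to CSV
#'
#' Columns `t_min, m_uM, M_uM, P_uM`; the generating parameters are written
#' alongside as JSON with explicit units when `params_json` is given.
#'
#' @param traj Result of [simulate_mass_curve()].
#' @param path Output CSV path.
#' @param params_json Optional path for a JSON record of the parameters.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, params_json = NULL) {
  stopifnot(inherits(traj, "aggregation_trajectory"))
  utils::write.csv(as.data.frame(traj)[, c("t_min", "m_uM", "M_uM", "P_uM")],
                   path, row.names = FALSE)
  if (!is.null(params_json)) {
    p <- attr(traj, "params")
    init <- attr(traj, "init")
    jsonlite::write_json(
      list(parameters = list(
             kn = list(value = p$kn, units = "uM^(1-nc).min^-1"),
             kp = list(value = p$kp, units = "uM^-1.min^-1"),
             km = list(value = p$km, units = "min^-1"),
             KE = list(value = p$KE, units = "uM"),
             nc = list(value = p$nc, units = "monomers")),
           initial_conditions = list(m0_uM = init$m0, M0_uM = init$M0,
                                     P0_uM = init$P0)),
      params_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
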