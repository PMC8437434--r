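# Independent fixed-step classical RK4 integrator of the aggregation model,
# written directly from the rate equations in plain R. Used as the oracle
# for the adaptive compiled solver; deliberately shares no code with it.
rk4_mass_oracle <- function(params, init, times, refine = 10L) {
  # returns c(dM, dP), positional
  rhs <- function(M, P, mtot) {
    m <- max(0, mtot - M)
    c(2 * params$kp * params$KE * m / (params$KE + m) * P,
      params$kn * m^params$nc + params$km * M)
  }
  mtot <- init$m0 + init$M0
  M <- init$M0
  P <- init$P0
  out_M <- numeric(length(times))
  out_P <- numeric(length(times))
  out_M[1] <- M
  out_P[1] <- P
  for (i in seq_along(times)[-1]) {
    h <- (times[i] - times[i - 1]) / refine
    for (k in seq_len(refine)) {
      k1 <- rhs(M, P, mtot)
      k2 <- rhs(M + h / 2 * k1[1], P + h / 2 * k1[2], mtot)
      k3 <- rhs(M + h / 2 * k2[1], P + h / 2 * k2[2], mtot)
      k4 <- rhs(M + h * k3[1], P + h * k3[2], mtot)
      M <- M + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      P <- P + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    }
    out_M[i] <- M
    out_P[i] <- P
  }
  data.frame(t = times, M = out_M, P = out_P)
}

# simulate one noise-free mass trace at the given parameters
sim_trace <- function(params, m0, times, M0 = 0, L = 100,
                      chaperone = "none", conc = 0, replicate = 1L) {
  init <- if (M0 > 0) seeded_initial_conditions(M0, L, m0)
          else initial_conditions(m0)
  tj <- simulate_mass_curve(params, init, times)
  mass_trace(tj$t_min, tj$M_uM,
             trace_condition(m0, chaperone = chaperone,
                             chaperone_conc = conc, seeded = M0 > 0,
                             seed_mass = M0, replicate = replicate))
}

fast_settings <- function(seed = 1L, iters = 60L) {
  fit_settings(max_iterations = iters, rng_seed = seed)
}
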