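test_that("parameter and initial-condition constructors enforce invariants", {
  expect_error(kinetic_parameters(-1, 1, 1, 1), "must be >= 0")
  expect_error(kinetic_parameters(1, 1, 1, 0), "KE must be > 0")
  expect_error(kinetic_parameters(1, 1, 1, 1, nc = 1.5), "integer")
  expect_error(kinetic_parameters(NaN, 1, 1, 1), "finite")
  expect_error(seeded_initial_conditions(1, 0.5, 10), "L must be >= 1")
  expect_error(initial_conditions(-1), ">= 0")
  expect_error(initial_conditions(10, M0 = 0, P0 = 1), "M0 > 0")
})

test_that("instantaneous rates match hand evaluation of the model", {
  # no monomer left: nucleation and growth vanish, fragmentation persists
  p <- kinetic_parameters(kn = 1e-4, kp = 2, km = 0.001, KE = 10)
  d <- aggregation_derivatives(list(M = 10, P = 0.1), p, total_mass = 10)
  expect_equal(unname(d["dP"]), 0.001 * 10)
  expect_equal(unname(d["dM"]), 0)

  # no fibrils and no sources
  p0 <- kinetic_parameters(kn = 0, kp = 2, km = 0, KE = 10)
  d0 <- aggregation_derivatives(list(M = 0, P = 0), p0, total_mass = 10)
  expect_equal(unname(d0), c(0, 0))

  # nucleation term: kn * m^nc = 1e-4 * 10^2
  pn <- kinetic_parameters(kn = 1e-4, kp = 0, km = 0, KE = 10, nc = 2)
  dn <- aggregation_derivatives(list(M = 0, P = 0), pn, total_mass = 10)
  expect_equal(unname(dn["dP"]), 0.01)

  # elongation term: 2 * 2 * (10*10/20) * 0.05 = 1
  pe <- kinetic_parameters(kn = 0, kp = 2, km = 0, KE = 10)
  de <- aggregation_derivatives(list(M = 0, P = 0.05), pe, total_mass = 10)
  expect_equal(unname(de["dM"]), 1.0)

  expect_error(aggregation_derivatives(list(M = NA, P = 0), p, 10), "finite")
})

test_that("trivial trajectories behave: nothing nucleates, full conversion", {
  p0 <- kinetic_parameters(kn = 0, kp = 50, km = 1e-4, KE = 10)
  tj <- simulate_mass_curve(p0, initial_conditions(10), seq(0, 100, 1))
  expect_true(all(tj$M_uM == 0))

  p <- kinetic_parameters(kn = 1e-5, kp = 50, km = 1e-4, KE = 10)
  tj <- simulate_mass_curve(p, initial_conditions(10), seq(0, 5000, 10))
  expect_lt(abs(tail(tj$M_uM, 1) - 10), 0.001 * 10)
})

test_that("adaptive solver agrees with a 10x finer fixed-step RK4 oracle", {
  p <- kinetic_parameters(kn = 1e-5, kp = 50, km = 1e-4, KE = 10)
  for (init in list(initial_conditions(10),
                    seeded_initial_conditions(1, 100, 10))) {
    times <- seq(0, 60, 0.5)
    got <- simulate_mass_curve(p, init, times, rtol = 1e-10, atol = 1e-12)
    ref <- rk4_mass_oracle(p, init, times, refine = 10L)
    scale <- max(ref$M)
    expect_lt(max(abs(got$M_uM - ref$M)) / scale, 1e-6)
    expect_lt(max(abs(got$P_uM - ref$P)) / max(ref$P), 1e-6)
  }
})

test_that("mass is conserved and M, P are monotone along trajectories", {
  cases <- list(
    list(p = kinetic_parameters(1e-5, 50, 1e-4, 10),
         i = initial_conditions(10)),
    list(p = kinetic_parameters(1e-6, 200, 1e-3, 0.5),
         i = initial_conditions(40)),
    list(p = kinetic_parameters(1e-8, 50, 8e-6, 2),
         i = seeded_initial_conditions(1, 100, 10)))
  for (cs in cases) {
    tj <- simulate_mass_curve(cs$p, cs$i, seq(0, 2000, 5))
    total <- cs$i$m0 + cs$i$M0
    expect_lt(max(abs(tj$m_uM + tj$M_uM - total)) / total, 1e-8)
    expect_true(all(diff(tj$M_uM) > -1e-9 * total))
    expect_true(all(diff(tj$P_uM) > -1e-12))
    expect_true(all(tj$M_uM <= total + 1e-8 * total))
  }
})

test_that("early-time fibril mass follows kn*kp*m0^3 * t^2", {
  # km = 0, KE >> m0, nc = 2: M(t) ~ kn*kp*m0^3 * t^2 as t -> 0
  kn <- 1e-5; kp <- 10; m0 <- 10
  p <- kinetic_parameters(kn, kp, 0, KE = 1e5)
  ts <- seq(0, 0.2, 0.01)
  tj <- simulate_mass_curve(p, initial_conditions(m0), ts,
                            rtol = 1e-12, atol = 1e-14)
  pred <- kn * kp * m0^3 * ts^2
  i <- length(ts)
  expect_lt(abs(tj$M_uM[i] / pred[i] - 1), 0.01)
})

test_that("unseeded trajectories are degenerate under (c*kn, kp/c, c*km)", {
  base <- kinetic_parameters(1e-5, 50, 1e-4, 10)
  times <- seq(0, 500, 2)
  ref <- simulate_mass_curve(base, initial_conditions(10), times)
  for (cc in c(0.1, 10)) {
    alt <- kinetic_parameters(cc * base$kn, base$kp / cc, cc * base$km,
                              base$KE)
    got <- simulate_mass_curve(alt, initial_conditions(10), times)
    expect_lt(max(abs(got$M_uM - ref$M_uM)) / max(ref$M_uM), 1e-6)
  }
  # with seeds the same transformation changes M(t)
  seed <- seeded_initial_conditions(1, 100, 10)
  sref <- simulate_mass_curve(base, seed, times)
  alt <- kinetic_parameters(10 * base$kn, base$kp / 10, 10 * base$km,
                            base$KE)
  sgot <- simulate_mass_curve(alt, seed, times)
  expect_gt(max(abs(sgot$M_uM - sref$M_uM)) / max(sref$M_uM), 1e-3)
})

test_that("seeded initial conditions divide seed mass by seed length", {
  expect_equal(seeded_initial_conditions(1, 100, 10)$P0, 0.01)
  expect_equal(seeded_initial_conditions(0, 100, 10)$P0, 0)
  expect_equal(seeded_initial_conditions(0.5, 50, 10)$P0, 0.01)
})

test_that("trajectory export round-trips through CSV and JSON", {
  p <- kinetic_parameters(1e-5, 50, 1e-4, 10)
  tj <- simulate_mass_curve(p, initial_conditions(10), seq(0, 100, 5))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_trajectory_csv(tj, csv, params_json = js)
  back <- utils::read.csv(csv)
  expect_equal(back$M_uM, tj$M_uM, tolerance = 1e-12)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$parameters$kp$value, 50)
  expect_equal(meta$parameters$kp$units, "uM^-1.min^-1")
  unlink(c(csv, js))
})
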