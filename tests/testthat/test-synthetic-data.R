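test_that("generators are pure functions of spec and seed", {
  sp <- scenario_spec(m0_series = c(5, 10), replicates = 2,
                      sampling = list(dt = 20, duration = 1000))
  d1 <- generate_aggregation_dataset(sp, noise_spec(0.02, "relative", 42))
  d2 <- generate_aggregation_dataset(sp, noise_spec(0.02, "relative", 42))
  expect_identical(lapply(d1$traces, `[[`, "M"),
                   lapply(d2$traces, `[[`, "M"))
  d3 <- generate_aggregation_dataset(sp, noise_spec(0.02, "relative", 43))
  expect_false(identical(d1$traces[[1]]$M, d3$traces[[1]]$M))

  t1 <- generate_titration(7.6, noise = noise_spec(0.02, "relative", 1))
  t2 <- generate_titration(7.6, noise = noise_spec(0.02, "relative", 1))
  expect_identical(t1$anisotropy, t2$anisotropy)
})

test_that("zero noise reproduces the model curves exactly", {
  sp <- scenario_spec(m0_series = 10, replicates = 1,
                      sampling = list(dt = 10, duration = 1000))
  ds <- generate_aggregation_dataset(sp, noise_spec(0))
  tr <- ds$traces[[1]]
  ref <- simulate_mass_curve(default_baseline_params(),
                             initial_conditions(10), tr$times)
  expect_equal(tr$M, ref$M_uM, tolerance = 1e-12)

  # exact midpoint at c = KD when the grid contains KD
  tc <- generate_titration(7.6, conc_grid = c(0, 1, 2, 5, 7.6, 10, 20, 50),
                           noise = noise_spec(0))
  truth <- attr(tc, "truth")
  mid <- truth$r_free + (truth$r_bound - truth$r_free) / 2
  expect_equal(tc$anisotropy[tc$ligand_conc == 7.6], mid, tolerance = 1e-12)

  q <- 1.8e7
  ac <- generate_autocorrelation(0.9, 4.46e-12, q, noise = noise_spec(0))
  expect_equal(ac$g2, 1 + 0.9 * exp(-2 * 4.46e-12 * q^2 * ac$lags),
               tolerance = 1e-12)
  # zero-lag identity g2(0) = 1 + beta
  ac0 <- generate_autocorrelation(0.9, 4.46e-12, q,
                                  lag_grid = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                                  noise = noise_spec(0))
  expect_equal(ac0$g2[1], 1.9)

  tab <- generate_nmr_table(footprints = list(), noise = noise_spec(0))
  expect_true(all(tab$I / tab$I0 == 1))
})

test_that("replicate averaging shrinks DLS noise by about sqrt(n)", {
  q <- 1.8e7
  model <- function(reps, seed) {
    ac <- generate_autocorrelation(0.9, 4.46e-12, q,
                                   noise = noise_spec(0.02, "relative", seed),
                                   replicates = reps)
    ac$g2 - (1 + 0.9 * exp(-2 * 4.46e-12 * q^2 * ac$lags))
  }
  sd1 <- stats::sd(unlist(lapply(1:40, function(s) model(1L, s))))
  sd20 <- stats::sd(unlist(lapply(1:40, function(s) model(20L, 100 + s))))
  expect_equal(sd1 / sd20, sqrt(20), tolerance = 0.25)
})

test_that("chaperone scenarios scale the stated microscopic rates", {
  eff <- data.frame(chaperone_uM = c(0, 5), fn = c(1, 0.1), fp = 1, fm = 1)
  sp <- scenario_spec(chaperone = "DNAJB1", chaperone_effects = eff,
                      replicates = 1, sampling = list(dt = 10,
                                                      duration = 1000))
  ds <- generate_aggregation_dataset(sp, noise_spec(0))
  base <- default_baseline_params()
  tr5 <- Filter(function(tr) tr$condition$chaperone_conc == 5, ds$traces)[[1]]
  ref <- simulate_mass_curve(
    kinetic_parameters(base$kn * 0.1, base$kp, base$km, base$KE),
    initial_conditions(10), tr5$times)
  expect_equal(tr5$M, ref$M_uM, tolerance = 1e-12)
  # effects table must include the zero-chaperone anchor with unit factors
  expect_error(scenario_spec(chaperone = "DNAJB1",
                             chaperone_effects = data.frame(
                               chaperone_uM = 5, fn = 0.1, fp = 1, fm = 1)),
               "0 uM row")
})

test_that("generated plate CSVs round-trip through the trace readers", {
  sp <- scenario_spec(m0_series = c(5, 10), replicates = 2,
                      sampling = list(dt = 20, duration = 1000))
  ds <- generate_aggregation_dataset(sp, noise_spec(0.01, "relative", 3),
                                     as_raw = TRUE, Smax_inf = 1000)
  f <- tempfile(fileext = ".csv")
  write_traces_csv(ds$traces, f)
  back <- read_traces_csv(f)
  expect_length(back, 4)
  expect_s3_class(back[[1]], "raw_trace")
  orig <- vapply(ds$traces, function(tr)
    paste(tr$condition$m0, tr$condition$replicate), "")
  got <- vapply(back, function(tr)
    paste(tr$condition$m0, tr$condition$replicate), "")
  expect_setequal(got, orig)
  i <- match(orig[1], got)
  expect_equal(back[[i]]$signal, ds$traces[[1]]$signal, tolerance = 1e-9)
  unlink(f)

  # raw emission inverts the signal-to-mass conversion
  masses <- signal_to_mass(ds$traces, conversion_spec(10, 1000))
  noisefree <- generate_aggregation_dataset(sp, noise_spec(0))
  expect_equal(masses[[1]]$M, noisefree$traces[[1]]$M, tolerance = 0.1)
})

test_that("ground truth records travel with every generated object", {
  ds <- generate_aggregation_dataset(
    scenario_spec(m0_series = 10, replicates = 1,
                  sampling = list(dt = 20, duration = 1000)),
    noise_spec(0.01, "relative", 2))
  truth <- attr(ds, "truth")
  expect_equal(truth$kn_prime, 8.2e-7, tolerance = 1e-9)
  expect_equal(truth$km_prime, 4.1e-4, tolerance = 1e-9)
  expect_equal(attr(generate_titration(43), "truth")$KD, 43)
  tab <- generate_nmr_table()
  expect_equal(attr(tab, "truth")$footprints[[1]]$interval, c(275, 280))
})
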