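# noise-free synthetic world used across the fitting tests (kept small so
# each differential-evolution fit stays in the seconds range)
truth <- default_baseline_params()
times_unseeded <- seq(0, 2000, 10)
times_seeded <- seq(0, 300, 2)

unseeded_ds <- kinetic_dataset(lapply(c(2.5, 5, 10, 20, 40), function(m0)
  sim_trace(truth, m0, times_unseeded)))

test_that("unseeded global fit recovers the reduced rates (noise-free)", {
  fit <- fit_unseeded_global(unseeded_ds, settings = fast_settings(2))
  expect_lt(abs(fit$rates$kn_prime / (truth$kn * truth$kp) - 1), 0.05)
  expect_lt(abs(fit$rates$km_prime / (truth$km * truth$kp) - 1), 0.05)
  expect_lt(abs(fit$rates$KE / truth$KE - 1), 0.05)
  expect_lt(fit$rmse, 0.05)
})

test_that("unseeded fit is invariant under the kp degeneracy transform", {
  # datasets generated with (c*kn, kp/c, c*km) are identical, so the fitted
  # reduced rates coincide
  cc <- 10
  alt <- kinetic_parameters(cc * truth$kn, truth$kp / cc, cc * truth$km,
                            truth$KE)
  alt_ds <- kinetic_dataset(lapply(c(2.5, 5, 10, 20, 40), function(m0)
    sim_trace(alt, m0, times_unseeded)))
  f1 <- fit_unseeded_global(unseeded_ds, settings = fast_settings(3, 40L))
  f2 <- fit_unseeded_global(alt_ds, settings = fast_settings(3, 40L))
  expect_equal(f1$rates$kn_prime, f2$rates$kn_prime, tolerance = 1e-6)
  expect_equal(f1$rates$km_prime, f2$rates$km_prime, tolerance = 1e-6)
})

test_that("fits are bit-reproducible with a fixed seed and refuse bad input", {
  small <- kinetic_dataset(unseeded_ds$traces[3])
  expect_error(fit_unseeded_global(small), "underdetermined")
  f1 <- fit_unseeded_global(unseeded_ds, settings = fast_settings(9, 15L))
  f2 <- fit_unseeded_global(unseeded_ds, settings = fast_settings(9, 15L))
  expect_identical(f1$rates, f2$rates)
})

test_that("a null fragmentation rate is recovered as negligible", {
  nofrag <- kinetic_parameters(truth$kn, truth$kp, 0, truth$KE)
  ds <- kinetic_dataset(lapply(c(2.5, 5, 10, 20, 40), function(m0)
    sim_trace(nofrag, m0, seq(0, 6000, 30))))
  fit <- fit_unseeded_global(ds, settings = fast_settings(4))
  # recovered fragmentation composite at least 100x below the value the
  # baseline (fragmenting) world carries
  expect_lt(fit$rates$km_prime, 1e-2 * truth$km * truth$kp)
  expect_lt(abs(fit$rates$kn_prime / (truth$kn * truth$kp) - 1), 0.1)
})

test_that("seeded global fit pins down the absolute elongation rate", {
  red <- reduced_rates(truth$kn * truth$kp, truth$km * truth$kp, truth$KE)
  seeded_ds <- kinetic_dataset(lapply(1:2, function(r)
    sim_trace(truth, 10, times_seeded, M0 = 1, L = 100, replicate = r)))
  fit <- fit_seeded_global(seeded_ds, red, L = 100)
  expect_lt(abs(fit$rates$kp / truth$kp - 1), 0.10)
  # composites preserved by construction
  expect_equal(fit$rates$kn * fit$rates$kp, red$kn_prime, tolerance = 1e-9)
  expect_equal(fit$rates$km * fit$rates$kp, red$km_prime, tolerance = 1e-9)

  expect_error(fit_seeded_global(unseeded_ds, red, L = 100),
               "no seeded traces")
  expect_error(fit_seeded_global(seeded_ds, red, L = -1), "positive")
})

test_that("halving seed number by doubling L is compensated by kp", {
  red <- reduced_rates(truth$kn * truth$kp, truth$km * truth$kp, truth$KE)
  seeded_ds <- kinetic_dataset(list(
    sim_trace(truth, 10, times_seeded, M0 = 1, L = 100)))
  f100 <- fit_seeded_global(seeded_ds, red, L = 100)
  f200 <- fit_seeded_global(seeded_ds, red, L = 200)
  # kp * P0 (initial elongation flux) should be stable within 15%
  flux100 <- f100$rates$kp / 100
  flux200 <- f200$rates$kp / 200
  expect_lt(abs(flux200 / flux100 - 1), 0.15)
  expect_gt(f200$rates$kp, f100$rates$kp)
})

test_that("single-rate chaperone fits recover the perturbed rate and factor", {
  doses <- c(0, 2, 5)
  kp_factors <- c(1, 0.3, 0.1)
  ds_kp <- kinetic_dataset(unlist(lapply(seq_along(doses), function(i) {
    pert <- kinetic_parameters(truth$kn, truth$kp * kp_factors[i], truth$km,
                               truth$KE)
    lapply(1, function(r) sim_trace(pert, 10, times_unseeded,
                                    chaperone = "HSPB1", conc = doses[i]))
  }), recursive = FALSE))
  eff_kp <- fit_chaperone_single_rate(ds_kp, truth, "kp")
  eff_kn <- fit_chaperone_single_rate(ds_kp, truth, "kn")
  # zero-chaperone condition: factor 1 within 2%
  expect_lt(abs(eff_kp$effects$fp[1] - 1), 0.02)
  # true mechanism recovered within 10%
  expect_lt(abs(eff_kp$effects$fp[3] / 0.1 - 1), 0.10)
  # the wrong hypothesis fits demonstrably worse at the strongest dose
  expect_lt(eff_kp$effects$rmse_uM[3], 0.5 * eff_kn$effects$rmse_uM[3])
})

test_that("hypothesis comparison ranks by pooled RMSE with parsimony ties", {
  mk <- function(hyp, nfree, rmse) structure(list(
    chaperone = "X", hypothesis = hyp, n_free = nfree,
    effects = data.frame(chaperone_uM = c(0, 5), fn = 1, fp = 1, fm = 1,
                         rmse_uM = rmse, n_points = c(100, 100))),
    class = "chaperone_effect")
  cmp <- compare_rate_hypotheses(list(mk("kn-only", 1L, c(0.4, 0.4)),
                                      mk("kp-only", 1L, c(0.1, 0.1))))
  expect_equal(cmp$hypothesis[1], "kp-only")
  expect_equal(cmp$rmse_ratio[2], 4, tolerance = 1e-9)

  tie <- compare_rate_hypotheses(list(mk("joint-kn-kp", 2L, c(0.1, 0.1)),
                                      mk("kp-only", 1L, c(0.1, 0.1))))
  expect_equal(tie$hypothesis[1], "kp-only") # fewer free parameters wins
  expect_true(all(tie$tied_with_best))

  bad <- mk("kp-only", 1L, c(0.1, 0.1))
  bad$effects$n_points <- c(50, 50)
  expect_error(compare_rate_hypotheses(list(mk("kn-only", 1L, c(0.1, 0.1)),
                                            bad)),
               "same trace sets")
})

test_that("joint fits recover simultaneous factors and respect null effects", {
  pert <- kinetic_parameters(truth$kn * 0.2, truth$kp * 0.3, truth$km,
                             truth$KE)
  ds <- kinetic_dataset(list(
    sim_trace(truth, 10, times_unseeded, chaperone = "DNAJA2", conc = 0),
    sim_trace(truth, 10, times_seeded, M0 = 1, L = 100,
              chaperone = "DNAJA2", conc = 0),
    sim_trace(pert, 10, times_unseeded, chaperone = "DNAJA2", conc = 5),
    sim_trace(pert, 10, times_seeded, M0 = 1, L = 100,
              chaperone = "DNAJA2", conc = 5)))
  eff <- fit_chaperone_joint(ds, truth, L = 100, fit_km = FALSE,
                             settings = fast_settings(5, 40L))
  expect_lt(abs(eff$effects$fn[1] - 1), 0.05)
  expect_lt(abs(eff$effects$fp[1] - 1), 0.05)
  expect_lt(abs(eff$effects$fn[2] / 0.2 - 1), 0.20)
  expect_lt(abs(eff$effects$fp[2] / 0.3 - 1), 0.20)
})

test_that("replicate-set error estimation follows the half-difference rule", {
  ds <- kinetic_dataset(unseeded_ds$traces[c(1, 2, 3, 1, 2, 3)],
                        replicate_sets = rep(c("A", "B"), each = 3))
  # duplicated identical sets give zero uncertainty
  res <- estimate_rate_errors(ds, function(d)
    c(knp = fit_unseeded_global(d, settings = fast_settings(6, 15L))$
        rates$kn_prime))
  expect_equal(unname(res$uncertainty), 0)

  # hand arithmetic on the half-difference rule via a stub fit
  stub_env <- new.env()
  stub_env$i <- 0
  stub <- function(d) {
    stub_env$i <- stub_env$i + 1
    c(knp = c(1.0, 1.1)[stub_env$i])
  }
  res2 <- estimate_rate_errors(ds, stub)
  expect_equal(unname(res2$uncertainty), 0.05)

  one_set <- kinetic_dataset(unseeded_ds$traces[1:3])
  expect_error(estimate_rate_errors(one_set, stub), "2 replicate sets")
})
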