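test_that("one-site fit identities: midpoint, flat curves, KD recovery", {
  cc <- c(0, 0.25, 0.5, 1, 1.7, 2.5, 5, 10)
  r <- 0.05 + 0.15 * cc / (1.7 + cc)
  fit <- fit_one_site(titration_curve(cc, r))
  expect_lt(abs(fit$KD / 1.7 - 1), 0.01)
  # at c = KD the signal sits exactly halfway between free and bound
  mid <- fit$r_free + (fit$r_bound - fit$r_free) * 1.7 / (fit$KD + 1.7)
  expect_equal(mid, (fit$r_free + fit$r_bound) / 2, tolerance = 1e-6)

  flat <- fit_one_site(titration_curve(cc, rep(0.05, length(cc))))
  expect_false(flat$identifiable)
  expect_true(is.na(flat$KD))
})

test_that("KD recovery across the experimental affinity range", {
  # titrations spanning 0.1-3x KD at 2 percent amplitude noise; the weakest
  # site is measured on a range that truncates saturation
  kds <- c(1.7, 7.6, 43)
  for (i in seq_along(kds)) {
    kd <- kds[i]
    grid <- kd * c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3)
    tc <- generate_titration(kd, conc_grid = grid,
                             noise = noise_spec(0.02, "relative", 100 + i))
    fit <- fit_one_site(tc)
    expect_true(fit$identifiable)
    expect_lt(abs(fit$KD / kd - 1), 0.10)
  }
  grid250 <- c(0, 10, 25, 50, 100, 150, 200, 250, 300)
  tc <- generate_titration(250, conc_grid = grid250,
                           noise = noise_spec(0.02, "relative", 104))
  fit <- fit_one_site(tc)
  expect_lt(abs(fit$KD / 250 - 1), 0.25)
})

test_that("quadratic (ligand-depletion) form matches hyperbolic when labeled << KD", {
  cc <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  tc <- generate_titration(7.6, conc_grid = cc, noise = noise_spec(0))
  h <- fit_one_site(tc)
  q <- fit_one_site(tc, quadratic = TRUE)
  expect_lt(abs(q$KD / h$KD - 1), 0.02)
})

test_that("combined chemical shift perturbation follows the 1H/15N norm", {
  tab <- peak_table(1:5, delta_H = c(0, 0.1, 0, -0.1, 0.02),
                    delta_N = c(0, 0.5, 0.5, -0.5, 0))
  csp <- compute_csp(tab)
  expect_equal(csp$csp[1], 0)
  expect_equal(csp$csp[2], sqrt(0.01 + 0.01), tolerance = 1e-12) # 0.1414
  expect_equal(csp$csp[3], 0.1)
  # symmetric in the sign of the shift differences
  expect_equal(csp$csp[4], csp$csp[2])
  # invariant to residue ordering
  shuf <- peak_table(c(3, 1, 5, 2, 4), delta_H = c(0, 0, 0.02, 0.1, -0.1),
                     delta_N = c(0.5, 0, 0, 0.5, -0.5))
  csp2 <- compute_csp(shuf)
  expect_equal(csp2$csp[order(csp2$residue)], csp$csp)
})

test_that("CSP significance uses the mean + 1 SD rule", {
  same <- data.frame(residue = 1:6, csp = rep(0.1, 6))
  expect_false(any(flag_significant_csp(same)))

  vals <- data.frame(residue = 1:10, csp = c(rep(0.1, 9), 0.3))
  # mean 0.12, sd ~0.0632, threshold ~0.183: only the 0.3 residue flags
  flags <- flag_significant_csp(vals)
  expect_identical(which(flags), 10L)

  one_big <- data.frame(residue = 1:100, csp = c(rep(0.01, 99), 0.5))
  expect_identical(which(flag_significant_csp(one_big)), 100L)
})

test_that("intensity-ratio profiles flag attenuation and apply the 0.5 rule", {
  tab <- peak_table(1:10, I = rep(1000, 10), I0 = rep(1000, 10))
  prof <- intensity_ratio_profile(tab)
  expect_true(all(prof$ratio == 1))
  expect_false(any(prof$significant))

  tab2 <- peak_table(1:10, I = c(rep(900, 9), 400), I0 = rep(1000, 10))
  prof2 <- intensity_ratio_profile(tab2)
  expect_equal(prof2$ratio[10], 0.4)
  expect_true(prof2$strong[10])
  expect_false(any(prof2$strong[1:9]))

  tab3 <- peak_table(1:6, I = rep(500, 6), I0 = c(rep(1000, 5), 0))
  expect_warning(p3 <- intensity_ratio_profile(tab3), "I0 = 0")
  expect_equal(nrow(p3), 5)
})

test_that("region calling reports maximal runs and bridges single gaps", {
  empty <- data.frame(residue = 1:20, significant = FALSE)
  expect_equal(nrow(call_binding_regions(empty)), 0)

  prof <- data.frame(residue = 270:290,
                     significant = 270:290 %in% 275:280)
  expect_equal(call_binding_regions(prof),
               data.frame(start = 275L, end = 280L))

  gappy <- data.frame(residue = 270:290,
                      significant = 270:290 %in% c(275:277, 279:280))
  expect_equal(call_binding_regions(gappy, bridge_gaps = TRUE),
               data.frame(start = 275L, end = 280L))
  expect_equal(call_binding_regions(gappy, bridge_gaps = FALSE)$start, 275L)
  expect_equal(call_binding_regions(gappy, bridge_gaps = FALSE)$end, 277L)

  short <- data.frame(residue = 1:10, significant = 1:10 %in% 4:5)
  expect_equal(nrow(call_binding_regions(short, min_run = 3)), 0)
})

test_that("synthetic rectangular footprints are recovered exactly", {
  tab <- generate_nmr_table(noise = noise_spec(0.02, "relative", 7))
  prof <- intensity_ratio_profile(tab)
  regions <- call_binding_regions(prof)
  expect_equal(regions, data.frame(start = c(275L, 306L),
                                   end = c(280L, 311L)))
  # the same footprints carry significant CSPs
  csp <- compute_csp(tab)
  flags <- flag_significant_csp(csp)
  expect_true(all(csp$residue[flags] %in% c(275:280, 306:311)))
})
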