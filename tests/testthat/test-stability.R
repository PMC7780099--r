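test_that("a noiseless Arrhenius series is recovered exactly", {
  s <- simulate_inactivation(200, 80, noise_sd = 0, seed = 1)
  fit <- fit_arrhenius(s)
  expect_equal(fit$ea_kj, 200, tolerance = 1e-6)
  expect_equal(fit$lnA, 80, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("Ea is recovered within 5% under 5% lognormal noise (n = 8)", {
  s <- simulate_inactivation(280, 104, noise_sd = 0.05, seed = 17)
  fit <- fit_arrhenius(s)
  expect_lt(abs(fit$ea_kj - 280) / 280, 0.05)
})

test_that("Arrhenius preconditions are enforced", {
  expect_error(fit_arrhenius(inactivation_series(c(10, 20), c(1e-4, 2e-4))),
               "at least 3")
  expect_error(inactivation_series(c(10, 20, 30), c(1e-4, -1, 1e-3)),
               "positive")
  expect_error(inactivation_series(c(10, 10, 30), c(1e-4, 2e-4, 1e-3)),
               "distinct")
})

test_that("T50 inverts the Arrhenius law at the 30-minute half-loss rate", {
  k_half <- log(2) / 1800
  expect_equal(k_half, 3.8508e-4, tolerance = 1e-4)

  # constructed so the solution is exactly 25 C
  ea <- 250
  lnA <- log(k_half) + ea * 1000 / (8.314 * 298.15)
  fit <- structure(list(ea_kj = ea, lnA = lnA, r_squared = 1, n_points = 8),
                   class = "ArrheniusFit")
  expect_equal(t50_from_fit(fit)$t50_C, 25.0, tolerance = 1e-9)

  # agreement with direct numeric root-finding over a parameter grid
  for (ea in c(80, 150, 280, 400)) {
    for (lnA_off in c(10, 30, 60)) {
      lnA <- log(k_half) + lnA_off
      fit <- structure(list(ea_kj = ea, lnA = lnA, r_squared = 1, n_points = 5),
                       class = "ArrheniusFit")
      expect_equal(t50_from_fit(fit)$t50_C, oracle_t50(ea, lnA),
                   tolerance = 0.01)
    }
  }

  # doubling Ea at fixed lnA moves T50 the way the root-finder says
  lnA <- log(k_half) + 40
  t1 <- t50_from_fit(structure(list(ea_kj = 150, lnA = lnA), class = "ArrheniusFit"))$t50_C
  t2 <- t50_from_fit(structure(list(ea_kj = 300, lnA = lnA), class = "ArrheniusFit"))$t50_C
  expect_equal(sign(t2 - t1), sign(oracle_t50(300, lnA) - oracle_t50(150, lnA)))

  bad <- structure(list(ea_kj = 100, lnA = log(k_half) - 1), class = "ArrheniusFit")
  expect_error(t50_from_fit(bad), "no finite")
})

test_that("two-state melt fits recover the planted midpoint", {
  clean <- simulate_melt(tm_C = 50.8, noise_sd = 0, seed = 1)
  fit <- fit_two_state_melt(clean)
  expect_equal(fit$tm_C, 50.8, tolerance = 0.1)
  fu <- fit$fraction_unfolded
  expect_true(all(fu$f_u >= 0 & fu$f_u <= 1))
  # F_U crosses one half at the fitted midpoint
  below <- max(fu$temperature_C[fu$f_u < 0.5])
  above <- min(fu$temperature_C[fu$f_u > 0.5])
  expect_true(below <= fit$tm_C && fit$tm_C <= above)

  noisy <- simulate_melt(tm_C = 50.8, noise_sd = 0.36, seed = 5)  # 2% of amplitude
  expect_equal(fit_two_state_melt(noisy)$tm_C, 50.8, tolerance = 0.5)
})

test_that("melt fits are invariant to linear rescaling of the signal", {
  curve <- simulate_melt(tm_C = 44.2, noise_sd = 0.2, seed = 9)
  fit1 <- fit_two_state_melt(curve)
  scaled <- melt_curve(curve$temperature_C, 3.7 * curve$signal + 12)
  fit2 <- fit_two_state_melt(scaled)
  expect_equal(fit1$tm_C, fit2$tm_C, tolerance = 1e-4)
})

test_that("melt preconditions reject unusable traces", {
  expect_error(melt_curve(c(30, 20, 40), c(1, 2, 3)), "increasing")
  flat <- melt_curve(seq(20, 90, 5), rep(1, 15))
  expect_error(fit_two_state_melt(flat), "flat|transition")
  short <- melt_curve(seq(20, 26, 1), rnorm(7))
  expect_error(fit_two_state_melt(short), "at least 8")
})

test_that("Michaelis-Menten fits recover planted constants", {
  clean <- simulate_mm(kcat = 302, km_mM = 0.19, noise_sd = 0, seed = 1)
  fit <- fit_michaelis_menten(clean, enzyme_conc = 1)
  expect_equal(fit$kcat, 302, tolerance = 1e-4)
  expect_equal(fit$km_mM, 0.19, tolerance = 1e-6)

  noisy <- simulate_mm(kcat = 302, km_mM = 0.19, noise_sd = 0.05, seed = 23)
  fitn <- fit_michaelis_menten(noisy, enzyme_conc = 1)
  expect_lt(abs(fitn$kcat - 302) / 302, 0.10)
  expect_lt(abs(fitn$km_mM - 0.19) / 0.19, 0.15)
  # catalytic efficiency is recovered at least as well as its parts
  expect_lt(abs(fitn$kcat / fitn$km_mM - 302 / 0.19) / (302 / 0.19), 0.15)
})

test_that("saturating data far below KM yields large uncertainties, loudly", {
  low <- simulate_mm(kcat = 300, km_mM = 50,
                     substrate_mM = c(0.01, 0.02, 0.04, 0.08, 0.16),
                     noise_sd = 0.03, seed = 4)
  fit <- fit_michaelis_menten(low)
  expect_gt(fit$km_se / fit$km_mM, 0.2)   # no silent confident estimate
})

test_that("stability CSVs are schema-detected and validated", {
  d <- withr::local_tempdir()
  inact <- file.path(d, "inact.csv")
  s <- simulate_inactivation(280, 104, noise_sd = 0, seed = 1)
  write.csv(data.frame(temperature_C = s$temperature_C, k_per_s = s$k),
            inact, row.names = FALSE)
  got <- read_stability_csv(inact)
  expect_equal(got$schema, "inactivation")
  expect_equal(fit_arrhenius(got$data)$ea_kj, 280, tolerance = 1e-6)

  melt <- file.path(d, "melt.csv")
  mc <- simulate_melt(noise_sd = 0, seed = 1)
  write.csv(data.frame(temperature_C = mc$temperature_C, signal = mc$signal),
            melt, row.names = FALSE)
  expect_equal(read_stability_csv(melt)$schema, "melt")

  amb <- file.path(d, "amb.csv")
  write.csv(data.frame(temperature_C = 1:5, k_per_s = 1:5, signal = 1:5),
            amb, row.names = FALSE)
  expect_error(read_stability_csv(amb), "ambiguous")

  bad <- file.path(d, "bad.csv")
  writeLines(c("temperature_C,k_per_s", "10,1e-4", "11,oops"), bad)
  expect_error(read_stability_csv(bad), "line 3")

  unknown <- file.path(d, "unknown.csv")
  write.csv(data.frame(a = 1:3, b = 1:3), unknown, row.names = FALSE)
  expect_error(read_stability_csv(unknown), "unrecognized")
})
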