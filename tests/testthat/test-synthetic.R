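test_that("generation is a pure function of spec and seed", {
  g1 <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 31))
  g2 <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 31))
  expect_identical(g1$model$atoms, g2$model$atoms)
  expect_identical(g1$truth$trace_chain_b, g2$truth$trace_chain_b)
  g3 <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 32))
  expect_false(identical(g1$model$atoms, g3$model$atoms))
})

test_that("an undisplaced spec yields a perfectly symmetric dimer", {
  gen <- helix_dimer(n = 30)
  expect_equal(max(gen$truth$trace_chain_b$displacement), 0)
  res <- superpose_chains(gen$model, "A", "B")
  expect_lt(max(res$trace$distance), 1e-6)
})

test_that("planted interaction distances are realized exactly", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 13))
  planted <- gen$truth$interactions
  expect_gt(nrow(planted), 40)   # both symmetric copies
  expect_lt(max(abs(planted$realized - planted$target)), 1e-9)
})

test_that("ground truth survives a PDB round trip", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 8))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(gen$model, f)
  m2 <- read_structure(f)
  planted <- gen$truth$interactions
  for (i in seq_len(nrow(planted))) {
    a1 <- select_residue(m2, planted$chain1[i], planted$res1[i])
    a2 <- select_residue(m2, planted$chain2[i], planted$res2[i])
    p1 <- as.numeric(a1[a1$atom == planted$atom1[i], c("x", "y", "z")])
    p2 <- as.numeric(a2[a2$atom == planted$atom2[i], c("x", "y", "z")])
    expect_equal(sqrt(sum((p1 - p2)^2)), planted$target[i], tolerance = 2e-3)
  }
})

test_that("conflicting planted constraints fail generation", {
  spec <- toy_dimer_spec(
    n_res = 12, geometry = "ideal-helix",
    interactions = list(
      list(chain1 = "A", res1 = 2L, atom1 = "N", chain2 = "A", res2 = 6L,
           atom2 = "O", target = 2.8, kind = "strong-hbond"),
      list(chain1 = "A", res1 = 2L, atom1 = "N", chain2 = "A", res2 = 6L,
           atom2 = "O", target = 4.5, kind = "weak-hbond")),
    seed = 1)
  expect_error(make_toy_dimer(spec), "conflict")
})

test_that("impossible water bridges are rejected", {
  spec <- toy_dimer_spec(
    n_res = 10, geometry = "ideal-helix",
    waters = list(list(chain1 = "A", res1 = 1L, atom1 = "N", chain2 = "A",
                       res2 = 9L, atom2 = "O", leg = 2.0)),
    seed = 1)
  expect_error(make_toy_dimer(spec), "water bridge")
})

test_that("planted target distances below the clash floor are rejected", {
  expect_error(toy_dimer_spec(
    interactions = list(list(chain1 = "A", res1 = 1L, atom1 = "OG",
                             chain2 = "B", res2 = 2L, atom2 = "OG",
                             target = 1.5, kind = "strong-hbond"))),
    ">= 2.2")
})

test_that("inactivation simulation is exact at zero noise and seed-stable", {
  s0 <- simulate_inactivation(280, 104, noise_sd = 0, seed = 3)
  expect_equal(log(s0$k), 104 - 280e3 / (8.314 * s0$temperature_K),
               tolerance = 1e-12)
  s1 <- simulate_inactivation(280, 104, noise_sd = 0.05, seed = 3)
  s2 <- simulate_inactivation(280, 104, noise_sd = 0.05, seed = 3)
  expect_identical(s1$k, s2$k)
  fit <- fit_arrhenius(s0)
  expect_equal(c(fit$ea_kj, fit$lnA), c(280, 104), tolerance = 1e-6)
})

test_that("melt simulation crosses one half exactly at the planted midpoint", {
  dense <- simulate_melt(tm_C = 50.8, noise_sd = 0,
                         temperatures_C = seq(20, 90, 0.1), seed = 1)
  fit <- fit_two_state_melt(dense)
  expect_equal(fit$tm_C, 50.8, tolerance = 0.01)
  expect_identical(simulate_melt(noise_sd = 0.3, seed = 6)$signal,
                   simulate_melt(noise_sd = 0.3, seed = 6)$signal)
  # sloped baselines do not bias the recovered midpoint at zero noise
  sloped <- simulate_melt(tm_C = 50.8, baseline_folded = c(-30, -0.15),
                          baseline_unfolded = c(5, -0.04), noise_sd = 0, seed = 1)
  expect_equal(fit_two_state_melt(sloped)$tm_C, 50.8, tolerance = 0.1)
})

test_that("kinetics simulation spans the assay range and round trips", {
  mm <- simulate_mm(noise_sd = 0, seed = 2)
  expect_gte(min(mm$substrate_mM), 0.0125)
  expect_lte(max(mm$substrate_mM), 1.0)
  fit <- fit_michaelis_menten(mm, enzyme_conc = 1)
  expect_equal(fit$kcat, 302, tolerance = 1e-4)
  expect_identical(simulate_mm(noise_sd = 0.05, seed = 7)$rate,
                   simulate_mm(noise_sd = 0.05, seed = 7)$rate)
})

test_that("ground-truth sidecars serialize to JSON and read back", {
  gen <- helix_dimer(n = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gen$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$seed, 1)
  expect_equal(back$geometry, "ideal-helix")
  expect_equal(length(back$trace_chain_b$resno), 10)
})
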