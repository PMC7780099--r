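bf_model <- function(values, chain = "A") {
  rows <- list()
  for (i in seq_along(values)) {
    rows <- c(rows, res_atoms(chain, i, c(4 * i, 0, 0), b = values[i]))
  }
  do.call(model_from_atoms, rows)
}

test_that("per-residue aggregation follows the selected atom set", {
  m <- bf_model(rep(20, 8))
  prof <- residue_bfactor_profile(m, "A")
  expect_equal(prof$value, rep(20, 8))

  # one residue with mainchain B {10, 20, 30, 40}
  rows <- res_atoms("A", 1, c(0, 0, 0))
  for (i in 1:4) rows[[i]]$b <- c(10, 20, 30, 40)[i]
  m2 <- do.call(model_from_atoms, rows)
  expect_equal(residue_bfactor_profile(m2, "A", "mainchain-mean")$value, 25)
  expect_equal(residue_bfactor_profile(m2, "A", "CA-only")$value, 20)
  expect_error(residue_bfactor_profile(m2, "B"), "no chain")
})

test_that("whole-structure protein mean B matches the planted profile", {
  gen <- make_toy_dimer(vap_dimer_spec("R336L", seed = 5))
  expect_equal(mean_structure_bfactor(gen$model),
               gen$truth$bfactor$mean_all_atom, tolerance = 1e-9)
})

test_that("max-normalization is exact, idempotent and scale invariant", {
  m <- bf_model(c(10, 20, 40))
  prof <- residue_bfactor_profile(m, "A")
  norm <- normalize_profile(prof)
  expect_equal(norm$value, c(0.25, 0.5, 1.0))
  expect_equal(attr(norm, "normalizer"), 40)
  expect_equal(normalize_profile(norm)$value, norm$value)

  scaled <- prof; scaled$value <- prof$value * 7.3
  expect_equal(normalize_profile(scaled)$value, norm$value)

  flat <- bf_model(rep(5, 12))
  expect_equal(normalize_profile(residue_bfactor_profile(flat, "A"))$value,
               rep(1, 12))
  zero <- prof; zero$value <- rep(0, 3)
  expect_error(normalize_profile(zero), "positive")
})

test_that("differential flexibility regions recover planted offsets", {
  base <- bf_model(rep(30, 120))
  px <- normalize_profile(residue_bfactor_profile(base, "A"))
  py <- px
  py$value[py$resno >= 81 & py$resno <= 100] <-
    py$value[py$resno >= 81 & py$resno <= 100] + 0.15

  cmp <- compare_flexibility(py, px, threshold = 0.1, min_run = 5)
  regions <- attr(cmp, "regions")
  expect_equal(nrow(regions), 1L)
  expect_equal(c(regions$start_resno, regions$end_resno), c(81, 100))
  expect_gte(regions$mean_abs_difference, 0.1)

  # antisymmetry
  rev <- compare_flexibility(px, py, threshold = 0.1, min_run = 5)
  expect_equal(rev$difference, -cmp$difference)
  expect_equal(attr(rev, "regions")$start_resno, regions$start_resno)

  # identical profiles and sub-threshold offsets flag nothing
  expect_equal(nrow(attr(compare_flexibility(px, px), "regions")), 0L)
  py2 <- px; py2$value <- px$value + 0.05
  expect_equal(nrow(attr(compare_flexibility(py2, px, threshold = 0.1),
                         "regions")), 0L)
})

test_that("planted B-factor bump regions are recovered within 2 residues", {
  wt <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 6))
  mut <- make_toy_dimer(vap_dimer_spec("R336L", seed = 7))
  px <- normalize_profile(residue_bfactor_profile(mut$model, "A"))
  py <- normalize_profile(residue_bfactor_profile(wt$model, "A"))
  regions <- attr(compare_flexibility(px, py, threshold = 0.1, min_run = 5),
                  "regions")
  expect_equal(nrow(regions), 2L)
  planted <- mut$truth$bfactor$bumps
  for (i in 1:2) {
    expect_lte(abs(regions$start_resno[i] - planted[[i]]$from), 2)
    expect_lte(abs(regions$end_resno[i] - planted[[i]]$to), 2)
  }
})

test_that("worm radii follow the 5th-95th percentile band", {
  m <- bf_model(1:100)
  prof <- normalize_profile(residue_bfactor_profile(m, "A"))
  w <- worm_scores(prof)
  expect_equal(w$radius[1:5], rep(0.3, 5))
  expect_equal(w$radius[96:100], rep(1.25, 5))
  expect_true(all(w$radius >= 0.3 & w$radius <= 1.25))

  flat <- worm_scores(normalize_profile(residue_bfactor_profile(bf_model(rep(3, 20)), "A")))
  expect_equal(flat$radius, rep(0.80, 20))
})

test_that("worm radius is non-decreasing in normalized B on random profiles", {
  set.seed(8)
  for (rep in 1:5) {
    m <- bf_model(runif(60, 5, 80))
    w <- worm_scores(normalize_profile(residue_bfactor_profile(m, "A")))
    ord <- order(w$value)
    expect_true(all(diff(w$radius[ord]) >= -1e-12))
  }
})

test_that("smoothing is a centered moving mean with shrinking ends", {
  m <- bf_model(c(0, 0, 9, 0, 0))
  prof <- residue_bfactor_profile(m, "A")
  sm <- smooth_profile(prof, window = 3)
  expect_equal(sm$value, c(0, 3, 3, 3, 0))
})
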