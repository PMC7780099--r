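test_that("kabsch_fit handles identity and pure translation exactly", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  same <- kabsch_fit(a, a)
  expect_lt(same$rmsd, 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  b <- sweep(a, 2, c(5, 0, 0), "+")
  fit <- kabsch_fit(a, b)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
})

test_that("kabsch_fit attains the brute-force optimum on noisy rotations", {
  set.seed(11)
  for (rep in 1:3) {
    a <- matrix(rnorm(30, sd = 4), 10, 3)
    rot <- rotation_about_axis(rnorm(3), runif(1, 10, 170))
    b <- a %*% t(rot) + matrix(rnorm(30, sd = 0.1), 10, 3)
    fit <- kabsch_fit(a, b)
    oracle <- oracle_rmsd(a, b)
    expect_lte(fit$rmsd, oracle + 1e-3)       # global optimality spot-check
    expect_lt(abs(fit$rmsd - oracle) / oracle, 0.10)
  }
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_fit(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_fit(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
})

test_that("rmsd is symmetric and invariant under rigid motions", {
  set.seed(21)
  a <- matrix(rnorm(45), 15, 3)
  b <- a %*% t(rotation_about_axis(c(1, 2, 3), 40)) +
    matrix(rnorm(45, sd = 0.3), 15, 3)
  r_ab <- kabsch_fit(a, b)$rmsd
  r_ba <- kabsch_fit(b, a)$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-6)

  pre <- rotation_about_axis(c(0, 0, 1), 77)
  b2 <- sweep(b %*% t(pre), 2, c(3, -4, 9), "+")
  expect_equal(kabsch_fit(a, b2)$rmsd, r_ab, tolerance = 1e-6)
})

test_that("a symmetric dimer superposes to a zero deviation trace", {
  gen <- helix_dimer(n = 25)
  res <- superpose_chains(gen$model, "A", "B")
  expect_lt(max(res$trace$distance), 1e-6)
  expect_lt(attr(res$trace, "mean"), 1e-6)
})

test_that("balanced planted displacements are recovered within 0.05 A", {
  spec <- toy_dimer_spec(
    n_res = 60, geometry = "extended",
    chain_b_bumps = list(list(range1 = c(10, 15), range2 = c(40, 45),
                              amplitude = 1.0)),
    seed = 5)
  gen <- make_toy_dimer(spec)
  res <- superpose_chains(gen$model, "A", "B")
  truth <- gen$truth$trace_chain_b$displacement
  expect_lt(max(abs(res$trace$distance - truth)), 0.05)
  peak <- res$trace$distance[res$trace$resno %in% 12:13]
  expect_equal(peak, rep(1.0, 2), tolerance = 0.05)
})

test_that("a free one-sided displacement is recovered up to the fit shift", {
  # an unbalanced rigid offset drags the least-squares fit by roughly
  # amplitude * planted fraction; recovery is correspondingly looser
  gen <- helix_dimer(n = 50, displacements =
                       list(list(from = 10, to = 15, offset = c(0, 1, 0))))
  res <- superpose_chains(gen$model, "A", "B")
  inside <- res$trace$resno %in% 10:15
  expect_gt(mean(res$trace$distance[inside]), 0.75)
  expect_lt(mean(res$trace$distance[!inside]), 0.25)
  expect_lt(max(abs(res$trace$distance[inside] - 1.0)), 0.3)
})

test_that("cross-structure comparison recovers the planted variant field", {
  wt <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 1))
  mut <- make_toy_dimer(vap_dimer_spec("R336L", seed = 2))
  self <- compare_structures(wt$model, "A", wt$model, "A")
  expect_lt(attr(self$trace, "mean"), 1e-9)

  res <- compare_structures(wt$model, "A", mut$model, "A")
  truth <- mut$truth$trace_chain_a$displacement
  expect_lt(max(abs(res$trace$distance - truth)), 0.05)
  expect_equal(attr(res$trace, "mean"), mut$truth$expected_mean_chain_a,
               tolerance = 0.02)
})

test_that("CA-only trace mean and rms bracket the fit rmsd consistently", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 4))
  res <- superpose_chains(gen$model, "A", "B", atom_set = "CA")
  m <- attr(res$trace, "mean")
  r <- attr(res$trace, "rms")
  expect_lte(m, r)                      # Jensen: mean <= root mean square
  expect_equal(r, res$fit$rmsd, tolerance = 1e-9)
})

test_that("deviation traces serialize with their fit header", {
  gen <- helix_dimer(n = 12)
  res <- superpose_chains(gen$model, "A", "B")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deviation_trace(res, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# rmsd_angstrom=", lines)))
  expect_true(any(grepl("^# atom_set=mainchain", lines)))
  body <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(body), 12L)
})
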