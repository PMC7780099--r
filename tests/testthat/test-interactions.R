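# Two-residue fixture: a serine donor on chain A, a backbone acceptor on
# chain B, with the OG placed at a controlled distance from B's O.
pair_model <- function(d) {
  og_xyz <- c(1.5 + 20, 1.23 + d, 0)   # B residue centred at x = 20
  rows <- c(res_atoms("A", 10, c(0, 0, 0), resname = "SER"),
            list(list(chain = "A", resno = 10, resname = "SER", atom = "OG",
                      xyz = og_xyz)),
            res_atoms("B", 30, c(20, 0, 0)))
  do.call(model_from_atoms, rows)
}

test_that("hydrogen bonds are classed purely by donor-acceptor distance", {
  hb <- detect_hbonds(pair_model(2.8))
  cross <- hb[hb$topology == "inter-chain" & hb$kind == "strong-hbond", ]
  expect_equal(nrow(cross), 1L)
  expect_equal(cross$distance, 2.8, tolerance = 1e-9)
  expect_equal(cross$backbone_class, "mainchain-sidechain")

  weak <- detect_hbonds(pair_model(4.0))
  cross_w <- weak[weak$topology == "inter-chain", ]
  expect_true(all(cross_w$kind == "weak-hbond"))
  expect_true(any(abs(cross_w$distance - 4.0) < 1e-9))
  none <- detect_hbonds(pair_model(5.5))
  expect_false(any(none$topology == "inter-chain" & none$distance > 5.4))

  expect_error(detect_hbonds(pair_model(3), d_strong = 6, d_weak_max = 5),
               "thresholds")
})

test_that("an ideal helix shows one i->i+4 backbone bond per turn residue", {
  n <- 18
  gen <- helix_dimer(n = n)
  hb <- detect_hbonds(gen$model)
  strong <- hb[hb$kind == "strong-hbond" & hb$topology == "intra-chain", ]
  for (ch in c("A", "B")) {
    sub <- strong[strong$chain1 == ch, ]
    expect_equal(nrow(sub), n - 4L)
    expect_true(all(abs(sub$resno2 - sub$resno1) == 4L))
    expect_true(all(sub$backbone_class == "mainchain-mainchain"))
  }
})

test_that("detection equals the exhaustive all-pairs oracle", {
  spec <- toy_dimer_spec(
    n_res = 14, geometry = "ideal-helix",
    residue_names = c("3" = "SER", "8" = "ASP", "12" = "LYS", "6" = "GLN"),
    interactions = list(
      list(chain1 = "A", res1 = 3L, atom1 = "OG", chain2 = "B", res2 = 12L,
           atom2 = "NZ", target = 2.8, kind = "strong-hbond"),
      list(chain1 = "A", res1 = 8L, atom1 = "OD1", chain2 = "B", res2 = 6L,
           atom2 = "NE2", target = 4.2, kind = "weak-hbond")),
    seed = 3)
  m <- make_toy_dimer(spec)$model
  expect_lt(nrow(m$atoms), 500L)

  hb <- detect_hbonds(m)
  oracle <- oracle_hbond_scan(m)
  expect_equal(
    edge_keys(hb, "chain1", "resno1", "atom1", "chain2", "resno2", "atom2"),
    edge_keys(oracle, "chain_i", "res_i", "atom_i", "chain_j", "res_j", "atom_j"))
  # and the class split matches pair by pair
  okeys <- edge_keys(oracle[oracle$kind == "strong-hbond", ],
                     "chain_i", "res_i", "atom_i", "chain_j", "res_j", "atom_j")
  hkeys <- edge_keys(hb[hb$kind == "strong-hbond", ],
                     "chain1", "resno1", "atom1", "chain2", "resno2", "atom2")
  expect_equal(hkeys, okeys)
})

test_that("edge sets are invariant to atom record order", {
  gen <- helix_dimer(n = 12)
  m <- gen$model
  set.seed(2)
  shuffled <- structure_model(m$atoms[sample(nrow(m$atoms)), ],
                              structure_id = "shuffled")
  k1 <- edge_keys(detect_hbonds(m), "chain1", "resno1", "atom1",
                  "chain2", "resno2", "atom2")
  k2 <- edge_keys(detect_hbonds(shuffled), "chain1", "resno1", "atom1",
                  "chain2", "resno2", "atom2")
  expect_equal(k1, k2)
})

test_that("raising d_strong only reclassifies weak edges as strong", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 9))
  lo <- detect_hbonds(gen$model, d_strong = 2.9)
  hi <- detect_hbonds(gen$model, d_strong = 3.4)
  keys <- function(df) edge_keys(df, "chain1", "resno1", "atom1",
                                 "chain2", "resno2", "atom2")
  expect_equal(keys(lo), keys(hi))          # same edges overall
  expect_gte(sum(hi$kind == "strong-hbond"), sum(lo$kind == "strong-hbond"))
  strong_lo <- keys(lo[lo$kind == "strong-hbond", ])
  strong_hi <- keys(hi[hi$kind == "strong-hbond", ])
  expect_true(all(strong_lo %in% strong_hi))
})

test_that("salt bridges use the exact minimum over charged-group atoms", {
  rows <- c(res_atoms("A", 1, c(0, 0, 0), resname = "ARG"),
            list(list(chain = "A", resno = 1, resname = "ARG", atom = "NH1",
                      xyz = c(0, 3, 0)),
                 list(chain = "A", resno = 1, resname = "ARG", atom = "NH2",
                      xyz = c(0.8, 2.4, 0))),
            res_atoms("B", 2, c(0, 10, 0), resname = "ASP"),
            list(list(chain = "B", resno = 2, resname = "ASP", atom = "OD1",
                      xyz = c(0, 6.5, 0)),
                 list(chain = "B", resno = 2, resname = "ASP", atom = "OD2",
                      xyz = c(0, 7.3, 0))))
  m <- do.call(model_from_atoms, rows)
  sb <- detect_salt_bridges(m)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)   # NH1(0,3)-OD1(0,6.5)
  # exhaustive minimum over the 2x2 group atoms
  expect_equal(sb$distance, min(3.5, sqrt(0.8^2 + 4.1^2), 4.3,
                                sqrt(0.8^2 + 4.9^2)), tolerance = 1e-9)
  expect_equal(sort(c(sb$atom1, sb$atom2)), c("NH1", "OD1"))

  none <- detect_salt_bridges(m, cutoff = 3.0)
  expect_equal(nrow(none), 0L)
})

test_that("the emulated dimer shows the interchain Arg336-Asp59 salt bridge", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 1))
  sb <- detect_salt_bridges(gen$model)
  expect_equal(nrow(sb), 2L)               # one per symmetric interface
  expect_equal(sb$distance, c(4.9, 4.9), tolerance = 1e-6)
  expect_true(all(sb$topology == "inter-chain"))
  one <- sb[sb$resno1 == 59 & sb$resno2 == 336, ]
  expect_equal(nrow(one), 1L)
  expect_equal(unname(c(one$atom1, one$atom2)), c("OD1", "NH1"))
})

test_that("water bridges require two distinct protein partners", {
  base <- c(res_atoms("A", 1, c(0, 0, 0), resname = "SER"),
            list(list(chain = "A", resno = 1, resname = "SER", atom = "OG",
                      xyz = c(0, 2, 0))),
            res_atoms("B", 2, c(0, 6.4, 0)))
  with_water <- c(base, list(list(chain = "A", resno = 901, resname = "HOH",
                                  atom = "O", xyz = c(0, 4.2, 1.5))))
  m <- do.call(model_from_atoms, with_water)
  wb <- detect_water_bridges(m, d_hb = 3.4)
  expect_gte(nrow(wb), 1L)
  expect_true(any(wb$topology == "inter-chain"))
  expect_true(all(wb$kind == "water-bridge"))
  expect_true(all(wb$distance <= 3.4))

  lonely <- c(res_atoms("A", 1, c(0, 0, 0)),
              list(list(chain = "A", resno = 901, resname = "HOH", atom = "O",
                        xyz = c(1.5, 4.0, 0))))
  expect_equal(nrow(detect_water_bridges(do.call(model_from_atoms, lonely))), 0L)
  dry <- do.call(model_from_atoms, base)
  expect_equal(nrow(detect_water_bridges(dry)), 0L)
})

test_that("the loop census separates intramolecular and intersubunit bonds", {
  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 1))
  net <- loop_interaction_summary(gen$model, "A", c(324, 354))
  truth <- gen$truth$census
  expect_equal(net$summary$intra_loop_strong_hbonds, truth$intra_strong)
  expect_equal(net$summary$intra_loop_strong_mainchain,
               truth$intra_strong_mainchain)
  expect_equal(net$summary$intersubunit_bonds, truth$inter_bonds)
  expect_equal(net$summary$intersubunit_salt_bridges, 1L)
  expect_gte(net$summary$intersubunit_water_bridges, 1L)
  # census counts sum to the edge count
  expect_equal(sum(net$by_class$Freq), nrow(net$edges))
  # thresholds are reported for reproducibility
  expect_equal(net$thresholds$d_strong, 3.0)

  empty <- loop_interaction_summary(gen$model, "A", c(96, 100))
  expect_equal(empty$summary$intersubunit_bonds, 0L)
  expect_error(loop_interaction_summary(gen$model, "A", c(400, 300)),
               "interval")
})

test_that("active-site separation is the metal-centroid distance", {
  rows <- c(res_atoms("A", 1, c(0, 0, 0)),
            res_atoms("B", 1, c(0, 0, 40)),
            list(list(chain = "A", resno = 900, resname = "ZN", atom = "ZN",
                      xyz = c(0, 0, 0)),
                 list(chain = "B", resno = 900, resname = "ZN", atom = "ZN",
                      xyz = c(0, 0, 10))))
  m <- do.call(model_from_atoms, rows)
  expect_equal(active_site_separation(m), 10)

  gen <- make_toy_dimer(vap_dimer_spec("wildtype", seed = 2))
  expect_equal(active_site_separation(gen$model),
               gen$truth$site_separation, tolerance = 1e-9)
  expect_error(active_site_separation(m, chains = c("A", "C")), "no chain|site")
})
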