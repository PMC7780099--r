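# Synthetic emulation of a cold-active alkaline phosphatase dimer: a
# two-fold symmetric 310-residue-per-chain model (author numbering 50-359)
# whose planted features mirror the study system's headline geometry --
# a large interface loop (residues 324-354) docked over the partner
# subunit's serine-loop face, an Arg336-centred bond cluster with an
# interchain salt bridge to Asp59' at 4.9 A, a 12-bond intramolecular loop
# census (6 mainchain-mainchain), 11 intersubunit bonds, Zn-site centroids
# 60 A apart, and insert-region main-chain asymmetry averaging ~0.30 A
# (wild-type) / ~0.35 A (variant vs wild-type).

# Intramolecular loop bonds: 6 mainchain-mainchain (the carbonyl O one spiral
# turn below each amide N is drawn up to bonding distance) + 6 involving side
# chains.
VAP_INTRA_BONDS <- list(
  list(chain1 = "A", res1 = 324L, atom1 = "N", chain2 = "A", res2 = 335L, atom2 = "O", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 326L, atom1 = "N", chain2 = "A", res2 = 337L, atom2 = "O", target = 2.90, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 328L, atom1 = "N", chain2 = "A", res2 = 339L, atom2 = "O", target = 2.80, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 330L, atom1 = "N", chain2 = "A", res2 = 341L, atom2 = "O", target = 2.88, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 340L, atom1 = "N", chain2 = "A", res2 = 351L, atom2 = "O", target = 2.92, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 342L, atom1 = "N", chain2 = "A", res2 = 353L, atom2 = "O", target = 2.86, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 334L, atom1 = "NE2", chain2 = "A", res2 = 345L, atom2 = "O", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 346L, atom1 = "OH", chain2 = "A", res2 = 336L, atom2 = "O", target = 2.90, kind = "strong-hbond",
       place_dir = c(-0.25, -0.2, -0.95)),
  list(chain1 = "A", res1 = 344L, atom1 = "ND2", chain2 = "A", res2 = 333L, atom2 = "O", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 331L, atom1 = "OG1", chain2 = "A", res2 = 342L, atom2 = "O", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 349L, atom1 = "OG", chain2 = "A", res2 = 338L, atom2 = "O", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 343L, atom1 = "OG", chain2 = "A", res2 = 354L, atom2 = "O", target = 2.85, kind = "strong-hbond"))

# Arg336-mediated intersubunit cluster (lost in the R336L variant).
VAP_ARG336_BONDS <- list(
  list(chain1 = "A", res1 = 336L, atom1 = "NH2", chain2 = "B", res2 = 79L, atom2 = "OG", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 336L, atom1 = "NE", chain2 = "B", res2 = 87L, atom2 = "OG", target = 2.90, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 336L, atom1 = "NH1", chain2 = "B", res2 = 59L, atom2 = "OD1", target = 4.90, kind = "salt-bridge"))

# Waters bridging planted pairs (anchor atoms must exist when placed).
vap_water_list <- function(variant) {
  w <- list(
    list(chain1 = "A", res1 = 334L, atom1 = "NE2", chain2 = "A", res2 = 345L,
         atom2 = "O", leg = 2.9),
    list(chain1 = "A", res1 = 344L, atom1 = "ND2", chain2 = "A", res2 = 333L,
         atom2 = "O", leg = 2.9))
  if (variant == "wildtype") {
    w <- c(w, list(list(chain1 = "A", res1 = 336L, atom1 = "NH2", chain2 = "B",
                        res2 = 79L, atom2 = "OG", leg = 2.9)))
  }
  w
}

# Remaining intersubunit bonds near the loop stem (anchor residues and
# partners fixed by the fold geometry; see data-raw note in the vignette).
VAP_STEM_BONDS <- list(
  list(chain1 = "A", res1 = 325L, atom1 = "OD1", chain2 = "B", res2 = 57L, atom2 = "NZ", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 332L, atom1 = "OD1", chain2 = "B", res2 = 62L, atom2 = "ND2", target = 2.90, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 333L, atom1 = "ND2", chain2 = "B", res2 = 64L, atom2 = "OD1", target = 2.90, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 335L, atom1 = "OD1", chain2 = "B", res2 = 66L, atom2 = "NZ", target = 2.80, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 342L, atom1 = "OD1", chain2 = "B", res2 = 72L, atom2 = "ND2", target = 2.95, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 345L, atom1 = "ND2", chain2 = "B", res2 = 76L, atom2 = "OE1", target = 2.95, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 351L, atom1 = "ND2", chain2 = "B", res2 = 81L, atom2 = "OD1", target = 2.85, kind = "strong-hbond"),
  list(chain1 = "A", res1 = 354L, atom1 = "OD1", chain2 = "B", res2 = 83L, atom2 = "NZ", target = 2.85, kind = "strong-hbond"))

VAP_RESIDUE_NAMES <- c(
  "325" = "ASN", "331" = "THR", "332" = "ASN", "333" = "ASN",
  "334" = "GLN", "335" = "ASN", "336" = "ARG", "342" = "ASN", "343" = "SER",
  "344" = "ASN", "345" = "ASN", "346" = "TYR", "349" = "SER", "351" = "ASN",
  "354" = "ASN",
  "57" = "LYS", "59" = "ASP", "62" = "ASN", "64" = "ASN", "66" = "LYS",
  "72" = "ASN", "76" = "GLN", "79" = "SER", "81" = "ASN", "83" = "LYS",
  "87" = "SER")

# Zn pair centroid placed so the two-fold image centroid lies exactly 60 A
# away: separation = 2 * sqrt(qy^2 + qz^2).
vap_metal_sites <- function() {
  qy <- 20.5
  qz <- sqrt(900 - qy^2)
  list(elements = c("ZN", "ZN", "MG"),
       xyz = rbind(c(17, qy, qz) + c(2, 0, 0),
                   c(17, qy, qz) - c(2, 0, 0),
                   c(17, qy + 2, qz + 1)))
}

#' Synthetic alkaline-phosphatase dimer specification
#'
#' Returns a fully populated [toy_dimer_spec()] emulating the study system:
#' `"wildtype"` carries the complete planted interface (12 intramolecular
#' loop bonds of which 6 mainchain-mainchain, 10 intersubunit hydrogen bonds
#' plus the 4.9 Angstrom Arg336-Asp59' salt bridge, all mirrored across the
#' two-fold axis), insert-region main-chain asymmetry averaging about 0.30
#' Angstrom, and Zn centroids 60 Angstrom apart.  `"R336L"` removes the three
#' Arg336 side-chain contacts, renames residue 336 to leucine, displaces its
#' monomer relative to the wild-type backbone by a planted field averaging
#' about 0.35 Angstrom, and raises B-factors in the regions 81-100 and
#' 115-150 of both chains.
#'
#' @param variant `"wildtype"` or `"R336L"`.
#' @param seed integer seed for the jitter and B-factor noise.
#' @return A `ToyDimerSpec`.
#' @export
vap_dimer_spec <- function(variant = c("wildtype", "R336L"), seed = 1L) {
  variant <- match.arg(variant)
  base_b <- function(resno) {
    26.14 + 4 * sin((resno - 50) / 13) +
      25 * exp(-((resno - 168) / 12)^2) +
      20 * exp(-((resno - 225) / 12)^2)
  }
  res_names <- VAP_RESIDUE_NAMES
  inter <- c(VAP_ARG336_BONDS, VAP_STEM_BONDS)
  intra <- VAP_INTRA_BONDS
  bumps_conn <- function(amp) {
    list(list(range1 = c(153, 183), range2 = c(210, 240), amplitude = amp))
  }
  waters <- vap_water_list(variant)
  if (variant == "wildtype") {
    toy_dimer_spec(
      n_res = 310L, first_resno = 50L, geometry = "folded-dimer",
      chain_a_bumps = list(), chain_b_bumps = bumps_conn(1.00),
      jitter_a = 0, jitter_b = c(0.11, 0.05),
      bfactor = list(baseline = base_b, bumps = list(), noise_sd = 0.5),
      residue_names = res_names,
      interactions = c(intra, inter),
      symmetric_interactions = TRUE,
      waters = waters,
      metals = vap_metal_sites(),
      validate = "strict",
      structure_id = "synthetic-vap-wildtype",
      seed = seed)
  } else {
    res_names["336"] <- "LEU"
    inter <- VAP_STEM_BONDS
    toy_dimer_spec(
      n_res = 310L, first_resno = 50L, geometry = "folded-dimer",
      chain_a_bumps = bumps_conn(1.18), chain_b_bumps = list(),
      jitter_a = c(0.13, 0.05), jitter_b = c(0.11, 0.05),
      bfactor = list(baseline = base_b,
                     bumps = list(list(from = 81, to = 100, amplitude = 9),
                                  list(from = 115, to = 150, amplitude = 9)),
                     noise_sd = 0.5),
      residue_names = res_names,
      interactions = c(intra, inter),
      symmetric_interactions = TRUE,
      waters = waters,
      metals = vap_metal_sites(),
      validate = "strict",
      structure_id = "synthetic-vap-R336L",
      seed = seed)
  }
}

#' Planted thermal-stability and kinetic parameters of the emulated wild-type
#'
#' The simulator defaults used throughout the package for the emulated
#' wild-type enzyme: an inactivation activation energy of 280 kJ/mol with the
#' pre-exponential chosen so the derived T50% is 25.8 C, a melting midpoint
#' of 50.8 C, and Michaelis-Menten constants kcat = 302 1/s, KM = 0.19 mM.
#'
#' @return list with `ea_kj`, `lnA`, `t50_C`, `tm_C`, `steepness`, `kcat`,
#'   `km_mM`.
#' @export
vap_stability_params <- function() {
  ea_kj <- 280
  t50_C <- 25.8
  lnA <- log(K_HALF_30MIN) + ea_kj * 1000 / (RGAS * (t50_C + 273.15))
  list(ea_kj = ea_kj, lnA = lnA, t50_C = t50_C,
       tm_C = 50.8, steepness = 2.2, kcat = 302, km_mM = 0.19)
}
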