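# Polar-atom chemistry tables.  Donor/acceptor assignment is by heavy atom
# (crystal structures at ~2 A carry no hydrogens); hydroxyls are listed as
# both donor and acceptor.  His is treated as cationic by default (protonation
# unknown at mildly alkaline pH) and its ring nitrogens as donor+acceptor.

SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2"),
  TRP = c("NE1"), ASN = c("ND2"), GLN = c("NE2"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"), CYS = c("SG"))

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), HIS = c("ND1", "NE2"), SER = c("OG"), THR = c("OG1"),
  TYR = c("OH"), MET = c("SD"), CYS = c("SG"))

CATIONIC_GROUPS <- list(ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"),
                        HIS = c("ND1", "NE2"))
ANIONIC_GROUPS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Polar atom classification table
#'
#' Returns the heavy-atom chemistry table used by the interaction detectors:
#' side-chain donors and acceptors per residue type, cationic and anionic
#' group atoms, plus the backbone rule (N donates, O/OXT accepts for every
#' residue type; C-terminal oxygens count as anionic).
#'
#' @param his_cationic treat histidine ring nitrogens as cationic.
#' @return list with elements `donors`, `acceptors`, `cationic`, `anionic`.
#' @export
polar_atom_table <- function(his_cationic = TRUE) {
  cat_groups <- CATIONIC_GROUPS
  if (!his_cationic) cat_groups$HIS <- NULL
  list(donors = SIDECHAIN_DONORS, acceptors = SIDECHAIN_ACCEPTORS,
       cationic = cat_groups, anionic = ANIONIC_GROUPS)
}

# Polymer heavy atoms with donor/acceptor flags.
polar_atoms <- function(model) {
  a <- model$atoms
  a <- a[a$kind == "polymer" & a$element != "H", , drop = FALSE]
  sd <- SIDECHAIN_DONORS
  sa <- SIDECHAIN_ACCEPTORS
  in_list <- function(lst) {
    hit <- logical(nrow(a))
    for (rn in names(lst)) hit <- hit | (a$resname == rn & a$atom %in% lst[[rn]])
    hit
  }
  donor <- a$atom == "N" | in_list(sd)
  acceptor <- a$atom %in% c("O", "OXT") | in_list(sa)
  keep <- donor | acceptor
  out <- a[keep, , drop = FALSE]
  out$donor <- donor[keep]
  out$acceptor <- acceptor[keep]
  rownames(out) <- NULL
  out
}

# Cell-list candidate pair search: returns index pairs (i < j) with
# distance <= cutoff.  Correctness is pinned to the exhaustive all-pairs scan
# used in the test suite.
pair_candidates <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cell)
  idx <- split(seq_len(n), paste(key[, 1], key[, 2], key[, 3]))
  cells <- do.call(rbind, strsplit(names(idx), " "))
  cells <- matrix(as.integer(cells), ncol = 3L)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(idx)) assign(paste(cells[k, ], collapse = " "), idx[[k]], lookup)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  res_i <- vector("list", length(idx))
  res_j <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    here <- idx[[k]]
    neigh <- integer()
    for (o in seq_len(nrow(offsets))) {
      nb_key <- paste(cells[k, ] + offsets[o, ], collapse = " ")
      nb <- lookup[[nb_key]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    cand_i <- rep(here, each = length(neigh))
    cand_j <- rep(neigh, times = length(here))
    keep <- cand_i < cand_j
    res_i[[k]] <- cand_i[keep]
    res_j[[k]] <- cand_j[keep]
  }
  i <- unlist(res_i)
  j <- unlist(res_j)
  if (!length(i)) return(cbind(i = integer(), j = integer()))
  d2 <- rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2)
  keep <- d2 <= cutoff^2
  cbind(i = i[keep], j = j[keep])
}

atom_ref <- function(a, rows) {
  sprintf("%s:%s%d%s:%s", a$chain[rows], a$resname[rows], a$resno[rows],
          a$icode[rows], a$atom[rows])
}

interaction_frame <- function(a, i, j, kind, dist, water_label = NA_character_) {
  # canonical partner ordering: lexicographic on (chain, resno, icode, atom)
  k1 <- sprintf("%s|%09d|%s|%s", a$chain[i], as.integer(a$resno[i] + 100000L),
                a$icode[i], a$atom[i])
  k2 <- sprintf("%s|%09d|%s|%s", a$chain[j], as.integer(a$resno[j] + 100000L),
                a$icode[j], a$atom[j])
  swap <- k1 > k2
  ii <- ifelse(swap, j, i)
  jj <- ifelse(swap, i, j)
  bc1 <- ifelse(a$is_mainchain[ii], "mainchain", "sidechain")
  bc2 <- ifelse(a$is_mainchain[jj], "mainchain", "sidechain")
  data.frame(
    kind = kind,
    chain1 = a$chain[ii], resno1 = a$resno[ii], icode1 = a$icode[ii],
    resname1 = a$resname[ii], atom1 = a$atom[ii],
    chain2 = a$chain[jj], resno2 = a$resno[jj], icode2 = a$icode[jj],
    resname2 = a$resname[jj], atom2 = a$atom[jj],
    distance = dist,
    topology = ifelse(a$chain[ii] == a$chain[jj], "intra-chain", "inter-chain"),
    backbone_class = paste(pmin(bc1, bc2), pmax(bc1, bc2), sep = "-"),
    water_label = rep(water_label, length.out = length(ii)),
    stringsAsFactors = FALSE)
}

empty_interactions <- function() {
  interaction_frame(data.frame(chain = character(), resno = integer(),
                               icode = character(), resname = character(),
                               atom = character(), is_mainchain = logical()),
                    integer(), integer(), character(), numeric())
}

sort_interactions <- function(edges) {
  if (!nrow(edges)) return(edges)
  ord <- order(edges$chain1, edges$resno1, edges$icode1, edges$atom1,
               edges$chain2, edges$resno2, edges$icode2, edges$atom2, edges$kind)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Detect hydrogen bonds by donor-acceptor distance
#'
#' Enumerates every heavy-atom donor/acceptor pair and classifies it purely by
#' distance, the convention used for rendering interaction networks in crystal
#' structures without hydrogens: strong hydrogen bonds below `d_strong`
#' (default 3.0 Angstrom), weak hydrogen bonds from `d_strong` to `d_weak_max`
#' (3.0-5.0 Angstrom).  No donor-H-acceptor angle term is applied.
#'
#' Pairs within one residue are excluded.  The trivially covalent
#' O(i)...N(i+1) contact across a peptide bond (sequence-adjacent main-chain
#' pair at bonding distance, below 2.6 Angstrom) is excluded; beyond that only
#' the `d_min` clash floor applies.
#'
#' @param model a `StructureModel`.
#' @param d_strong strong/weak class boundary, Angstrom.
#' @param d_weak_max weak-bond upper limit, Angstrom.
#' @param d_min clash floor, Angstrom.
#' @return data.frame of interactions: `kind` (`strong-hbond` / `weak-hbond`),
#'   canonical partner columns, `distance`, `topology`, `backbone_class`.
#' @export
detect_hbonds <- function(model, d_strong = 3.0, d_weak_max = 5.0, d_min = 2.2) {
  stopifnot(inherits(model, "StructureModel"))
  if (!(d_min < d_strong && d_strong <= d_weak_max)) {
    stop("detect_hbonds: thresholds must satisfy d_min < d_strong <= d_weak_max",
         call. = FALSE)
  }
  pa <- polar_atoms(model)
  if (nrow(pa) == 0L) return(empty_interactions())
  xyz <- as.matrix(pa[, c("x", "y", "z")])
  cand <- pair_candidates(xyz, d_weak_max)
  if (!nrow(cand)) return(empty_interactions())
  i <- cand[, 1]; j <- cand[, 2]
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  ok <- d >= d_min &
    ((pa$donor[i] & pa$acceptor[j]) | (pa$donor[j] & pa$acceptor[i]))
  same_res <- pa$chain[i] == pa$chain[j] & pa$resno[i] == pa$resno[j] &
    pa$icode[i] == pa$icode[j]
  peptide <- pa$chain[i] == pa$chain[j] & abs(pa$resno[i] - pa$resno[j]) == 1L &
    pa$is_mainchain[i] & pa$is_mainchain[j] &
    ((pa$atom[i] == "N" & pa$atom[j] == "O") |
       (pa$atom[i] == "O" & pa$atom[j] == "N")) & d < 2.6
  ok <- ok & !same_res & !peptide
  if (!any(ok)) return(empty_interactions())
  i <- i[ok]; j <- j[ok]; d <- d[ok]
  kind <- ifelse(d < d_strong, "strong-hbond", "weak-hbond")
  sort_interactions(interaction_frame(pa, i, j, kind, d))
}

#' Detect salt bridges
#'
#' For each (cationic residue, anionic residue) pair, takes the minimum
#' distance over cationic-group x anionic-group heavy-atom pairs (Arg
#' guanidinium / Lys ammonium / optionally His ring versus Asp/Glu carboxylate
#' or C-terminal oxygens) and emits a salt bridge when that minimum is within
#' `cutoff`.
#'
#' @param model a `StructureModel`.
#' @param cutoff maximum group-to-group minimum distance, Angstrom (default 5.0).
#' @param his_cationic treat His as cationic (default TRUE).
#' @return data.frame of `salt-bridge` interactions; the partner atoms are the
#'   closest group-atom pair and `distance` the exact group minimum.
#' @export
detect_salt_bridges <- function(model, cutoff = 5.0, his_cationic = TRUE) {
  stopifnot(inherits(model, "StructureModel"), cutoff > 0)
  a <- model$atoms
  a <- a[a$kind == "polymer" & a$element != "H", , drop = FALSE]
  tab <- polar_atom_table(his_cationic)
  flag_group <- function(groups) {
    hit <- logical(nrow(a))
    for (rn in names(groups)) hit <- hit | (a$resname == rn & a$atom %in% groups[[rn]])
    hit
  }
  cat_f <- flag_group(tab$cationic)
  ani_f <- flag_group(tab$anionic) | a$atom == "OXT"
  # C-terminal carboxylate: the backbone O of an OXT-bearing residue
  oxt_res <- unique(paste(a$chain, a$resno, a$icode)[a$atom == "OXT"])
  ani_f <- ani_f | (a$atom == "O" & paste(a$chain, a$resno, a$icode) %in% oxt_res)
  ci <- which(cat_f)
  ai <- which(ani_f)
  if (!length(ci) || !length(ai)) return(empty_interactions())
  sub <- a[c(ci, ai), , drop = FALSE]
  role_cat <- c(rep(TRUE, length(ci)), rep(FALSE, length(ai)))
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  cand <- pair_candidates(xyz, cutoff)
  if (!nrow(cand)) return(empty_interactions())
  i <- cand[, 1]; j <- cand[, 2]
  opp <- role_cat[i] != role_cat[j]
  i <- i[opp]; j <- j[opp]
  if (!length(i)) return(empty_interactions())
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  rkey <- function(rows) paste(sub$chain[rows], sub$resno[rows], sub$icode[rows])
  pair_key <- paste(pmin(rkey(i), rkey(j)), pmax(rkey(i), rkey(j)), sep = " // ")
  best <- tapply(seq_along(d), pair_key, function(rows) rows[which.min(d[rows])])
  best <- as.integer(best)
  sort_interactions(interaction_frame(sub, i[best], j[best], "salt-bridge", d[best]))
}

#' Detect water-mediated bridges
#'
#' Emits a water bridge for every water whose oxygen lies within `d_hb` of
#' polar atoms of two distinct protein residues; one edge per
#' (residue, residue, water) triple, with the reported distance the larger of
#' the two water legs (each leg being the water's closest polar atom of that
#' residue).  The default leg length is slightly looser than the strong
#' hydrogen-bond class, reflecting structured-water geometry.
#'
#' @param model a `StructureModel` containing waters.
#' @param d_hb maximum water-polar atom leg, Angstrom (default 3.4).
#' @return data.frame of `water-bridge` interactions; `water_label` names the
#'   bridging water.
#' @export
detect_water_bridges <- function(model, d_hb = 3.4) {
  stopifnot(inherits(model, "StructureModel"), d_hb > 0)
  a <- model$atoms
  wat <- a[a$kind == "water" & a$element == "O", , drop = FALSE]
  if (nrow(wat) == 0L) return(empty_interactions())
  pa <- polar_atoms(model)
  if (nrow(pa) == 0L) return(empty_interactions())
  pxyz <- as.matrix(pa[, c("x", "y", "z")])
  out <- vector("list", nrow(wat))
  for (w in seq_len(nrow(wat))) {
    wp <- as.numeric(wat[w, c("x", "y", "z")])
    d <- sqrt(colSums((t(pxyz) - wp)^2))
    near <- which(d <= d_hb)
    if (length(near) < 2L) next
    rkey <- paste(pa$chain[near], pa$resno[near], pa$icode[near])
    legs <- tapply(seq_along(near), rkey, function(rows) {
      rows[which.min(d[near][rows])]
    })
    if (length(legs) < 2L) next
    reps <- near[as.integer(legs)]
    combos <- utils::combn(seq_along(reps), 2L)
    wl <- sprintf("%s:HOH%d", wat$chain[w], wat$resno[w])
    edges <- interaction_frame(pa, reps[combos[1, ]], reps[combos[2, ]],
                               "water-bridge",
                               pmax(d[reps[combos[1, ]]], d[reps[combos[2, ]]]),
                               water_label = wl)
    out[[w]] <- edges
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty_interactions())
  sort_interactions(out)
}

in_loop <- function(edges, side, loop_chain, loop_range) {
  ch <- edges[[paste0("chain", side)]]
  rn <- edges[[paste0("resno", side)]]
  ch == loop_chain & rn >= loop_range[1] & rn <= loop_range[2]
}

#' Interaction network around a loop or focal residue range
#'
#' Collects every hydrogen bond, salt bridge and water bridge with at least
#' one partner inside `loop_range` of `loop_chain`, and summarises the census
#' the way interface-loop studies report it: (a) bonds with both partners
#' inside the loop (intramolecular-within-loop), with a mainchain-mainchain
#' subcount, and (b) bonds spanning the two chains (intersubunit).  Pairs
#' satisfying both the salt-bridge and the weak hydrogen-bond distance class
#' are counted once, as salt bridges.  Counts by kind x topology x backbone
#' class are always included so alternative readings of a printed census can
#' be checked; the threshold set is recorded on the result.
#'
#' @param model a `StructureModel`.
#' @param loop_chain chain carrying the loop.
#' @param loop_range length-2 integer vector, inclusive author-numbered range.
#' @param d_strong,d_weak_max,d_min hydrogen-bond thresholds (see
#'   [detect_hbonds()]).
#' @param salt_cutoff salt-bridge cutoff (see [detect_salt_bridges()]).
#' @param water_d_hb water-bridge leg (see [detect_water_bridges()]).
#' @param his_cationic treat His as cationic.
#' @return An `InteractionNetwork`: list with `focal`, `edges`, `summary`
#'   (list of headline counts), `by_class` (kind x topology x backbone_class
#'   table), `thresholds`.
#' @export
loop_interaction_summary <- function(model, loop_chain, loop_range,
                                     d_strong = 3.0, d_weak_max = 5.0,
                                     d_min = 2.2, salt_cutoff = 5.0,
                                     water_d_hb = 3.4, his_cationic = TRUE) {
  loop_range <- as.integer(loop_range)
  if (length(loop_range) != 2L || loop_range[1] > loop_range[2]) {
    stop("loop_interaction_summary: loop_range must be an increasing length-2 interval",
         call. = FALSE)
  }
  hb <- detect_hbonds(model, d_strong, d_weak_max, d_min)
  sb <- detect_salt_bridges(model, salt_cutoff, his_cationic)
  wb <- detect_water_bridges(model, water_d_hb)
  edges <- rbind(hb, sb, wb)
  if (nrow(edges)) {
    touch <- in_loop(edges, 1, loop_chain, loop_range) |
      in_loop(edges, 2, loop_chain, loop_range)
    edges <- edges[touch, , drop = FALSE]
  }
  # salt-bridge precedence: drop a weak/strong H-bond duplicating the exact
  # atom pair of a detected salt bridge
  if (nrow(edges)) {
    pkey <- paste(edges$chain1, edges$resno1, edges$icode1, edges$atom1,
                  edges$chain2, edges$resno2, edges$icode2, edges$atom2)
    salt_keys <- pkey[edges$kind == "salt-bridge"]
    drop <- edges$kind %in% c("strong-hbond", "weak-hbond") & pkey %in% salt_keys
    edges <- edges[!drop, , drop = FALSE]
  }
  rownames(edges) <- NULL

  both_in <- nrow(edges) > 0 &
    in_loop(edges, 1, loop_chain, loop_range) &
    in_loop(edges, 2, loop_chain, loop_range) &
    edges$topology == "intra-chain"
  inter <- nrow(edges) > 0 & edges$topology == "inter-chain"
  non_water <- edges$kind != "water-bridge"

  summary <- list(
    n_edges = nrow(edges),
    intra_loop_strong_hbonds = sum(both_in & edges$kind == "strong-hbond"),
    intra_loop_strong_mainchain = sum(both_in & edges$kind == "strong-hbond" &
                                        edges$backbone_class == "mainchain-mainchain"),
    intra_loop_weak_hbonds = sum(both_in & edges$kind == "weak-hbond"),
    intra_loop_salt_bridges = sum(both_in & edges$kind == "salt-bridge"),
    intersubunit_bonds = sum(inter & non_water),
    intersubunit_strong_hbonds = sum(inter & edges$kind == "strong-hbond"),
    intersubunit_weak_hbonds = sum(inter & edges$kind == "weak-hbond"),
    intersubunit_salt_bridges = sum(inter & edges$kind == "salt-bridge"),
    intersubunit_water_bridges = sum(inter & edges$kind == "water-bridge"))
  by_class <- if (nrow(edges)) {
    as.data.frame(table(kind = edges$kind, topology = edges$topology,
                        backbone_class = edges$backbone_class),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), topology = character(),
               backbone_class = character(), Freq = integer())
  }
  structure(list(focal = list(chain = loop_chain, range = loop_range),
                 edges = edges, summary = summary,
                 by_class = by_class[by_class$Freq > 0, , drop = FALSE],
                 thresholds = list(d_strong = d_strong, d_weak_max = d_weak_max,
                                   d_min = d_min, salt_cutoff = salt_cutoff,
                                   water_d_hb = water_d_hb,
                                   his_cationic = his_cationic)),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  s <- x$summary
  cat(sprintf("InteractionNetwork around %s:%d-%d\n", x$focal$chain,
              x$focal$range[1], x$focal$range[2]))
  cat(sprintf("  edges: %d\n", s$n_edges))
  cat(sprintf("  intramolecular within loop: %d strong H-bonds (%d mainchain-mainchain), %d weak, %d salt\n",
              s$intra_loop_strong_hbonds, s$intra_loop_strong_mainchain,
              s$intra_loop_weak_hbonds, s$intra_loop_salt_bridges))
  cat(sprintf("  intersubunit: %d bonds (%d strong, %d weak, %d salt; %d water bridges)\n",
              s$intersubunit_bonds, s$intersubunit_strong_hbonds,
              s$intersubunit_weak_hbonds, s$intersubunit_salt_bridges,
              s$intersubunit_water_bridges))
  cat(sprintf("  thresholds: strong < %.2f, weak <= %.2f, floor %.2f, salt <= %.2f, water leg <= %.2f A\n",
              x$thresholds$d_strong, x$thresholds$d_weak_max, x$thresholds$d_min,
              x$thresholds$salt_cutoff, x$thresholds$water_d_hb))
  invisible(x)
}

#' Distance between the two active-site metal centroids
#'
#' Computes the Euclidean distance between per-chain centroids of the selected
#' metal element (default Zn, the catalytic metal of alkaline phosphatases) --
#' the "distance between the active sites of each monomer" statistic.
#'
#' @param model a `StructureModel` with metal sites assigned to chains.
#' @param chains length-2 chain selection; defaults to the two chains carrying
#'   the element.
#' @param element metal element symbol (default `"ZN"`).
#' @return distance in Angstrom.
#' @export
active_site_separation <- function(model, chains = NULL, element = "ZN") {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  met <- a[a$kind == "metal" & a$element == toupper(element), , drop = FALSE]
  if (is.null(chains)) {
    chains <- unique(met$chain)
    if (length(chains) != 2L) {
      stop(sprintf("active_site_separation: expected %s sites on exactly 2 chains, found %d",
                   element, length(chains)), call. = FALSE)
    }
  }
  cents <- lapply(chains, function(ch) {
    m <- met[met$chain == ch, , drop = FALSE]
    if (nrow(m) == 0L) {
      stop(sprintf("active_site_separation: chain %s has no %s site atoms",
                   ch, element), call. = FALSE)
    }
    colMeans(as.matrix(m[, c("x", "y", "z")]))
  })
  sqrt(sum((cents[[1]] - cents[[2]])^2))
}

#' Write an interaction table as TSV
#' @param edges interaction data.frame from the detectors.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_interactions_tsv <- function(edges, path) {
  out <- data.frame(kind = edges$kind,
                    chain1 = edges$chain1, res1 = paste0(edges$resname1, edges$resno1, edges$icode1),
                    atom1 = edges$atom1,
                    chain2 = edges$chain2, res2 = paste0(edges$resname2, edges$resno2, edges$icode2),
                    atom2 = edges$atom2,
                    distance_angstrom = sprintf("%.3f", edges$distance),
                    topology = edges$topology, backbone_class = edges$backbone_class,
                    water_label = ifelse(is.na(edges$water_label), "", edges$water_label),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
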