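# ---- small vector helpers -------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("unit3: zero-length vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis vector (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit3(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

# Natural-extension reference frame placement: position a new atom at bond
# length L from c, bond angle theta (at c, degrees) and dihedral chi
# (a-b-c-new, degrees).
nerf_place <- function(a, b, c, L, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-L * cos(theta), L * sin(theta) * cos(chi), L * sin(theta) * sin(chi))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal-geometry backbone from repeated (phi, psi) dihedrals.  Bond lengths
# and angles are standard peptide values; carbonyl O trails the psi dihedral.
build_backbone_dihedral <- function(n, phi, psi, omega = 180) {
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, -120)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
      CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, omega)
      C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2, phi)
      # carbonyl O is anti to the next amide N across the C(i) centre
      O[i, ] <- nerf_place(N[i + 1, ], CA[i, ], C[i, ], 1.231, 120.8, 180)
    } else {
      O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
    }
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Backbone laid along an arbitrary CA path: N and C sit in-line along the
# local path tangent, the carbonyl O along a supplied normal.  Internal
# distances are fixed; this trades bond-angle realism for exact control of
# the fold, which is what planted-truth fixtures need.
backbone_from_path <- function(ca, normal, tangent = NULL) {
  n <- nrow(ca)
  if (is.null(tangent)) {
    tangent <- matrix(0, n, 3)
    tangent[-n, ] <- ca[-1, ] - ca[-n, ]
    tangent[n, ] <- tangent[n - 1, ]
  }
  tangent <- tangent / sqrt(rowSums(tangent^2))
  # orthogonalize normals against the tangent
  nr <- normal - tangent * rowSums(normal * tangent)
  bad <- sqrt(rowSums(nr^2)) < 1e-6
  if (any(bad)) nr[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)), ncol = 3, byrow = TRUE)
  nr <- nr / sqrt(rowSums(nr^2))
  list(N = ca - 1.20 * tangent,
       CA = ca,
       C = ca + 1.50 * tangent,
       O = ca + 1.50 * tangent + 1.23 * nr)
}

# ---- the folded-dimer reference path --------------------------------------

# Stylized compact fold for one monomer of a two-fold symmetric dimer
# (C2 axis = x axis).  Three segments:
#   * "ball"      residues 1..46   : raster grid in the plane y = +by (rows
#                                    along x, spaced in z): the serine-loop /
#                                    helix face that the partner's large loop
#                                    docks onto via the C2 image at y = -by.
#   * "connector" residues 47..266 : wide solenoid lifted well above the
#                                    interface (z >= conn_z0, image at
#                                    z <= -conn_z0); hosts the planted
#                                    asymmetry bumps.
#   * "loop"      residues 267..310: the large interface loop, a raster grid
#                                    in the plane y = -by + gap hovering a
#                                    fixed 8 A above the image of the partner
#                                    ball, so every planted interface span is
#                                    8-12 A by construction.
# Backbone N/C run in-line along the row direction and carbonyl O points +y
# (away from the interface gap), which keeps every non-planted cross-chain
# donor/acceptor pair beyond the weak hydrogen-bond class.  Chain breaks
# between rows and segments are intentional (the fold is a scaffold for
# planted geometry, not a physical conformer).
FOLD_PARAMS <- list(
  n_ball = 46L, n_conn = 220L, n_loop = 44L,
  by = 13, gap = 8, row_dx = 3.8, row_dz = 4.8,
  ball_row_len = 10L, loop_row_len = 11L, loop_row_dz = 6.0, loop_x0 = -8.4,
  conn_r = 25, conn_cy = 8, conn_z0 = 25, conn_dz = 0.25,
  loop_z_top = 1.2)

fold_path <- function(p = FOLD_PARAMS) {
  n <- p$n_ball + p$n_conn + p$n_loop
  ca <- matrix(NA_real_, n, 3)
  normal <- matrix(NA_real_, n, 3)
  tangent <- matrix(NA_real_, n, 3)
  segment <- character(n)

  k <- 0:(p$n_ball - 1L)
  ca[k + 1L, ] <- cbind((k %% p$ball_row_len) * p$row_dx,
                        p$by,
                        (k %/% p$ball_row_len) * p$row_dz)
  tangent[k + 1L, ] <- matrix(c(1, 0, 0), p$n_ball, 3, byrow = TRUE)
  normal[k + 1L, ] <- matrix(c(0, 1, 0), p$n_ball, 3, byrow = TRUE)
  segment[k + 1L] <- "ball"

  k <- 0:(p$n_conn - 1L)
  dphi <- sqrt(p$row_dx^2 - p$conn_dz^2) / p$conn_r
  ph <- k * dphi
  idx <- p$n_ball + k + 1L
  ca[idx, ] <- cbind(p$conn_r * sin(ph), p$conn_cy + p$conn_r * cos(ph),
                     p$conn_z0 + k * p$conn_dz)
  tangent[idx, ] <- cbind(cos(ph), -sin(ph), rep(p$conn_dz / p$row_dx, p$n_conn))
  normal[idx, ] <- cbind(-sin(ph), -cos(ph), 0)     # O points inward: keeps the
  # O(i)..N(i+1) contact at true peptide-bond distance on the curved segment
  segment[idx] <- "connector"

  k <- 0:(p$n_loop - 1L)
  idx <- p$n_ball + p$n_conn + k + 1L
  ca[idx, ] <- cbind(p$loop_x0 + (k %% p$loop_row_len) * p$row_dx,
                     -p$by + p$gap,
                     p$loop_z_top - (k %/% p$loop_row_len) * p$loop_row_dz)
  tangent[idx, ] <- matrix(c(1, 0, 0), p$n_loop, 3, byrow = TRUE)
  normal[idx, ] <- matrix(c(0, 1, 0), p$n_loop, 3, byrow = TRUE)
  segment[idx] <- "loop"

  list(ca = ca, normal = normal, tangent = tangent, segment = segment)
}

# ---- toy dimer specification ----------------------------------------------

#' Specification for a synthetic two-chain homodimer
#'
#' Describes every planted feature of a generated dimer: backbone layout,
#' two-fold symmetry, per-residue displacements of either chain (balanced
#' bump pairs, free interval offsets, random jitter), a per-residue B-factor
#' profile with bump regions, polar-contact plantings at exact target
#' distances, metal sites and bridging waters.  [make_toy_dimer()] realizes
#' the spec deterministically from its seed and returns the model together
#' with its ground truth.
#'
#' @param n_res residues per chain.
#' @param first_resno author number of the first residue.
#' @param geometry `"ideal-helix"`, `"extended"` (NeRF dihedral builders) or
#'   `"folded-dimer"` (the compact interface fold used for the study-system
#'   emulation; requires `n_res = 310`).
#' @param offset_a translation applied to chain A before symmetry (used to
#'   separate the straight-chain geometries from their C2 image).
#' @param symmetry list with `axis` and `angle` (degrees) defining the
#'   rotation generating chain B from chain A.
#' @param chain_a_bumps,chain_b_bumps lists of balanced displacement pairs,
#'   each `list(range1 = c(from, to), range2 = c(from, to), amplitude = a)`:
#'   range1 moves by `+a` and range2 by a compensating amount along the line
#'   joining the two region centroids, so the net translation and torque of
#'   the planted field vanish and least-squares superposition recovers the
#'   planted per-residue displacement exactly.
#' @param chain_b_offsets free displacement list
#'   `list(list(from, to, offset = c(dx, dy, dz)))` applied to chain B.
#' @param jitter_a,jitter_b per-residue isotropic Gaussian jitter SD
#'   (Angstrom); either a single value or `c(default, interface)` where the
#'   interface value applies to ball and loop segments of the folded layout.
#' @param bfactor list: `baseline` (function of resno returning Angstrom^2),
#'   `bumps` (list of `list(from, to, amplitude)` added to both chains of a
#'   variant), `noise_sd`.
#' @param residue_names named character vector (names = residue numbers)
#'   overriding the default GLY.
#' @param interactions list of planted contacts:
#'   `list(chain1, res1, atom1, chain2, res2, atom2, target, kind)` with
#'   `kind` in `strong-hbond`, `weak-hbond`, `salt-bridge`.
#' @param symmetric_interactions also plant every contact with chain labels
#'   swapped (homodimer realism).
#' @param waters list of bridging waters:
#'   `list(chain1, res1, atom1, chain2, res2, atom2, leg)`.
#' @param metals list with `elements` (character) and `xyz` (matrix, chain A
#'   coordinates; chain B sites are the symmetry image).
#' @param validate `"strict"` (generation fails if the realized strong-bond /
#'   salt-bridge / inter-chain contact sets differ from the planted ones) or
#'   `"record"` (no cross-checking; used for layouts whose backbone makes its
#'   own hydrogen bonds, e.g. the ideal helix).
#' @param structure_id model label.
#' @param seed integer seed; the generator is a pure function of spec + seed.
#' @return A `ToyDimerSpec` list.
#' @export
toy_dimer_spec <- function(n_res = 40L, first_resno = 1L,
                           geometry = c("ideal-helix", "extended", "folded-dimer"),
                           offset_a = c(0, 8, 0),
                           symmetry = list(axis = c(1, 0, 0), angle = 180),
                           chain_a_bumps = list(), chain_b_bumps = list(),
                           chain_b_offsets = list(),
                           jitter_a = 0, jitter_b = 0,
                           bfactor = list(baseline = function(resno) rep(20, length(resno)),
                                          bumps = list(), noise_sd = 0),
                           residue_names = character(),
                           interactions = list(),
                           symmetric_interactions = FALSE,
                           waters = list(),
                           metals = NULL,
                           validate = c("record", "strict"),
                           structure_id = "toy_dimer",
                           seed = 1L) {
  geometry <- match.arg(geometry)
  validate <- match.arg(validate)
  if (geometry == "folded-dimer" && n_res != 310L) {
    stop("toy_dimer_spec: the folded-dimer layout is defined for n_res = 310",
         call. = FALSE)
  }
  for (it in interactions) {
    if (it$target < 2.2) {
      stop("toy_dimer_spec: planted target distances must be >= 2.2 Angstrom",
           call. = FALSE)
    }
  }
  spec <- list(n_res = as.integer(n_res), first_resno = as.integer(first_resno),
               geometry = geometry, offset_a = offset_a, symmetry = symmetry,
               chain_a_bumps = chain_a_bumps, chain_b_bumps = chain_b_bumps,
               chain_b_offsets = chain_b_offsets,
               jitter_a = jitter_a, jitter_b = jitter_b,
               bfactor = bfactor, residue_names = residue_names,
               interactions = interactions,
               symmetric_interactions = symmetric_interactions,
               waters = waters, metals = metals, validate = validate,
               structure_id = structure_id, seed = as.integer(seed))
  class(spec) <- "ToyDimerSpec"
  spec
}

# per-residue displacement matrix for one chain
planted_displacements <- function(ca, resno, bumps, offsets, jitter, segment) {
  n <- length(resno)
  d <- matrix(0, n, 3)
  # bump edges are feathered over 3 residues so a displaced interval never
  # stretches the peptide O(i)..N(i+1) contact into the hydrogen-bond window
  feather <- function(range) {
    sel <- which(resno >= range[1] & resno <= range[2])
    k <- seq_along(sel)
    w <- pmin(1, k / 3, rev(k) / 3)
    list(idx = sel, w = w)
  }
  for (b in bumps) {
    f1 <- feather(b$range1)
    f2 <- feather(b$range2)
    if (!length(f1$idx) || !length(f2$idx)) {
      stop("displacement bump outside chain", call. = FALSE)
    }
    w <- unit3(colMeans(ca[f1$idx, , drop = FALSE]) - colMeans(ca[f2$idx, , drop = FALSE]))
    amp2 <- b$amplitude * sum(f1$w) / sum(f2$w)
    d[f1$idx, ] <- d[f1$idx, ] + (b$amplitude * f1$w) %o% w
    d[f2$idx, ] <- d[f2$idx, ] - (amp2 * f2$w) %o% w
  }
  for (o in offsets) {
    sel <- resno >= o$from & resno <= o$to
    d[sel, ] <- d[sel, ] + matrix(o$offset, sum(sel), 3, byrow = TRUE)
  }
  if (length(jitter) == 1L) jitter <- c(jitter, jitter)
  sd_res <- ifelse(segment %in% c("ball", "loop"), jitter[2], jitter[1])
  noise <- matrix(stats::rnorm(3 * n, sd = rep(sd_res, each = 3)), n, 3, byrow = TRUE)
  d + noise
}

#' Generate a synthetic dimer with known ground truth
#'
#' Realizes a [toy_dimer_spec()]: chain A is built on the chosen backbone
#' layout (displaced by its own planted field), chain B is the rigid two-fold
#' image of chain A with chain-B displacements applied afterwards, B-factors
#' follow the planted profile, and every planted polar contact is placed at
#' its target distance exactly.  In `"strict"` validation mode the generator
#' re-scans its own output and fails if any unplanned strong hydrogen bond,
#' salt bridge or inter-chain contact arises, so the returned ground truth is
#' guaranteed, not merely intended.
#'
#' @param spec a `ToyDimerSpec`.
#' @return list with `model` (a `StructureModel`) and `truth` (a `GroundTruth`
#'   list: planted per-residue displacement norms and their means, realized
#'   B-factor profiles and bump regions, the planted interaction table with
#'   realized distances, expected census counts, metal-site separation, seed
#'   and parameters).
#' @export
make_toy_dimer <- function(spec) {
  stopifnot(inherits(spec, "ToyDimerSpec"))
  set.seed(spec$seed)
  n <- spec$n_res
  resno <- spec$first_resno + seq_len(n) - 1L

  if (spec$geometry == "folded-dimer") {
    fp <- fold_path()
    bb0 <- backbone_from_path(fp$ca, fp$normal, fp$tangent)
    segment <- fp$segment
  } else {
    # helix dihedrals chosen so the i -> i+4 O..N contact sits at 2.87 A
    # (strong class) while i+3 / i+2 contacts stay beyond 3.2 A
    phi_psi <- if (spec$geometry == "ideal-helix") c(-58, -50) else c(-139, 135)
    bb0 <- build_backbone_dihedral(n, phi_psi[1], phi_psi[2])
    bb0 <- lapply(bb0, function(m) sweep(m, 2L, spec$offset_a, "+"))
    segment <- rep("chain", n)
  }

  rot <- rotation_about_axis(spec$symmetry$axis, spec$symmetry$angle)

  d_a <- planted_displacements(bb0$CA, resno, spec$chain_a_bumps, list(),
                               spec$jitter_a, segment)
  bb_a <- lapply(bb0, function(m) m + d_a)
  bb_b_pristine <- lapply(bb_a, function(m) m %*% t(rot))
  d_b <- planted_displacements(bb_b_pristine$CA, resno, spec$chain_b_bumps,
                               spec$chain_b_offsets, spec$jitter_b, segment)
  bb_b <- lapply(bb_b_pristine, function(m) m + d_b)

  resnames <- rep("GLY", n)
  if (length(spec$residue_names)) {
    hit <- match(as.integer(names(spec$residue_names)), resno)
    resnames[hit[!is.na(hit)]] <- unname(spec$residue_names[!is.na(hit)])
  }

  bf <- spec$bfactor
  base_b <- bf$baseline(resno)
  for (bump in bf$bumps) {
    sel <- resno >= bump$from & resno <= bump$to
    base_b[sel] <- base_b[sel] + bump$amplitude
  }
  noise_sd <- if (is.null(bf$noise_sd)) 0 else bf$noise_sd
  bvals_a <- pmax(1, base_b + stats::rnorm(n, sd = noise_sd))
  bvals_b <- pmax(1, base_b + stats::rnorm(n, sd = noise_sd))

  chain_atoms <- function(bb, chain, bvals) {
    do.call(rbind, lapply(c("N", "CA", "C", "O"), function(at) {
      data.frame(chain = chain, resno = resno, icode = "", resname = resnames,
                 kind = "polymer", atom = at,
                 element = substr(at, 1, 1),
                 x = bb[[at]][, 1], y = bb[[at]][, 2], z = bb[[at]][, 3],
                 occ = 1, b = bvals, altloc = "", is_mainchain = TRUE,
                 stringsAsFactors = FALSE)
    }))
  }
  atoms <- rbind(chain_atoms(bb_a, "A", bvals_a), chain_atoms(bb_b, "B", bvals_b))
  ord <- order(atoms$chain, atoms$resno,
               match(atoms$atom, c("N", "CA", "C", "O")))
  atoms <- atoms[ord, , drop = FALSE]

  # ---- planted interactions -----------------------------------------------
  inter <- spec$interactions
  if (spec$symmetric_interactions) {
    sw <- function(ch) ifelse(ch == "A", "B", "A")
    mirrored <- lapply(inter, function(it) {
      it$chain1 <- sw(it$chain1); it$chain2 <- sw(it$chain2)
      # explicit placement directions live in the image frame for the mirror
      if (!is.null(it$place_dir)) it$place_dir <- as.numeric(it$place_dir %*% t(rot))
      it
    })
    inter <- c(inter, mirrored)
  }

  find_atom <- function(chain, res, atom) {
    which(atoms$chain == chain & atoms$resno == res & atoms$atom == atom)
  }
  get_b <- function(chain, res) {
    v <- if (chain == "A") bvals_a else bvals_b
    v[match(res, resno)]
  }
  add_atom <- function(chain, res, atom) {
    row <- data.frame(chain = chain, resno = res, icode = "",
                      resname = resnames[match(res, resno)], kind = "polymer",
                      atom = atom, element = guess_element(atom),
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      occ = 1, b = get_b(chain, res), altloc = "",
                      is_mainchain = FALSE, stringsAsFactors = FALSE)
    atoms <<- rbind(atoms, row)
    nrow(atoms)
  }
  xyz_of <- function(i) as.numeric(atoms[i, c("x", "y", "z")])
  ca_of <- function(chain, res) xyz_of(find_atom(chain, res, "CA"))

  pinned <- character()
  pin_key <- function(chain, res, atom) paste(chain, res, atom)
  planted_rows <- list()

  for (it in inter) {
    i1 <- find_atom(it$chain1, it$res1, it$atom1)
    i2 <- find_atom(it$chain2, it$res2, it$atom2)
    exists1 <- length(i1) == 1L
    exists2 <- length(i2) == 1L
    p1_pinned <- pin_key(it$chain1, it$res1, it$atom1) %in% pinned
    p2_pinned <- pin_key(it$chain2, it$res2, it$atom2) %in% pinned
    if (p1_pinned && p2_pinned) {
      d <- sqrt(sum((xyz_of(i1) - xyz_of(i2))^2))
      if (abs(d - it$target) > 1e-6) {
        stop(sprintf("make_toy_dimer: conflicting constraints pin %s:%s:%s / %s:%s:%s (realized %.3f, target %.3f)",
                     it$chain1, it$res1, it$atom1, it$chain2, it$res2, it$atom2,
                     d, it$target), call. = FALSE)
      }
    } else if (exists1 && exists2) {
      # move whichever end is free (mainchain-mainchain plantings move atom 2)
      mv <- if (p1_pinned || (!p2_pinned)) list(from = i1, to = i2) else list(from = i2, to = i1)
      u <- unit3(xyz_of(mv$to) - xyz_of(mv$from))
      atoms[mv$to, c("x", "y", "z")] <- xyz_of(mv$from) + it$target * u
    } else if (exists1 || exists2) {
      anchor <- if (exists1) i1 else i2
      new_chain <- if (exists1) it$chain2 else it$chain1
      new_res <- if (exists1) it$res2 else it$res1
      new_atom <- if (exists1) it$atom2 else it$atom1
      u <- if (!is.null(it$place_dir)) unit3(it$place_dir) else
        unit3(ca_of(new_chain, new_res) - xyz_of(anchor))
      idx <- add_atom(new_chain, new_res, new_atom)
      atoms[idx, c("x", "y", "z")] <- xyz_of(anchor) + it$target * u
    } else {
      ca1 <- ca_of(it$chain1, it$res1)
      ca2 <- ca_of(it$chain2, it$res2)
      u <- unit3(ca2 - ca1)
      span <- sqrt(sum((ca2 - ca1)^2))
      o1 <- (span - it$target) / 2
      idx1 <- add_atom(it$chain1, it$res1, it$atom1)
      atoms[idx1, c("x", "y", "z")] <- ca1 + o1 * u
      idx2 <- add_atom(it$chain2, it$res2, it$atom2)
      atoms[idx2, c("x", "y", "z")] <- ca1 + (o1 + it$target) * u
    }
    pinned <- c(pinned, pin_key(it$chain1, it$res1, it$atom1),
                pin_key(it$chain2, it$res2, it$atom2))
    i1 <- find_atom(it$chain1, it$res1, it$atom1)
    i2 <- find_atom(it$chain2, it$res2, it$atom2)
    planted_rows[[length(planted_rows) + 1L]] <-
      data.frame(kind = it$kind, chain1 = it$chain1, res1 = it$res1,
                 atom1 = it$atom1, chain2 = it$chain2, res2 = it$res2,
                 atom2 = it$atom2, target = it$target,
                 realized = sqrt(sum((xyz_of(i1) - xyz_of(i2))^2)),
                 stringsAsFactors = FALSE)
  }
  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(kind = character(), chain1 = character(), res1 = integer(),
               atom1 = character(), chain2 = character(), res2 = integer(),
               atom2 = character(), target = numeric(), realized = numeric(),
               stringsAsFactors = FALSE)

  # carboxylate second oxygen for planted Asp/Glu, set back along the line to
  # the CA so the planted group minimum distance is preserved exactly
  sib_map <- list(c("ASP", "OD1", "OD2", 0.8), c("GLU", "OE1", "OE2", 0.8))
  for (sb in sib_map) {
    rows <- which(atoms$resname == sb[1] & atoms$atom == sb[2] & !atoms$is_mainchain)
    for (r in rows) {
      if (length(find_atom(atoms$chain[r], atoms$resno[r], sb[3]))) next
      u <- unit3(ca_of(atoms$chain[r], atoms$resno[r]) - xyz_of(r))
      idx <- add_atom(atoms$chain[r], atoms$resno[r], sb[3])
      atoms[idx, c("x", "y", "z")] <- xyz_of(r) + as.numeric(sb[4]) * u
    }
  }

  # ---- bridging waters ----------------------------------------------------
  wat_no <- 9000L
  for (wb in spec$waters) {
    w_list <- list(wb)
    if (spec$symmetric_interactions) {
      sw <- function(ch) ifelse(ch == "A", "B", "A")
      m <- wb; m$chain1 <- sw(m$chain1); m$chain2 <- sw(m$chain2)
      w_list <- c(w_list, list(m))
    }
    for (w in w_list) {
      q1 <- xyz_of(find_atom(w$chain1, w$res1, w$atom1))
      q2 <- xyz_of(find_atom(w$chain2, w$res2, w$atom2))
      leg <- if (is.null(w$leg)) 2.9 else w$leg
      dd <- sqrt(sum((q2 - q1)^2))
      if (2 * leg < dd) stop("make_toy_dimer: water bridge legs cannot span the anchors", call. = FALSE)
      u <- unit3(q2 - q1)
      xfoot <- dd / 2
      h <- sqrt(leg^2 - xfoot^2)
      perp <- c(0, 0, 1) - u * u[3]
      if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0) - u * u[1]
      perp <- unit3(perp)
      wat_no <- wat_no + 1L
      atoms <- rbind(atoms, data.frame(
        chain = w$chain1, resno = wat_no, icode = "", resname = "HOH",
        kind = "water", atom = "O", element = "O",
        x = q1[1] + xfoot * u[1] + h * perp[1],
        y = q1[2] + xfoot * u[2] + h * perp[2],
        z = q1[3] + xfoot * u[3] + h * perp[3],
        occ = 1, b = 30, altloc = "", is_mainchain = FALSE,
        stringsAsFactors = FALSE))
    }
  }

  # ---- metal sites ---------------------------------------------------------
  site_sep <- NA_real_
  if (!is.null(spec$metals)) {
    mx <- spec$metals$xyz
    mb <- mx %*% t(rot)
    met <- function(chain, xyz) {
      data.frame(chain = chain, resno = 8000L + seq_len(nrow(xyz)), icode = "",
                 resname = spec$metals$elements, kind = "metal",
                 atom = spec$metals$elements, element = spec$metals$elements,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 occ = 1, b = 20, altloc = "", is_mainchain = FALSE,
                 stringsAsFactors = FALSE)
    }
    atoms <- rbind(atoms, met("A", mx), met("B", mb))
    zn_a <- mx[spec$metals$elements == "ZN", , drop = FALSE]
    zn_b <- mb[spec$metals$elements == "ZN", , drop = FALSE]
    if (nrow(zn_a)) site_sep <- sqrt(sum((colMeans(zn_a) - colMeans(zn_b))^2))
  }

  model <- structure_model(atoms, structure_id = spec$structure_id)

  truth <- list(
    seed = spec$seed,
    geometry = spec$geometry,
    trace_chain_b = data.frame(resno = resno, displacement = sqrt(rowSums(d_b^2))),
    trace_chain_a = data.frame(resno = resno, displacement = sqrt(rowSums(d_a^2))),
    expected_mean_intra = mean(sqrt(rowSums(d_b^2))),
    expected_mean_chain_a = mean(sqrt(rowSums(d_a^2))),
    bfactor = list(profile_a = data.frame(resno = resno, value = bvals_a),
                   profile_b = data.frame(resno = resno, value = bvals_b),
                   bumps = bf$bumps,
                   mean_all_atom = mean(model$atoms$b[model$atoms$kind == "polymer"])),
    interactions = planted,
    census = census_from_planted(planted),
    site_separation = site_sep,
    params = spec)
  class(truth) <- "GroundTruth"

  if (spec$validate == "strict") validate_planted(model, planted)

  list(model = model, truth = truth)
}

# Expected census for the focal (chain A) loop; mirrored copies of the
# planted set belong to the equivalent chain-B loop and are not counted.
census_from_planted <- function(planted) {
  if (!nrow(planted)) {
    return(list(intra_strong = 0L, intra_strong_mainchain = 0L, inter_bonds = 0L))
  }
  intra <- planted$chain1 == "A" & planted$chain2 == "A"
  inter <- planted$chain1 == "A" & planted$chain2 == "B"
  strong <- planted$kind == "strong-hbond"
  mc <- planted$atom1 %in% MAINCHAIN_ATOMS & planted$atom2 %in% MAINCHAIN_ATOMS
  list(intra_strong = sum(intra & strong),
       intra_strong_mainchain = sum(intra & strong & mc),
       inter_bonds = sum(inter & planted$kind != "water-bridge"))
}

pair_key_planted <- function(df, c1, r1, a1, c2, r2, a2) {
  k1 <- paste(df[[c1]], df[[r1]], df[[a1]])
  k2 <- paste(df[[c2]], df[[r2]], df[[a2]])
  paste(pmin(k1, k2), pmax(k1, k2), sep = " <> ")
}

# Strict generation-time audit: the realized interaction sets must equal the
# planted ones, otherwise the fixture's ground truth would be a lie.
validate_planted <- function(model, planted) {
  hb <- detect_hbonds(model)
  sb <- detect_salt_bridges(model)
  hb_key <- pair_key_planted(hb, "chain1", "resno1", "atom1", "chain2", "resno2", "atom2")
  sb_key <- pair_key_planted(sb, "chain1", "resno1", "atom1", "chain2", "resno2", "atom2")
  pl_key <- pair_key_planted(planted, "chain1", "res1", "atom1", "chain2", "res2", "atom2")

  exp_strong <- pl_key[planted$kind == "strong-hbond"]
  got_strong <- hb_key[hb$kind == "strong-hbond"]
  exp_salt <- pl_key[planted$kind == "salt-bridge"]
  # a 4.9 A salt bridge is also inside the weak H-bond distance class
  exp_weak_inter <- pl_key[planted$kind %in% c("weak-hbond", "salt-bridge") &
                             planted$chain1 != planted$chain2]
  got_weak_inter <- hb_key[hb$kind == "weak-hbond" & hb$topology == "inter-chain"]
  problems <- character()
  if (!setequal(got_strong, exp_strong)) {
    problems <- c(problems, sprintf(
      "strong H-bonds: %d unplanned [%s], %d missing [%s]",
      length(setdiff(got_strong, exp_strong)),
      paste(utils::head(setdiff(got_strong, exp_strong), 4), collapse = "; "),
      length(setdiff(exp_strong, got_strong)),
      paste(utils::head(setdiff(exp_strong, got_strong), 4), collapse = "; ")))
  }
  if (!setequal(sb_key, exp_salt)) {
    problems <- c(problems, sprintf(
      "salt bridges: got [%s], planted [%s]",
      paste(sb_key, collapse = "; "), paste(exp_salt, collapse = "; ")))
  }
  if (length(setdiff(got_weak_inter, exp_weak_inter))) {
    problems <- c(problems, sprintf(
      "unplanned inter-chain weak contacts: [%s]",
      paste(utils::head(setdiff(got_weak_inter, exp_weak_inter), 6), collapse = "; ")))
  }
  if (any(abs(planted$realized - planted$target) > 1e-6)) {
    problems <- c(problems, "planted distances not realized exactly")
  }
  if (length(problems)) {
    stop("make_toy_dimer: planted-geometry audit failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Serialize a ground-truth sidecar as JSON
#' @param truth a `GroundTruth` from [make_toy_dimer()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$params <- out$params[setdiff(names(out$params), "bfactor")]
  out$params$baseline <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}

# ---- stability-data simulators --------------------------------------------

#' Simulate a thermal-inactivation series
#'
#' Rate constants follow the Arrhenius law
#' `k = exp(lnA - Ea*1000 / (R*T))` with multiplicative lognormal noise.
#'
#' @param ea_kj activation energy, kJ/mol.
#' @param lnA log pre-exponential factor (k in 1/s).
#' @param temperatures_C incubation temperatures, Celsius.
#' @param noise_sd lognormal sigma (0 = exact).
#' @param seed integer seed.
#' @return An [inactivation_series()]; the planted parameters are attached as
#'   attribute `truth`.
#' @export
simulate_inactivation <- function(ea_kj, lnA, temperatures_C = seq(10, 27, length.out = 8),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(ea_kj > 0, length(temperatures_C) >= 3L)
  set.seed(seed)
  tk <- temperatures_C + 273.15
  k <- exp(lnA - ea_kj * 1000 / (RGAS * tk))
  k <- k * exp(stats::rnorm(length(k), sd = noise_sd))
  s <- inactivation_series(temperatures_C, k)
  attr(s, "truth") <- list(ea_kj = ea_kj, lnA = lnA, noise_sd = noise_sd, seed = seed)
  s
}

#' Simulate a two-state melting curve
#'
#' Sigmoid between linear folded/unfolded baselines plus Gaussian noise.
#'
#' @param tm_C planted midpoint, Celsius.
#' @param steepness transition width parameter, Celsius.
#' @param baseline_folded,baseline_unfolded `c(intercept, slope)` pairs.
#' @param temperatures_C temperature grid (default 20-90 by 1).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param seed integer seed.
#' @return A [melt_curve()]; planted parameters attached as attribute `truth`.
#' @export
simulate_melt <- function(tm_C = 50.8, steepness = 2.2,
                          baseline_folded = c(-20, -0.05),
                          baseline_unfolded = c(-2, -0.01),
                          temperatures_C = seq(20, 90, by = 1),
                          noise_sd = 0, seed = 1L) {
  set.seed(seed)
  tt <- temperatures_C
  fu <- 1 / (1 + exp((tm_C - tt) / steepness))
  fn <- baseline_folded[1] + baseline_folded[2] * tt
  fd <- baseline_unfolded[1] + baseline_unfolded[2] * tt
  y <- fn + (fd - fn) * fu + stats::rnorm(length(tt), sd = noise_sd)
  curve <- melt_curve(tt, y)
  attr(curve, "truth") <- list(tm_C = tm_C, steepness = steepness,
                               noise_sd = noise_sd, seed = seed)
  curve
}

#' Simulate Michaelis-Menten rate data
#'
#' @param kcat turnover number, 1/s.
#' @param km_mM Michaelis constant, mM.
#' @param enzyme_conc enzyme concentration (rate = kcat * enzyme_conc at
#'   saturation).
#' @param substrate_mM substrate grid, mM (default spans 0.0125-1.0).
#' @param noise_sd relative Gaussian noise.
#' @param seed integer seed.
#' @return data.frame with `substrate_mM`, `rate`; planted parameters attached
#'   as attribute `truth`.
#' @export
simulate_mm <- function(kcat = 302, km_mM = 0.19, enzyme_conc = 1,
                        substrate_mM = c(0.0125, 0.025, 0.05, 0.1, 0.2, 0.4, 0.8, 1.0),
                        noise_sd = 0, seed = 1L) {
  stopifnot(all(substrate_mM > 0))
  set.seed(seed)
  v <- kcat * enzyme_conc * substrate_mM / (km_mM + substrate_mM)
  v <- v * (1 + stats::rnorm(length(v), sd = noise_sd))
  out <- data.frame(substrate_mM = substrate_mM, rate = v)
  attr(out, "truth") <- list(kcat = kcat, km_mM = km_mM,
                             enzyme_conc = enzyme_conc, noise_sd = noise_sd,
                             seed = seed)
  out
}
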