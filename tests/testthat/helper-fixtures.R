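# Shared fixtures and independent oracles for the test suite.

# Small helical dimer: two parallel ideal alpha-helices related by a two-fold
# axis, optionally with planted contacts.
helix_dimer <- function(n = 20, interactions = list(), seed = 1,
                        displacements = list(), jitter_b = 0) {
  spec <- toy_dimer_spec(n_res = n, geometry = "ideal-helix",
                         interactions = interactions,
                         chain_b_offsets = displacements,
                         jitter_b = jitter_b, seed = seed)
  make_toy_dimer(spec)
}

# Build a bare StructureModel from a compact atom description:
# list(chain, resno, resname, atom, xyz, b)
model_from_atoms <- function(..., structure_id = "fixture") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain, resno = r$resno, icode = "",
               resname = r$resname,
               kind = if (r$resname %in% c("HOH")) "water" else
                 if (r$resname %in% c("ZN", "MG")) "metal" else "polymer",
               atom = r$atom, element = substr(r$atom, 1, 1),
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occ = 1, b = if (is.null(r$b)) 20 else r$b, altloc = "",
               stringsAsFactors = FALSE)
  }))
  df$element[df$resname %in% c("ZN", "MG")] <- df$resname[df$resname %in% c("ZN", "MG")]
  df$is_mainchain <- df$kind == "polymer" & df$atom %in% c("N", "CA", "C", "O")
  structure_model(df, structure_id = structure_id)
}

# A minimal residue (N, CA, C, O) centred at `at`, lying along x.
res_atoms <- function(chain, resno, at, resname = "GLY", b = 20) {
  list(
    list(chain = chain, resno = resno, resname = resname, atom = "N",
         xyz = at + c(-1.2, 0, 0), b = b),
    list(chain = chain, resno = resno, resname = resname, atom = "CA",
         xyz = at, b = b),
    list(chain = chain, resno = resno, resname = resname, atom = "C",
         xyz = at + c(1.5, 0, 0), b = b),
    list(chain = chain, resno = resno, resname = resname, atom = "O",
         xyz = at + c(1.5, 1.23, 0), b = b))
}

# Brute-force rigid-superposition oracle: minimizes rmsd over Euler angles
# and translation (translation optimal = centroid match) by multi-start
# numerical optimization, independent of the SVD route.
oracle_rmsd <- function(A, B, n_starts = 12) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
  }
  set.seed(99)
  best <- Inf
  for (i in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  best
}

# Exhaustive all-pairs hydrogen-bond scan implementing the same distance
# rules as the detector, written independently with plain loops over an
# explicit donor/acceptor table.
oracle_hbond_scan <- function(model, d_strong = 3.0, d_weak_max = 5.0,
                              d_min = 2.2) {
  a <- model$atoms
  a <- a[a$kind == "polymer" & a$element != "H", ]
  sidedon <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"), TRP = "NE1", ASN = "ND2",
                  GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG")
  sideacc <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
                  GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
                  TYR = "OH", MET = "SD", CYS = "SG")
  is_don <- function(i) {
    a$atom[i] == "N" || a$atom[i] %in% sidedon[[a$resname[i]]]
  }
  is_acc <- function(i) {
    a$atom[i] %in% c("O", "OXT") || a$atom[i] %in% sideacc[[a$resname[i]]]
  }
  out <- list()
  n <- nrow(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(a$x[j], a$y[j], a$z[j]))^2))
      if (d < d_min || d > d_weak_max) next
      if (!((is_don(i) && is_acc(j)) || (is_don(j) && is_acc(i)))) next
      if (a$chain[i] == a$chain[j] && a$resno[i] == a$resno[j]) next
      adjacent <- a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) == 1 &&
        a$is_mainchain[i] && a$is_mainchain[j] &&
        sort(c(a$atom[i], a$atom[j]))[1] == "N" &&
        sort(c(a$atom[i], a$atom[j]))[2] == "O" && d < 2.6
      if (adjacent) next
      out[[length(out) + 1]] <- data.frame(
        chain_i = a$chain[i], res_i = a$resno[i], atom_i = a$atom[i],
        chain_j = a$chain[j], res_j = a$resno[j], atom_j = a$atom[j],
        distance = d,
        kind = if (d < d_strong) "strong-hbond" else "weak-hbond",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# canonical unordered pair keys for comparing edge sets
edge_keys <- function(df, c1, r1, a1, c2, r2, a2) {
  k1 <- paste(df[[c1]], df[[r1]], df[[a1]])
  k2 <- paste(df[[c2]], df[[r2]], df[[a2]])
  sort(paste(pmin(k1, k2), pmax(k1, k2), sep = "|"))
}

# Direct numeric root-finder for the Arrhenius half-loss temperature.
oracle_t50 <- function(ea_kj, lnA, k_half = log(2) / 1800) {
  f <- function(tC) lnA - ea_kj * 1000 / (8.314 * (tC + 273.15)) - log(k_half)
  stats::uniroot(f, c(-272, 2e4), tol = 1e-10)$root
}

minimal_pdb_text <- function() {
  c("HEADER    TEST FIXTURE",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 12.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 14.00           C",
    "END")
}

altloc_pdb_text <- function() {
  c("ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  OG ASER A   1       2.000   1.000   0.000  0.60 11.00           O",
    "ATOM      4  OG BSER A   1       2.100   1.100   0.000  0.40 12.00           O",
    "END")
}
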