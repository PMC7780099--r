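#' @keywords internal
"_PACKAGE"

# Atom names making up the peptide backbone for flag purposes.
MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
METAL_ELEMENTS <- c("ZN", "MG", "MN", "CA", "FE", "NA", "K", "CU", "NI", "CO")

ATOM_COLUMNS <- c("chain", "resno", "icode", "resname", "kind", "atom",
                  "element", "x", "y", "z", "occ", "b", "altloc",
                  "is_mainchain")

#' Construct a structure model
#'
#' A `StructureModel` is the package's in-memory representation of one crystal
#' structure: a flat atom table (one row per atom, in the style of the
#' coordinate section of a PDB file) plus structure-level metadata.  All
#' geometry, B-factor and interaction functions in the package consume this
#' class, so downstream code never touches file formats directly.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `kind` (one of `"polymer"`, `"water"`, `"metal"`, `"hetero"`), `atom`
#'   (atom name), `element`, `x`, `y`, `z` (Angstrom), `occ`, `b` (Angstrom^2),
#'   `altloc`.  An `is_mainchain` column is derived if absent.
#' @param structure_id character label for the structure.
#' @param resolution optional resolution in Angstrom (`NA` if unknown).
#' @param space_group optional space-group symbol (`NA` if unknown).
#'
#' @return An object of class `StructureModel`: a list with elements
#'   `structure_id`, `atoms`, `resolution`, `space_group`.
#' @export
structure_model <- function(atoms, structure_id = "model",
                            resolution = NA_real_, space_group = NA_character_) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0L) {
    stop("structure_model: no atoms", call. = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  if (is.null(atoms$kind)) atoms$kind <- "polymer"
  if (is.null(atoms$is_mainchain)) {
    atoms$is_mainchain <- atoms$kind == "polymer" & atoms$atom %in% MAINCHAIN_ATOMS
  }
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols)) {
    stop("structure_model: missing atom columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  atoms <- atoms[ATOM_COLUMNS]
  atoms$resno <- as.integer(atoms$resno)
  atoms$icode[is.na(atoms$icode)] <- ""
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("structure_model: non-finite coordinates", call. = FALSE)
  if (any(atoms$b < 0)) stop("structure_model: negative B-factor", call. = FALSE)
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    stop("structure_model: occupancy outside [0, 1]", call. = FALSE)
  }
  if (any(nchar(atoms$chain) != 1L)) {
    stop("structure_model: chain identifiers must be single characters", call. = FALSE)
  }
  ord <- order(atoms$chain, atoms$kind != "polymer", atoms$resno, atoms$icode)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  model <- structure(
    list(structure_id = structure_id, atoms = atoms,
         resolution = resolution, space_group = space_group),
    class = "StructureModel")
  model
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel '%s': %d atoms, chains [%s]\n",
              x$structure_id, nrow(a), paste(chain_ids(x), collapse = ", ")))
  for (k in unique(a$kind)) {
    cat(sprintf("  %-8s %6d atoms, %5d residues\n", k, sum(a$kind == k),
                length(unique(paste(a$chain, a$resno, a$icode)[a$kind == k]))))
  }
  invisible(x)
}

guess_element <- function(atom_names) {
  e <- sub("^[0-9]*", "", atom_names)
  two <- toupper(e) %in% METAL_ELEMENTS & nchar(e) <= 2
  ifelse(two, toupper(e), toupper(substr(e, 1L, 1L)))
}

#' Chain identifiers of a structure
#' @param model a `StructureModel`.
#' @return character vector of chain identifiers, in file order.
#' @export
chain_ids <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  unique(model$atoms$chain)
}

#' Extract one chain of a structure
#'
#' @param model a `StructureModel`.
#' @param chain_id single-character chain identifier.
#' @param polymer_only drop waters/metals/hetero groups sharing the chain id.
#' @return A `ChainModel`: the chain's atom table (same columns as
#'   `model$atoms`) with attributes `chain_id` and `structure_id`.
#' @export
get_chain <- function(model, chain_id, polymer_only = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  sel <- model$atoms$chain == chain_id
  if (!any(sel)) {
    stop(sprintf("get_chain: no chain '%s' in structure '%s'",
                 chain_id, model$structure_id), call. = FALSE)
  }
  atoms <- model$atoms[sel, , drop = FALSE]
  if (polymer_only) atoms <- atoms[atoms$kind == "polymer", , drop = FALSE]
  rownames(atoms) <- NULL
  structure(atoms, chain_id = chain_id, structure_id = model$structure_id,
            class = c("ChainModel", "data.frame"))
}

#' Look up one residue by author numbering
#'
#' Residues are addressed exactly as numbered in the coordinate file (author
#' numbering, 1-based and possibly gapped), so residue labels from the
#' literature (R336, S79, ...) can be used verbatim.
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @param seq_num author residue number.
#' @param icode insertion code (default none).
#' @return A `ResidueRecord`: the residue's atom rows with attributes
#'   `resname`, `kind`, `chain_id`, `seq_num`, `icode`.
#' @export
select_residue <- function(model, chain_id, seq_num, icode = "") {
  ch <- get_chain(model, chain_id)
  sel <- ch$resno == seq_num & ch$icode == icode
  if (!any(sel)) {
    stop(sprintf("select_residue: no residue %s%s in chain %s of '%s'",
                 seq_num, icode, chain_id, model$structure_id), call. = FALSE)
  }
  res <- as.data.frame(ch[sel, , drop = FALSE])
  rownames(res) <- NULL
  structure(res, resname = res$resname[1L], kind = res$kind[1L],
            chain_id = chain_id, seq_num = as.integer(seq_num), icode = icode,
            class = c("ResidueRecord", "data.frame"))
}

residue_key <- function(atoms) paste(atoms$resno, atoms$icode, sep = "|")

#' Map equivalent residues between two chains
#'
#' Pairs polymer residues carrying identical author numbering
#' (`seq_num` + insertion code) in both chains, the correspondence needed to
#' superpose one monomer of a homodimer onto the other (or onto a point-mutant
#' structure with conserved numbering).  Only pairs where both residues expose
#' a CA atom are retained; residues present in just one chain are excluded and
#' counted.  Residue-name mismatches at matched positions are allowed (point
#' mutants) and recorded.
#'
#' @param chain_a,chain_b `ChainModel` objects (see [get_chain()]).
#' @return A `Correspondence`: data.frame with columns `resno`, `icode`,
#'   `resname_a`, `resname_b` and attributes `n_unmatched_a`, `n_unmatched_b`,
#'   `n_mismatched_names`.
#' @export
map_equivalent_residues <- function(chain_a, chain_b) {
  stopifnot(inherits(chain_a, "ChainModel"), inherits(chain_b, "ChainModel"))
  pa <- chain_a[chain_a$kind == "polymer", , drop = FALSE]
  pb <- chain_b[chain_b$kind == "polymer", , drop = FALSE]
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop("map_equivalent_residues: both chains must contain polymer residues",
         call. = FALSE)
  }
  ca_a <- pa[pa$atom == "CA", , drop = FALSE]
  ca_b <- pb[pb$atom == "CA", , drop = FALSE]
  key_a <- residue_key(ca_a)
  key_b <- residue_key(ca_b)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) {
    stop("map_equivalent_residues: zero matched residue pairs", call. = FALSE)
  }
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  pairs <- data.frame(resno = ca_a$resno[ia], icode = ca_a$icode[ia],
                      resname_a = ca_a$resname[ia], resname_b = ca_b$resname[ib],
                      stringsAsFactors = FALSE)
  ord <- order(pairs$resno, pairs$icode)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs,
            n_unmatched_a = length(setdiff(key_a, key_b)),
            n_unmatched_b = length(setdiff(key_b, key_a)),
            n_mismatched_names = sum(pairs$resname_a != pairs$resname_b),
            class = c("Correspondence", "data.frame"))
}

#' @export
print.Correspondence <- function(x, ...) {
  cat(sprintf("Correspondence: %d residue pairs (%d unmatched in A, %d in B, %d name mismatches)\n",
              nrow(x), attr(x, "n_unmatched_a"), attr(x, "n_unmatched_b"),
              attr(x, "n_mismatched_names")))
  invisible(x)
}

residue_label <- function(resname, resno, icode = "") {
  paste0(resname, resno, ifelse(icode == "", "", icode))
}
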