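#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF coordinate file (via bio3d) into a [structure_model()].
#' All ATOM/HETATM records are represented; waters are classified
#' `kind = "water"`, single-atom Zn/Mg-type hetero groups `kind = "metal"`,
#' remaining hetero groups `kind = "hetero"`.  Where alternate locations are
#' present, the highest-occupancy conformer is retained per atom (first listed
#' wins ties) and the number of dropped records is reported via a message:
#' downstream distance analysis assumes single-conformer geometry.
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param structure_id label for the model; defaults to the file base name.
#' @return A `StructureModel`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("read_structure: file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      stop(sprintf("read_structure: cannot parse '%s' as %s (%s)%s",
                   path, toupper(format), conditionMessage(e),
                   first_bad_line(path, format)), call. = FALSE)
    })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop(sprintf("read_structure: no atoms in '%s'", path), call. = FALSE)
  }
  chain <- ifelse(is.na(at$chain) | at$chain == "", " ", at$chain)
  icode <- ifelse(is.na(at$insert), "", at$insert)
  altloc <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  b <- ifelse(is.na(at$b), 0, at$b)
  element <- ifelse(is.na(at$elesy) | at$elesy == "",
                    guess_element(at$elety), toupper(at$elesy))
  resname <- toupper(at$resid)
  kind <- classify_kind(at$type, resname, element, chain, at$resno, icode)
  atoms <- data.frame(chain = chain, resno = at$resno, icode = icode,
                      resname = resname, kind = kind, atom = at$elety,
                      element = element, x = at$x, y = at$y, z = at$z,
                      occ = occ, b = b, altloc = altloc,
                      stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  structure_model(atoms, structure_id = structure_id)
}

classify_kind <- function(type, resname, element, chain, resno, icode) {
  kind <- ifelse(type == "ATOM", "polymer", "hetero")
  kind[type != "ATOM" & resname %in% WATER_RESNAMES] <- "water"
  key <- paste(chain, resno, icode)
  grp_size <- table(key)
  single <- grp_size[key] == 1L
  kind[type != "ATOM" & kind == "hetero" & single & element %in% METAL_ELEMENTS] <- "metal"
  kind
}

# Altloc policy: per atom site keep the highest-occupancy record, first
# listed on ties; never increases the atom count.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  keep <- !duplicated(key[ord])
  dropped <- sum(!keep)
  out <- atoms[ord, , drop = FALSE][keep, , drop = FALSE]
  out <- out[order(as.integer(factor(key[ord][keep], levels = unique(key)))), ,
             drop = FALSE]
  message(sprintf("read_structure: dropped %d lower-occupancy alternate location record(s)",
                  dropped))
  rownames(out) <- NULL
  out
}

first_bad_line <- function(path, format) {
  if (format != "pdb") return("")
  ok <- c("ATOM", "HETATM", "TER", "END", "ENDMDL", "MODEL", "HEADER", "TITLE",
          "REMARK", "SEQRES", "HELIX", "SHEET", "CRYST1", "SCALE", "ORIGX",
          "COMPND", "SOURCE", "KEYWDS", "EXPDTA", "AUTHOR", "REVDAT", "JRNL",
          "DBREF", "SEQADV", "MODRES", "HET", "HETNAM", "HETSYN", "FORMUL",
          "SSBOND", "LINK", "CISPEP", "SITE", "CONECT", "MASTER", "ANISOU",
          "OBSLTE", "SPRSDE", "CAVEAT", "SPLIT", "NUMMDL", "MTRIX", "SEQ")
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  rec <- toupper(substr(lines, 1, 6))
  bad <- which(!trimws(rec) %in% ok & nzchar(trimws(lines)))
  if (length(bad)) sprintf("; first unrecognized record at line %d", bad[1L]) else ""
}

#' Write a structure model as PDB text
#'
#' Emits standard fixed-column PDB ATOM/HETATM records (via bio3d), re-readable
#' by [read_structure()].  Coordinates are preserved to 3 decimals and
#' B-factors to 2 decimals (the format's precision).
#'
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  if (nrow(a) == 0L) stop("write_structure: empty model", call. = FALSE)
  if (any(nchar(a$chain) > 1L)) {
    stop("write_structure: chain identifiers longer than one character cannot be written as PDB",
         call. = FALSE)
  }
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$kind == "polymer", "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$atom, chain = a$chain, insert = a$icode,
                   alt = ifelse(a$altloc == "", NA, a$altloc),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}
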