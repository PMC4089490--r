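# Hierarchical coordinate model: a structure is an atom table plus provenance.
# Author residue numbering is preserved throughout; hydrogens are never kept.

# Fixed heavy-atom van der Waals radii (Angstrom), Bondi-style set.
# Unknown elements are an error, never silently defaulted.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Fixed 20-entry three-letter -> one-letter table; anything else maps to "X".
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.AA1TO3 <- structure(names(.AA3TO1), names = unname(.AA3TO1))

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (e.g. `"C"`, `"O"`).
#' @return numeric vector of radii in Angstrom.
#' @details Only the heavy-atom set C/N/O/S is supported; hydrogens are
#'   excluded from all analyses and any other element raises an error so that
#'   surface areas are never computed with a silently guessed radius.
#' @export
vdw_radius <- function(element) {
  element <- toupper(trimws(element))
  bad <- !(element %in% names(.VDW_RADII))
  if (any(bad)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[bad]), collapse = ", "))
  }
  unname(.VDW_RADII[element])
}

#' Convert three-letter residue codes to one-letter codes
#'
#' @param resid character vector of three-letter codes.
#' @return one-letter codes; `"X"` for anything outside the standard 20.
#' @export
aa_three_to_one <- function(resid) {
  out <- .AA3TO1[toupper(trimws(resid))]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Convert one-letter residue codes to three-letter codes
#' @param aa character vector of one-letter codes.
#' @return three-letter codes; `"UNK"` for unknown letters.
#' @export
aa_one_to_three <- function(aa) {
  out <- .AA1TO3[toupper(aa)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

.element_from_name <- function(elety) {
  # First alphabetic character of the atom name; adequate for protein
  # heavy atoms (CA -> C, OD1 -> O, NZ -> N, SG -> S).
  e <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", trimws(elety))
  toupper(e)
}

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `serial`, `elety` (atom name), `alt`,
#'   `resid` (three-letter residue code), `chain`, `resno`, `icode`, `x`, `y`,
#'   `z`, `occ`, `element`.
#' @param id structure identifier string.
#' @param metadata free-form provenance list.
#' @return object of class `pyd_structure`.
#' @details Assigns van der Waals radii from the fixed element table (erroring
#'   on unknown elements), checks coordinate finiteness and uniqueness of
#'   (chain, resno, icode, elety, alt) atom records.
#' @export
new_structure <- function(atoms, id = "structure", metadata = list()) {
  stopifnot(is.data.frame(atoms))
  required <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms after filtering")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$elety)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atomic coordinates")
  atoms$radius <- vdw_radius(atoms$element)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, atoms$alt)
  if (anyDuplicated(key)) {
    stop("duplicate atom record(s): ", key[which(duplicated(key))[1]])
  }
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, metadata = metadata),
    class = "pyd_structure"
  )
}

#' @export
print.pyd_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc) nrow(unique(
    x$atoms[x$atoms$chain == cc, c("resno", "icode")])), integer(1))
  cat("pyd_structure '", x$id, "': ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s)\n", sep = "")
  cat("  chains:", paste0(ch, " (", nres, " res)", collapse = ", "), "\n")
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s a `pyd_structure`.
#' @return character vector of chain ids in order of first appearance.
#' @export
chain_ids <- function(s) {
  stopifnot(inherits(s, "pyd_structure"))
  unique(s$atoms$chain)
}

.apply_altloc_policy <- function(atoms, policy) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    a <- alt[idx]
    if (policy == "first") return(idx[1])
    occ <- atoms$occ[idx]
    occ[is.na(occ)] <- 0
    cand <- idx[occ == max(occ)]
    # occupancy ties broken by altloc character order
    cand[order(alt[cand])][1]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' @param path file path.
#' @param format `"pdb"` (reference dialect) or `"mmcif"`.
#' @param keep_het keep non-water HETATM records? Waters are always dropped.
#' @param altloc_policy `"highest_occupancy"` (ties broken by altloc character
#'   order) or `"first"`; exactly one conformer is retained per atom.
#' @return a [new_structure()] object. Hydrogens (and deuteriums) are dropped;
#'   author residue numbering and insertion codes are preserved.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"), keep_het = FALSE,
                           altloc_policy = c("highest_occupancy", "first")) {
  format <- match.arg(format)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (!keep_het) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  } else {
    at <- at[at$type == "ATOM" |
               !(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- toupper(trimws(elem))
  fix <- is.na(elem) | elem == ""
  elem[fix] <- .element_from_name(at$elety[fix])
  hyd <- elem %in% c("H", "D")
  at <- at[!hyd, , drop = FALSE]
  elem <- elem[!hyd]
  if (nrow(at) == 0) stop("empty structure: no protein atoms in '", path, "'")
  atoms <- data.frame(
    serial = at$eleno,
    elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    element = elem,
    stringsAsFactors = FALSE
  )
  atoms <- .apply_altloc_policy(atoms, altloc_policy)
  atoms$alt <- ""
  new_structure(atoms, id = sub("\\.(pdb|cif|ent)$", "", basename(path)),
                metadata = list(source = path, format = format,
                                keep_het = keep_het,
                                altloc_policy = altloc_policy))
}

#' Write a structure to a PDB-format file
#'
#' @param s a `pyd_structure`.
#' @param path output file path.
#' @return invisibly, `path`. Coordinates are written to 3 decimals;
#'   re-reading reproduces identifiers exactly and coordinates to 3 decimals.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "pyd_structure"))
  a <- s$atoms
  if (nrow(a) == 0) stop("cannot write an empty structure")
  if (any(a$resno > 9999 | a$resno < -999)) {
    stop("residue numbers outside the PDB-encodable range")
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain, insert = a$icode,
    o = a$occ, b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

#' Select atoms of a structure
#'
#' Deterministic predicate-based atom selection; the building block for all
#' surface and contact computations.
#'
#' @param s a `pyd_structure`.
#' @param chains chain ids to keep (`NULL` = all).
#' @param resno residue numbers to keep (`NULL` = all).
#' @param resid three-letter residue names to keep (`NULL` = all).
#' @param elety atom names to keep (`NULL` = all).
#' @param part `"all"`, `"sidechain"` (non-backbone) or `"backbone"`
#'   (N, CA, C, O, OXT).
#' @return integer vector of row indices into `s$atoms` (possibly empty).
#' @export
select_atoms <- function(s, chains = NULL, resno = NULL, resid = NULL,
                         elety = NULL, part = c("all", "sidechain", "backbone")) {
  stopifnot(inherits(s, "pyd_structure"))
  part <- match.arg(part)
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & toupper(a$resid) %in% toupper(resid)
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (part == "sidechain") keep <- keep & !(a$elety %in% .BACKBONE_ATOMS)
  if (part == "backbone") keep <- keep & a$elety %in% .BACKBONE_ATOMS
  which(keep)
}

.atom_xyz <- function(s, idx = NULL) {
  a <- if (is.null(idx)) s$atoms else s$atoms[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

.residue_key <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resno,
         ifelse(atoms$icode == "", "", atoms$icode))
}

#' Residue table of one chain
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @return data.frame with one row per residue (`resno`, `icode`, `resid`,
#'   `one_letter`) in file order.
#' @export
chain_residues <- function(s, chain_id) {
  stopifnot(inherits(s, "pyd_structure"))
  a <- s$atoms[s$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) stop("no such chain: '", chain_id, "'")
  key <- paste(a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    resno = a$resno[first], icode = a$icode[first], resid = a$resid[first],
    one_letter = aa_three_to_one(a$resid[first]),
    stringsAsFactors = FALSE
  )
}

#' Extract the one-letter sequence of a chain
#'
#' @param s a `pyd_structure`.
#' @param chain_id chain identifier.
#' @return list with `sequence` (single string, `"X"` for nonstandard
#'   residues) and `map` (data.frame `position` vs author `resno`/`icode`,
#'   a bijection between sequence positions and residue numbers).
#' @export
extract_sequence <- function(s, chain_id) {
  res <- chain_residues(s, chain_id)
  list(
    sequence = paste(res$one_letter, collapse = ""),
    map = data.frame(position = seq_len(nrow(res)), resno = res$resno,
                     icode = res$icode, stringsAsFactors = FALSE)
  )
}
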