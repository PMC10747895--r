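#' Read an atomic model from PDB or mmCIF
#'
#' Parses coordinate files through bio3d and normalizes them into an
#' [assembly_model]. The B-factor column is preserved verbatim: for
#' predictor output it carries per-residue pLDDT on the 0-100 scale.
#' Alternate locations are reduced to the highest-occupancy conformer;
#' hydrogens and waters are dropped by default (predicted models contain
#' neither, and interface areas are computed on heavy atoms). For
#' multi-model (NMR-style) files only model 1 is used.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension: .cif/.mmcif vs rest).
#' @param keep_hydrogens keep H/D atoms (default FALSE).
#' @param keep_waters keep water HETATMs (default FALSE).
#' @return An [assembly_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hydrogens = FALSE, keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse %s as %s: %s",
                                     path, format, conditionMessage(e))))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in file: ", path)
  el <- a$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(a))
  el[is.na(el) | el == ""] <- guess_element(a$elety[is.na(el) | el == ""])
  atoms <- data.frame(
    name = a$elety, element = toupper(el), resno = a$resno,
    ins = ifelse(is.na(a$insert), "", a$insert), resid = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    alt = if (is.null(a$alt)) "" else ifelse(is.na(a$alt), "", a$alt),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  if (!keep_waters) atoms <- atoms[!(atoms$het & atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms left after filtering: ", path)
  # alternate locations: keep the highest-occupancy conformer per atom identity
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name, sep = "\r")
    ord <- order(key, -atoms$occ)
    atoms <- atoms[ord, ][!duplicated(key[ord]), , drop = FALSE]
  }
  atoms$alt <- NULL; atoms$het <- NULL
  assembly_model(atoms, name = sub("\\.[^.]*$", "", basename(path)),
                 source = path)
}

guess_element <- function(atom_names) {
  if (!length(atom_names)) return(character(0))
  # strip digits/primes, take first letter; two-letter check for common cases
  nm <- toupper(gsub("[0-9*']", "", atom_names))
  el <- substr(nm, 1, 1)
  el[nm %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "CA_ION")] <- nm[nm %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "CA_ION")]
  el
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB output goes through bio3d; mmCIF output is a minimal `atom_site`
#' loop (label and auth fields, coordinates to 3 decimals, B to 2) that
#' round-trips through [read_structure]. Models with more than 62 chains or
#' multi-character chain ids cannot be expressed in the single-character
#' PDB dialect and are refused with a pointer to mmCIF.
#'
#' @param model an [assembly_model].
#' @param path output path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    ids <- chain_ids(model)
    if (length(ids) > 62L || any(nchar(ids) > 1L))
      stop("model needs ", length(ids), " chain ids, beyond the single-character ",
           "PDB dialect: write mmCIF instead (format = 'mmcif')")
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, eleno = a$serial,
                     elety = a$name, chain = a$chain, insert = a$ins,
                     o = a$occ, b = a$b, elesy = a$element)
  } else {
    write_mmcif(model, path)
  }
  invisible(path)
}

# minimal mmCIF writer: one atom_site loop, auth numbering = label numbering
write_mmcif <- function(model, path) {
  a <- model$atoms
  chains <- chain_ids(model)
  ent <- match(a$chain, chains)
  lines <- c(
    sprintf("data_%s", gsub("[^A-Za-z0-9_-]", "_", model$name)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s %d %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            a$serial, a$element, a$name, a$resid, a$chain, ent, a$resno,
            ifelse(a$ins == "", "?", a$ins), a$x, a$y, a$z, a$occ, a$b,
            a$resno, a$resid, a$chain, a$name),
    "#")
  writeLines(lines, path)
  invisible(path)
}
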