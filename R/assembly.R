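#' Hierarchical atomic model
#'
#' `assembly_model` is the universal coordinate container of the package: a
#' flat atom table organised as chains -> residues -> atoms, with per-residue
#' predictor confidence (pLDDT, 0-100) carried in the B-factor column, as
#' structure predictors write it.
#'
#' The atom table has columns `serial` (integer), `name` (atom name, e.g.
#' "CA"), `element` (element symbol), `resno` (author residue number),
#' `ins` (insertion code, "" when absent), `resid` (3-letter residue name),
#' `chain` (chain id), `x`, `y`, `z` (Angstrom), `occ` (occupancy) and
#' `b` (isotropic B / pLDDT).
#'
#' @param atoms data.frame with the columns above (`serial` optional).
#' @param name model name (metadata).
#' @param source provenance note, e.g. the source file.
#' @return An object of class `assembly_model`.
#' @export
assembly_model <- function(atoms, name = "model", source = NA_character_) {
  req <- c("name", "element", "resno", "resid", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("no atoms: refusing to build an empty model")
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(is.na(atoms$element) | atoms$element == ""))
    stop("empty element symbol in atom table")
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  # order: chains by first appearance, residues by (resno, ins), file order inside
  chain_lev <- unique(atoms$chain)
  ord <- order(match(atoms$chain, chain_lev), atoms$resno, atoms$ins,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resno, ins, name): ",
         key[duplicated(key)][1])
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, name = name, source = source,
                 provenance = character(0)),
            class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("assembly_model '%s': %d chains, %d residues, %d atoms\n",
              x$name, length(chain_ids(x)), n_residues(x), nrow(x$atoms)))
  for (ch in chain_ids(x)) {
    a <- x$atoms[x$atoms$chain == ch, ]
    cat(sprintf("  chain %s: residues %d-%d (%d), mean B %.1f\n", ch,
                min(a$resno), max(a$resno),
                length(unique(paste(a$resno, a$ins))), mean(a$b)))
  }
  invisible(x)
}

#' Chain identifiers of a model, in model order
#' @param model an `assembly_model`.
#' @return character vector of chain ids.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Total residue count of a model
#' @param model an `assembly_model`.
#' @return integer, residues summed over chains.
#' @export
n_residues <- function(model) {
  a <- model$atoms
  length(unique(paste(a$chain, a$resno, a$ins, sep = "\r")))
}

#' Atom coordinates as a matrix
#' @param model an `assembly_model`.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Subset a model
#'
#' Select chains, residues (by author number) and/or atom names. Empty
#' selections are an error, never a silent empty model.
#'
#' @param model an `assembly_model`.
#' @param chains chain ids to keep (NULL = all).
#' @param residues residue numbers to keep: a length-2 vector is read as an
#'   inclusive interval `c(lo, hi)`, anything longer as an explicit set
#'   (NULL = all).
#' @param atom_names atom names to keep, e.g. "CA" (NULL = all).
#' @return A new `assembly_model`.
#' @export
select_atoms <- function(model, chains = NULL, residues = NULL,
                         atom_names = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) {
    missing <- setdiff(chains, a$chain)
    if (length(missing)) stop("chain(s) not in model: ", paste(missing, collapse = ", "))
    keep <- keep & a$chain %in% chains
  }
  if (!is.null(residues)) keep <- keep & a$resno %in% expand_range(residues)
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (!any(keep)) stop("selection matches no atoms")
  out <- model
  out$atoms <- a[keep, , drop = FALSE]
  out$atoms$serial <- seq_len(nrow(out$atoms))
  rownames(out$atoms) <- NULL
  out
}

# length-2 vector = inclusive interval, longer = explicit residue set
expand_range <- function(residues) {
  residues <- as.integer(residues)
  if (length(residues) == 2L && residues[2] >= residues[1])
    seq.int(residues[1], residues[2]) else residues
}

#' Apply a rigid transform to a whole model
#' @param model an `assembly_model`.
#' @param tf a `rigid_transform`.
#' @return The transformed model (input untouched).
#' @export
transform_model <- function(model, tf) {
  set_coords(model, apply_transform(tf, coords(model)))
}

#' Merge models into one assembly
#'
#' Chains keep their ids; on collision the incoming chain is relabeled to
#' the first free id (A-Z, a-z, 0-9, then two-character ids) and the
#' relabeling recorded in `provenance`.
#'
#' @param ... `assembly_model` objects (or one list of them).
#' @param name name of the merged model.
#' @return A single `assembly_model`.
#' @export
merge_models <- function(..., name = "assembly") {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "assembly_model"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  used <- character(0)
  prov <- character(0)
  tabs <- list()
  for (p in seq_along(parts)) {
    m <- parts[[p]]
    a <- m$atoms
    for (ch in chain_ids(m)) {
      new_id <- ch
      if (new_id %in% used) {
        new_id <- next_chain_id(used)
        prov <- c(prov, sprintf("part %d chain %s -> %s", p, ch, new_id))
      }
      used <- c(used, new_id)
      sub <- a[a$chain == ch, , drop = FALSE]
      sub$chain <- new_id
      tabs[[length(tabs) + 1L]] <- sub
    }
  }
  out <- assembly_model(do.call(rbind, tabs), name = name)
  out$provenance <- prov
  out
}

chain_id_pool <- function() {
  one <- c(LETTERS, letters, as.character(0:9))
  c(one, as.vector(outer(one, one, paste0)))
}

next_chain_id <- function(used) {
  pool <- chain_id_pool()
  free <- setdiff(pool, used)
  if (!length(free)) stop("chain id pool exhausted")
  free[1]
}

#' Relabel chains sequentially
#'
#' @param model an `assembly_model`.
#' @param ids replacement ids in model chain order (default A, B, C, ...).
#' @return Model with relabeled chains.
#' @export
relabel_chains <- function(model, ids = NULL) {
  old <- chain_ids(model)
  if (is.null(ids)) ids <- chain_id_pool()[seq_along(old)]
  stopifnot(length(ids) == length(old), !anyDuplicated(ids))
  model$atoms$chain <- ids[match(model$atoms$chain, old)]
  model
}

#' Chain centroids
#' @param model an `assembly_model`.
#' @param atom_names atoms to average over (default CA only, falling back to
#'   all atoms for chains without CA).
#' @return matrix with one row per chain (rownames = chain ids).
#' @export
chain_centroids <- function(model, atom_names = "CA") {
  ids <- chain_ids(model)
  out <- t(vapply(ids, function(ch) {
    a <- model$atoms[model$atoms$chain == ch, ]
    ca <- a[a$name %in% atom_names, ]
    if (nrow(ca) == 0L) ca <- a
    c(mean(ca$x), mean(ca$y), mean(ca$z))
  }, numeric(3)))
  rownames(out) <- ids
  out
}

#' Residue numbers of a chain
#' @param model an `assembly_model`.
#' @param chain_id a chain id.
#' @return sorted integer vector of author residue numbers.
#' @export
residue_numbers <- function(model, chain_id) {
  a <- model$atoms[model$atoms$chain == chain_id, ]
  if (nrow(a) == 0L) stop("chain not in model: ", chain_id)
  sort(unique(a$resno))
}
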