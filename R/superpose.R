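#' Pair equivalent atoms of two chains
#'
#' Builds the ordered 1:1 atom pairing every superposition rests on.
#' Pairing is by author residue number by default; when numbering disagrees
#' between models, a global sequence alignment (Needleman-Wunsch, BLOSUM62,
#' gap open -10 / extend -0.5, via Biostrings) recovers the correspondence.
#' Residues missing on either side are dropped.
#'
#' @param ref,mov [assembly_model]s; must be single-chain unless
#'   `ref_chain`/`mov_chain` name the chain to use.
#' @param selection atoms to pair: "CA", "backbone" (N, CA, C, O) or "all"
#'   (all heavy atoms).
#' @param by "residue_number" or "sequence_alignment".
#' @param shared_range optional residue interval `c(lo, hi)` (or explicit
#'   set) restricting the pairing, in `ref` numbering.
#' @param ref_chain,mov_chain chain ids when the models have several.
#' @return list with `ref_xyz`, `mov_xyz` (paired N x 3 matrices) and
#'   `pairing` (data.frame ref_resno, mov_resno, name).
#' @export
match_atoms <- function(ref, mov, selection = c("CA", "backbone", "all"),
                        by = c("residue_number", "sequence_alignment"),
                        shared_range = NULL, ref_chain = NULL,
                        mov_chain = NULL) {
  selection <- match.arg(selection)
  by <- match.arg(by)
  ra <- single_chain_atoms(ref, ref_chain)
  ma <- single_chain_atoms(mov, mov_chain)
  ra <- filter_selection(ra, selection)
  ma <- filter_selection(ma, selection)
  if (by == "residue_number") {
    map <- data.frame(ref_resno = sort(unique(ra$resno)),
                      mov_resno = sort(unique(ra$resno)))
    map <- map[map$mov_resno %in% ma$resno, , drop = FALSE]
  } else {
    map <- align_residues(ra, ma)
  }
  if (!is.null(shared_range))
    map <- map[map$ref_resno %in% expand_range(shared_range), , drop = FALSE]
  pairs <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    rr <- ra[ra$resno == map$ref_resno[i], , drop = FALSE]
    mm <- ma[ma$resno == map$mov_resno[i], , drop = FALSE]
    common <- intersect(rr$name, mm$name)
    if (!length(common)) return(NULL)
    data.frame(ref_resno = map$ref_resno[i], mov_resno = map$mov_resno[i],
               name = common, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("fewer than 3 atom pairs under the pairing rule (",
         if (is.null(pairs)) 0L else nrow(pairs), " found)")
  ridx <- match(paste(pairs$ref_resno, pairs$name, sep = "\r"),
                paste(ra$resno, ra$name, sep = "\r"))
  midx <- match(paste(pairs$mov_resno, pairs$name, sep = "\r"),
                paste(ma$resno, ma$name, sep = "\r"))
  list(ref_xyz = as.matrix(ra[ridx, c("x", "y", "z")]),
       mov_xyz = as.matrix(ma[midx, c("x", "y", "z")]),
       pairing = pairs)
}

single_chain_atoms <- function(model, chain = NULL) {
  ids <- chain_ids(model)
  if (is.null(chain)) {
    if (length(ids) != 1L)
      stop("model has ", length(ids), " chains; name one explicitly")
    chain <- ids
  }
  if (!chain %in% ids) stop("chain not in model: ", chain)
  model$atoms[model$atoms$chain == chain, , drop = FALSE]
}

filter_selection <- function(atoms, selection) {
  out <- switch(selection,
    CA = atoms[atoms$name == "CA", , drop = FALSE],
    backbone = atoms[atoms$name %in% c("N", "CA", "C", "O"), , drop = FALSE],
    all = atoms[!atoms$element %in% c("H", "D"), , drop = FALSE])
  if (nrow(out) == 0L) stop("selection '", selection, "' matches no atoms")
  out
}

# global NW alignment of one-letter sequences -> residue-number map
align_residues <- function(ra, ma) {
  ref_res <- unique(ra[, c("resno", "resid")])
  mov_res <- unique(ma[, c("resno", "resid")])
  seq_of <- function(res) paste(bio3d::aa321(res$resid), collapse = "")
  al <- Biostrings::pairwiseAlignment(seq_of(ref_res), seq_of(mov_res),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  rpos <- as.character(Biostrings::alignedPattern(al))
  mpos <- as.character(Biostrings::alignedSubject(al))
  rc <- strsplit(rpos, "")[[1]]
  mc <- strsplit(mpos, "")[[1]]
  ri <- cumsum(rc != "-")
  mi <- cumsum(mc != "-")
  keep <- rc != "-" & mc != "-"
  data.frame(ref_resno = ref_res$resno[ri[keep]],
             mov_resno = mov_res$resno[mi[keep]])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between paired coordinate sets. Reflections are always
#' rejected: protein structure is chiral, so a mirror image must score as a
#' genuine mismatch, not be silently inverted.
#'
#' @param ref_coords,mov_coords equal-length N x 3 matrices, N >= 3, not
#'   collinear.
#' @param weights optional non-negative weights, length N.
#' @return An object of class `superposition_result`: list with
#'   `transform` (the [rigid_transform] taking mov onto ref), `rmsd`
#'   (Angstrom, after transformation), `n_pairs`.
#' @export
kabsch <- function(ref_coords, mov_coords, weights = NULL) {
  X <- as.matrix(mov_coords); Y <- as.matrix(ref_coords)
  if (!all(dim(X) == dim(Y))) stop("coordinate sets differ in shape")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 atom pairs, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[1] < 1e-9 || sv_x[2] < 1e-8 * sv_x[1])
    stop("degenerate input: points are coincident or collinear, rotation is ill-defined")
  H <- crossprod(Xc * w, Yc)             # 3x3 covariance, mov -> ref
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cy - R %*% cx)
  tf <- rigid_transform(R, tr)
  dev <- apply_transform(tf, X) - Y
  rmsd <- sqrt(sum(w * rowSums(dev^2)))
  structure(list(transform = tf, rmsd = rmsd, n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: rmsd %.4f A over %d pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

#' Superpose one model onto another over a shared region
#'
#' Computes the pairing on `shared_range` only, then applies the resulting
#' transform to every atom of `mov`. `mov` itself is untouched.
#'
#' @param ref,mov [assembly_model]s.
#' @param selection,by,shared_range,ref_chain,mov_chain see [match_atoms].
#' @return list with `model` (transformed copy of `mov`) and `result`
#'   (the [kabsch] `superposition_result`, with the atom pairing attached).
#' @export
superpose_chains <- function(ref, mov, selection = "CA",
                             by = "residue_number", shared_range = NULL,
                             ref_chain = NULL, mov_chain = NULL) {
  m <- match_atoms(ref, mov, selection = selection, by = by,
                   shared_range = shared_range, ref_chain = ref_chain,
                   mov_chain = mov_chain)
  res <- kabsch(m$ref_xyz, m$mov_xyz)
  res$pairing <- m$pairing
  list(model = transform_model(mov, res$transform), result = res)
}

#' Graft full-length monomers onto a truncated ring
#'
#' The workaround for oligomers beyond a predictor's size limit: predict a
#' "short" ring of truncated subunits plus one full-length monomer, then
#' rebuild the full-length ring by superposing the monomer onto each
#' subunit over the residue range they share. Inter-chain clashes between
#' the grafted extensions are counted and reported but never fatal: grafted
#' models are used without energy refinement.
#'
#' @param short_ring [assembly_model], one chain per truncated subunit.
#' @param full_monomer single-chain [assembly_model] covering
#'   `shared_range` plus the truncated parts.
#' @param shared_range residue interval `c(lo, hi)` common to both.
#' @param selection atoms used for the superposition (default "CA").
#' @param by pairing rule, see [match_atoms].
#' @param max_missing largest tolerated fraction of `shared_range` absent
#'   from a subunit, default 0.2.
#' @param clash_cutoff inter-chain heavy-atom distance (Angstrom) counted
#'   as a clash, default 2.4.
#' @return An [assembly_model] of the full-length ring (one chain per
#'   subunit, ids A, B, C, ...), with `$graft` holding `per_chain_rmsd`,
#'   `transforms` and `n_clashes`.
#' @export
graft_full_length <- function(short_ring, full_monomer, shared_range,
                              selection = "CA", by = "residue_number",
                              max_missing = 0.2, clash_cutoff = 2.4) {
  if (length(chain_ids(full_monomer)) != 1L)
    stop("full_monomer must be a single chain")
  want <- expand_range(shared_range)
  mono_res <- residue_numbers(full_monomer, chain_ids(full_monomer))
  if (!all(want %in% mono_res))
    stop("full_monomer does not cover shared_range")
  placed <- list()
  rmsds <- numeric(0)
  tfs <- list()
  for (ch in chain_ids(short_ring)) {
    have <- residue_numbers(short_ring, ch)
    missing_frac <- mean(!want %in% have)
    if (missing_frac > max_missing)
      stop(sprintf("chain %s misses %.0f%% of shared_range (> %.0f%% allowed)",
                   ch, 100 * missing_frac, 100 * max_missing))
    sp <- superpose_chains(ref = short_ring, mov = full_monomer,
                           selection = selection, by = by,
                           shared_range = shared_range, ref_chain = ch)
    placed[[ch]] <- sp$model
    rmsds[ch] <- sp$result$rmsd
    tfs[[ch]] <- sp$result$transform
  }
  out <- merge_models(placed, name = paste0(short_ring$name, "_full"))
  out <- relabel_chains(out)
  ext <- select_atoms_safe(out, residues_not = want)
  out$graft <- list(per_chain_rmsd = rmsds, transforms = tfs,
                    n_clashes = if (is.null(ext)) 0L else
                      count_interchain_clashes(ext, clash_cutoff))
  out
}

# subset to residues NOT in a set; NULL when nothing remains
select_atoms_safe <- function(model, residues_not) {
  keep <- !model$atoms$resno %in% residues_not
  if (!any(keep)) return(NULL)
  out <- model
  out$atoms <- model$atoms[keep, , drop = FALSE]
  out
}

count_interchain_clashes <- function(model, cutoff) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- 0L
  ids <- unique(a$chain)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    pi <- xyz[a$chain == ids[i], , drop = FALSE]
    pj <- xyz[a$chain == ids[j], , drop = FALSE]
    # bounding-box prefilter
    if (any(apply(pi, 2, min) > apply(pj, 2, max) + cutoff) ||
        any(apply(pj, 2, min) > apply(pi, 2, max) + cutoff)) next
    d2 <- outer(rowSums(pi^2), rowSums(pj^2), "+") - 2 * tcrossprod(pi, pj)
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

#' Extend a stacked-ring tube
#'
#' Estimates the screw transform (rise + twist) taking each ring onto the
#' next by superposition over all adjacent ring pairs, then applies it
#' repeatedly to append `n_extra` rings at the chosen end — the same move
#' as adding a fourth tail-tube hexamer to three predicted ones.
#'
#' @param tube [assembly_model] containing at least 2 stacked rings of
#'   identical subunit composition.
#' @param n_extra number of rings to add.
#' @param direction "top" (larger axial coordinate) or "bottom".
#' @param rings optional list of chain-id vectors, one per ring, in
#'   consistent subunit order; inferred by axial clustering of chain
#'   centroids when omitted.
#' @param selection atoms for the superposition, default "CA".
#' @return The extended [assembly_model]; `$stack` holds the generator
#'   `transform`, `rise` (Angstrom), `twist` (degrees) and ring membership.
#' @export
extend_stack <- function(tube, n_extra = 1L, direction = c("top", "bottom"),
                         rings = NULL, selection = "CA") {
  direction <- match.arg(direction)
  if (is.null(rings)) rings <- infer_rings(tube)
  if (length(rings) < 2L) stop("need at least 2 rings, found ", length(rings))
  sizes <- lengths(rings)
  if (length(unique(sizes)) != 1L)
    stop("rings of unequal size: ", paste(sizes, collapse = ", "))
  cent <- chain_centroids(tube)
  ring_cent <- t(vapply(rings, function(ids)
    colMeans(cent[ids, , drop = FALSE]), numeric(3)))
  # ring centroids sit on the tube axis: order along their principal line
  rc <- sweep(ring_cent, 2, colMeans(ring_cent))
  axis0 <- svd(rc)$v[, 1]
  # fix the sign so "top" is reproducible: largest |component| positive
  if (axis0[which.max(abs(axis0))] < 0) axis0 <- -axis0
  ord <- order(ring_cent %*% axis0)
  rings <- rings[ord]
  # generator estimated jointly over all adjacent ring pairs
  refs <- NULL; movs <- NULL
  for (i in seq_len(length(rings) - 1L)) {
    pr <- pair_ring_chains(tube, rings[[i]], rings[[i + 1L]], selection)
    movs <- rbind(movs, pr$a)
    refs <- rbind(refs, pr$b)
  }
  gen <- kabsch(refs, movs)
  scr <- transform_screw(gen$transform)
  out <- tube
  step_tf <- gen$transform
  src_ids <- rings[[length(rings)]]
  if (direction == "bottom") {
    step_tf <- invert_transform(gen$transform)
    src_ids <- rings[[1L]]
  }
  new_rings <- list()
  seed_model <- select_atoms(tube, chains = src_ids)
  for (k in seq_len(n_extra)) {
    seed_model <- transform_model(seed_model, step_tf)
    new_rings[[k]] <- seed_model
  }
  out <- merge_models(c(list(tube), new_rings), name = tube$name)
  added <- setdiff(chain_ids(out), chain_ids(tube))
  out$stack <- list(transform = gen$transform, rise = abs(scr$rise),
                    twist = scr$angle * 180 / pi, generator_rmsd = gen$rmsd,
                    rings = rings, added_chains = added,
                    direction = direction)
  out
}

# pair chains of two rings by best cyclic shift of centroids, then stack
# matched selection coordinates (a = lower ring, b = upper ring)
pair_ring_chains <- function(model, ids_a, ids_b, selection) {
  cent <- chain_centroids(model)
  n <- length(ids_a)
  best <- NULL; best_cost <- Inf
  for (s in 0:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    cost <- sum((cent[ids_a, ] - cent[ids_b[idx], ])^2)
    if (cost < best_cost) { best_cost <- cost; best <- idx }
  }
  A <- NULL; B <- NULL
  for (k in seq_len(n)) {
    m <- match_atoms(select_atoms(model, chains = ids_a[k]),
                     select_atoms(model, chains = ids_b[best[k]]),
                     selection = selection)
    A <- rbind(A, m$ref_xyz)
    B <- rbind(B, m$mov_xyz)
  }
  list(a = A, b = B)
}

# axial clustering of chain centroids into rings (documented heuristic):
# each principal axis of the centroid cloud is tried as the tube axis; the
# one along which the centroids split into >= 2 equal-size, well-separated
# groups wins
infer_rings <- function(model) {
  cent <- chain_centroids(model)
  ids <- rownames(cent)
  cc <- sweep(cent, 2, colMeans(cent))
  cand_axes <- svd(cc)$v
  best <- NULL; best_score <- -Inf; axis <- NULL
  for (k in 1:3) {
    ax <- cand_axes[, k]
    proj <- as.numeric(cent %*% ax)
    ord <- order(proj)
    gaps <- diff(proj[ord])
    if (!length(gaps)) next
    thr <- max(mean(gaps), 1e-6)
    grp <- cumsum(c(1, as.integer(gaps > thr)))
    groups <- split(ord, grp)
    sizes <- lengths(groups)
    if (length(groups) < 2L || length(unique(sizes)) != 1L || sizes[1] < 2L)
      next
    within <- max(vapply(groups, function(g) diff(range(proj[g])), numeric(1)))
    centers <- vapply(groups, function(g) mean(proj[g]), numeric(1))
    sep <- min(diff(sort(centers)))
    score <- sep / max(within, 1e-6)
    if (score > best_score) {
      best_score <- score
      best <- lapply(groups, function(g) ids[g])
      axis <- ax
    }
  }
  if (is.null(best))
    stop("cannot infer ring membership by axial clustering; pass `rings`")
  rings <- best
  names(rings) <- NULL
  # order chains within each ring by azimuth about the axis for consistency
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  lapply(rings, function(g) {
    c0 <- colMeans(cent[g, , drop = FALSE])
    rel <- sweep(cent[g, , drop = FALSE], 2, c0)
    g[order(atan2(rel %*% e2, rel %*% e1))]
  })
}

#' Compose virion sections into one assembly
#'
#' Chains parts together by superposing each next part's shared component
#' onto the copy already placed — e.g. clip/adaptor onto the full portal,
#' then stopper, tail terminator and tail rings down the axis. Chains
#' duplicated by the junction are dropped from the incoming part;
#' provenance of every relabeled chain is recorded.
#'
#' @param parts list; first element `list(model = <assembly_model>)`,
#'   subsequent elements additionally carry
#'   `junction = list(chains = <ids in the incoming part>,
#'   onto = <matching ids in the assembly, default the same>,
#'   range = <residue interval or NULL>)`.
#' @param gate largest junction rmsd (Angstrom) accepted before the
#'   assembly is aborted, default 5.
#' @param selection atoms for junction superposition, default "CA".
#' @return The composed [assembly_model]; `$junctions` lists per-junction
#'   rmsd and dropped/relabeled chains.
#' @export
compose_assembly <- function(parts, gate = 5, selection = "CA") {
  stopifnot(is.list(parts), length(parts) >= 1L)
  assembled <- parts[[1L]]$model
  info <- list()
  if (length(parts) == 1L) { assembled$junctions <- info; return(assembled) }
  for (p in 2L:length(parts)) {
    part <- parts[[p]]
    j <- part$junction
    if (is.null(j) || is.null(j$chains))
      stop("part ", p, " has no junction spec")
    new_ids <- j$chains
    ref_ids <- if (is.null(j$onto)) j$chains else j$onto
    if (length(new_ids) != length(ref_ids))
      stop("junction chain sets differ in length at part ", p)
    refs <- NULL; movs <- NULL
    for (k in seq_along(new_ids)) {
      m <- match_atoms(select_atoms(assembled, chains = ref_ids[k]),
                       select_atoms(part$model, chains = new_ids[k]),
                       selection = selection, shared_range = j$range)
      refs <- rbind(refs, m$ref_xyz)
      movs <- rbind(movs, m$mov_xyz)
    }
    res <- kabsch(refs, movs)
    if (res$rmsd > gate)
      stop(sprintf("junction %d rmsd %.2f A exceeds gate %.2f A: assembly aborted",
                   p - 1L, res$rmsd, gate))
    placed <- transform_model(part$model, res$transform)
    incoming_ids <- setdiff(chain_ids(placed), new_ids)
    if (length(incoming_ids) == 0L) {
      info[[length(info) + 1L]] <- list(part = p, rmsd = res$rmsd,
                                        added = character(0))
      next
    }
    placed <- select_atoms(placed, chains = incoming_ids)
    before <- chain_ids(assembled)
    assembled <- merge_models(assembled, placed, name = assembled$name)
    info[[length(info) + 1L]] <- list(part = p, rmsd = res$rmsd,
                                      added = setdiff(chain_ids(assembled), before))
  }
  assembled$junctions <- info
  assembled
}
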