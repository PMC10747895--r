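#' Van der Waals radii used for surface areas
#'
#' Protein heavy-atom radii (Angstrom): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, SE 1.90, plus H 1.20 for the rare model that keeps hydrogens.
#' Unknown elements are a hard error — a silently defaulted radius would
#' corrupt every buried-area number downstream.
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii.
#' @export
vdw_radii <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
           H = 1.20, D = 1.20)
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  unname(tab[el])
}

# deterministic golden-section spiral on the unit sphere, symmetrized so
# the set is invariant under a two-fold rotation about z (each point is
# paired with its pi-rotated image): a z-aligned C2 dimer then gets exactly
# equal per-chain areas instead of quadrature-jitter asymmetry
sphere_points <- function(n) {
  h <- ceiling(n / 2)
  i <- seq_len(h) - 0.5
  phi <- acos(1 - 2 * i / h)
  theta <- pi * (1 + sqrt(5)) * i
  half <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rbind(half, cbind(-half[, 1], -half[, 2], half[, 3]))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley rolling-probe point method:
#' `n_points` test points on a deterministic golden-section spiral are
#' placed on each atom's solvent sphere (vdW radius + probe) and counted
#' accessible when outside every neighbor's solvent sphere. Deterministic
#' for fixed `n_points`.
#'
#' @param model an [assembly_model].
#' @param probe_radius probe radius in Angstrom, default 1.4 (water).
#' @param n_points test points per atom, default 960.
#' @return An object of class `sasa_result`: `per_atom_area` (Angstrom^2,
#'   parallel to the atom table), `per_residue_area` (data.frame),
#'   `per_chain_total` (named vector), `probe_radius`, `n_points`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  a <- model$atoms
  r <- vdw_radii(a$element) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  npts <- nrow(pts)
  area <- numeric(n)
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + rmax)^2 & d2 > 1e-12)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (!length(nb)) { area[i] <- 4 * pi * r[i]^2; next }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, npts)
    for (j in nb) {
      if (!any(acc)) break
      acc[acc] <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2) >
        r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / npts
  }
  per_res <- stats::aggregate(area, by = list(chain = a$chain, resno = a$resno),
                              FUN = sum)
  names(per_res)[3] <- "area"
  per_chain <- tapply(area, a$chain, sum)
  structure(list(per_atom_area = area,
                 per_residue_area = per_res[order(match(per_res$chain, chain_ids(model)),
                                                  per_res$resno), ],
                 per_chain_total = per_chain[chain_ids(model)],
                 probe_radius = probe_radius, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              length(x$per_atom_area), sum(x$per_atom_area), x$probe_radius,
              x$n_points))
  invisible(x)
}

#' Buried surface area between two chains (or chain groups)
#'
#' BSA is reported per monomer as the SASA that chain loses on complex
#' formation: `SASA(a alone) - SASA(a in the a+b union)` (and analogously
#' for b), clamped at 0 against quadrature jitter. This per-monomer
#' convention is the one phage interface tables use when they relate a
#' monomer's buried area to its own total surface; note that some
#' interface servers halve the two-sided sum instead, differing by a
#' factor of about two.
#'
#' @param model an [assembly_model] containing both chains.
#' @param chain_a,chain_b chain ids (each may be a vector forming a group).
#' @param probe_radius,n_points passed to [sasa].
#' @return named numeric `c(buried_a, buried_b)` in Angstrom^2.
#' @export
buried_area <- function(model, chain_a, chain_b, probe_radius = 1.4,
                        n_points = 960L) {
  if (length(intersect(chain_a, chain_b)))
    stop("chain groups overlap: ", paste(intersect(chain_a, chain_b),
                                         collapse = ", "))
  ma <- select_atoms(model, chains = chain_a)
  mb <- select_atoms(model, chains = chain_b)
  mab <- select_atoms(model, chains = c(chain_a, chain_b))
  sa <- sum(sasa(ma, probe_radius, n_points)$per_atom_area)
  sb <- sum(sasa(mb, probe_radius, n_points)$per_atom_area)
  sab <- sasa(mab, probe_radius, n_points)
  in_a <- mab$atoms$chain %in% chain_a
  buried_a <- max(0, sa - sum(sab$per_atom_area[in_a]))
  buried_b <- max(0, sb - sum(sab$per_atom_area[!in_a]))
  c(buried_a = buried_a, buried_b = buried_b)
}

# chain pairs whose solvent spheres could overlap (bounding-box + distance)
contacting_chain_pairs <- function(model, margin) {
  ids <- chain_ids(model)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  boxes <- lapply(ids, function(ch) {
    p <- xyz[model$atoms$chain == ch, , drop = FALSE]
    rbind(apply(p, 2, min), apply(p, 2, max))
  })
  names(boxes) <- ids
  out <- NULL
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    bi <- boxes[[i]]; bj <- boxes[[j]]
    if (any(bi[1, ] > bj[2, ] + margin) || any(bj[1, ] > bi[2, ] + margin))
      next
    pi <- xyz[model$atoms$chain == ids[i], , drop = FALSE]
    pj <- xyz[model$atoms$chain == ids[j], , drop = FALSE]
    d2 <- outer(rowSums(pi^2), rowSums(pj^2), "+") - 2 * tcrossprod(pi, pj)
    if (min(d2) < margin^2) out <- rbind(out, c(ids[i], ids[j]))
  }
  out
}

#' Interface report over all chain pairs
#'
#' The PISA-style interface table: every chain pair with positive buried
#' area, each chain's total (isolated) surface area, its summed buried
#' area, and the buried percentage. With `group_map`, chains are rolled up
#' into components (all adaptor chains vs all stopper chains, etc.) and
#' the pair list reports component pairs.
#'
#' @param model an [assembly_model] with >= 2 chains.
#' @param group_map optional named character vector chain id -> component
#'   label.
#' @param probe_radius,n_points passed to [sasa].
#' @return An object of class `interface_report`: `pairs` (data.frame
#'   chain_a, chain_b, buried_a, buried_b), `per_chain` (data.frame chain,
#'   total_area, buried_total, percent_buried).
#' @export
interface_report <- function(model, group_map = NULL, probe_radius = 1.4,
                             n_points = 960L) {
  ids <- chain_ids(model)
  if (length(ids) < 2L) stop("interface report needs at least 2 chains")
  work <- model
  if (!is.null(group_map)) {
    miss <- setdiff(ids, names(group_map))
    if (length(miss)) stop("group_map misses chain(s): ",
                           paste(miss, collapse = ", "))
    # roll chains up into one pseudo-chain per component
    work$atoms$chain <- unname(group_map[work$atoms$chain])
    key <- paste(work$atoms$chain, work$atoms$resno, work$atoms$ins,
                 work$atoms$name, sep = "\r")
    if (anyDuplicated(key)) {
      # disambiguate merged residues by offsetting residue numbers per source chain
      src <- model$atoms$chain
      off <- (match(src, ids) - 1L) * (max(model$atoms$resno) + 1000L)
      work$atoms$resno <- work$atoms$resno + off
    }
    work <- assembly_model(work$atoms, name = model$name)
    ids <- chain_ids(work)
  }
  margin <- 2 * (max(vdw_radii(work$atoms$element)) + probe_radius)
  cand <- contacting_chain_pairs(work, margin)
  iso <- lapply(ids, function(ch)
    sum(sasa(select_atoms(work, chains = ch), probe_radius, n_points)$per_atom_area))
  names(iso) <- ids
  pairs <- data.frame(chain_a = character(0), chain_b = character(0),
                      buried_a = numeric(0), buried_b = numeric(0))
  if (!is.null(cand)) {
    for (k in seq_len(nrow(cand))) {
      ba <- buried_area(work, cand[k, 1], cand[k, 2], probe_radius, n_points)
      if (ba[1] > 0 || ba[2] > 0)
        pairs <- rbind(pairs, data.frame(chain_a = cand[k, 1],
                                         chain_b = cand[k, 2],
                                         buried_a = unname(ba[1]),
                                         buried_b = unname(ba[2])))
    }
  }
  per_chain <- data.frame(chain = ids,
                          total_area = unlist(iso),
                          buried_total = vapply(ids, function(ch)
                            sum(pairs$buried_a[pairs$chain_a == ch]) +
                            sum(pairs$buried_b[pairs$chain_b == ch]),
                            numeric(1)),
                          stringsAsFactors = FALSE)
  per_chain$percent_buried <- 100 * per_chain$buried_total / per_chain$total_area
  rownames(per_chain) <- NULL
  structure(list(pairs = pairs, per_chain = per_chain,
                 probe_radius = probe_radius, n_points = as.integer(n_points),
                 grouped = !is.null(group_map)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %d contacting pair(s)\n", nrow(x$pairs)))
  if (nrow(x$pairs)) print(within(x$pairs, {
    buried_a <- round(buried_a, 1); buried_b <- round(buried_b, 1)
  }))
  print(within(x$per_chain, {
    total_area <- round(total_area, 1)
    buried_total <- round(buried_total, 1)
    percent_buried <- round(percent_buried, 1)
  }))
  invisible(x)
}

#' Write an interface report as TSV
#' @param report an [interface_report].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_interface_report <- function(report, path) {
  df <- merge(report$pairs, report$per_chain, by.x = "chain_a", by.y = "chain")
  df <- df[, c("chain_a", "chain_b", "buried_a", "buried_b", "total_area")]
  df$pct_a <- 100 * df$buried_a / df$total_area
  names(df) <- c("chain_a", "chain_b", "bsa_a", "bsa_b", "total_a", "pct_a")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Residue pairs in contact across an interface
#'
#' Heavy-atom minimum-distance contacts between two chains.
#'
#' @param model an [assembly_model].
#' @param chain_a,chain_b chain ids.
#' @param cutoff heavy-atom distance cutoff in Angstrom, default 4.0.
#' @return data.frame with `resno_a`, `resid_a`, `resno_b`, `resid_b`,
#'   `min_dist`.
#' @export
contact_residues <- function(model, chain_a, chain_b, cutoff = 4.0) {
  aa <- filter_selection(single_chain_atoms(model, chain_a), "all")
  ab <- filter_selection(single_chain_atoms(model, chain_b), "all")
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(resno_a = integer(0), resid_a = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      min_dist = numeric(0)))
  df <- data.frame(resno_a = aa$resno[hit[, 1]], resid_a = aa$resid[hit[, 1]],
                   resno_b = ab$resno[hit[, 2]], resid_b = ab$resid[hit[, 2]],
                   d = sqrt(d2[hit]))
  agg <- stats::aggregate(d ~ resno_a + resid_a + resno_b + resid_b, df, min)
  names(agg)[5] <- "min_dist"
  agg[order(agg$resno_a, agg$resno_b), ]
}
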