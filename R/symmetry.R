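#' Fit a cyclic-symmetry axis to a ring
#'
#' Phage rings (portal/adaptor dodecamers, stopper/tail hexamers, tail-tube
#' rings) are cyclic (Cn) oligomers. The axis is seeded from the chain
#' centroids (plane normal by least squares through the centroid
#' mid-point), then refined by Nelder-Mead over direction and in-plane
#' offset, minimizing the mean rmsd between each subunit and its
#' neighbor rotated by 2*pi/order.
#'
#' @param ring [assembly_model] with >= 2 chains of identical residue
#'   composition.
#' @param order symmetry order; defaults to the chain count.
#' @param selection atoms used, default "CA".
#' @param refine run the local refinement (default TRUE).
#' @return An object of class `symmetry_fit`: `order`, `axis_direction`
#'   (unit 3-vector), `axis_point` (Angstrom), `per_subunit_rmsd`,
#'   `mean_rmsd`.
#' @export
fit_cyclic_axis <- function(ring, order = NULL, selection = "CA",
                            refine = TRUE) {
  ids <- chain_ids(ring)
  if (length(ids) < 2L) stop("ring needs at least 2 chains")
  if (is.null(order)) order <- length(ids)
  sub_xyz <- lapply(ids, function(ch)
    as.matrix(filter_selection(ring$atoms[ring$atoms$chain == ch, ],
                               selection)[, c("x", "y", "z")]))
  nlen <- vapply(sub_xyz, nrow, integer(1))
  if (length(unique(nlen)) != 1L)
    stop("chains of unequal length: ", paste(nlen, collapse = ", "))
  cent <- t(vapply(sub_xyz, colMeans, numeric(3)))
  c0 <- colMeans(cent)
  cc <- sweep(cent, 2, c0)
  axis0 <- svd(cc)$v[, 3]                     # plane normal
  ids_ord <- order_by_azimuth(cent, axis0, c0)
  sub_xyz <- sub_xyz[ids_ord]
  score <- function(axis, point, ang) {
    R <- rotation_about_axis(axis, ang)
    per <- vapply(seq_along(sub_xyz), function(k) {
      nxt <- if (k == length(sub_xyz)) 1L else k + 1L
      rot <- sweep(sweep(sub_xyz[[k]], 2, point) %*% t(R), 2, point, "+")
      sqrt(mean(rowSums((rot - sub_xyz[[nxt]])^2)))
    }, numeric(1))
    per
  }
  ang_step <- 2 * pi / order
  # sense of rotation: pick the sign that maps neighbor onto neighbor
  sgn <- if (mean(score(axis0, c0, ang_step)) <=
             mean(score(axis0, c0, -ang_step))) 1 else -1
  axis <- axis0; point <- c0
  if (refine) {
    # parameterize direction by small tilts about two transverse axes and
    # the point by in-plane offsets
    base <- transverse_basis(axis0)
    obj <- function(p) {
      ax <- rotation_about_axis(base$e1, p[1]) %*%
            rotation_about_axis(base$e2, p[2]) %*% axis0
      pt <- c0 + p[3] * base$e1 + p[4] * base$e2
      mean(score(as.numeric(ax), pt, sgn * ang_step))
    }
    op <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
    axis <- as.numeric(rotation_about_axis(base$e1, op$par[1]) %*%
                       rotation_about_axis(base$e2, op$par[2]) %*% axis0)
    point <- c0 + op$par[3] * base$e1 + op$par[4] * base$e2
  }
  axis <- sgn * axis / sqrt(sum(axis^2))      # axis oriented with rotation sense
  per <- score(axis, point, 2 * pi / order)
  structure(list(order = as.integer(order), axis_direction = axis,
                 axis_point = point, per_subunit_rmsd = per,
                 mean_rmsd = mean(per), chain_order = chain_ids(ring)[ids_ord]),
            class = "symmetry_fit")
}

#' @export
print.symmetry_fit <- function(x, ...) {
  cat(sprintf("symmetry_fit: C%d, axis (%.4f, %.4f, %.4f) through (%.2f, %.2f, %.2f), mean rmsd %.4f A\n",
              x$order, x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3], x$axis_point[1], x$axis_point[2],
              x$axis_point[3], x$mean_rmsd))
  invisible(x)
}

transverse_basis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

order_by_azimuth <- function(cent, axis, c0) {
  b <- transverse_basis(axis)
  rel <- sweep(cent, 2, c0)
  ang <- atan2(rel %*% b$e2, rel %*% b$e1)
  order((ang - ang[1]) %% (2 * pi))
}

#' Build an ideal Cn ring from one subunit
#'
#' Places `order` copies of the monomer at rotations k * 2*pi/order about
#' the fitted axis; chain ids run A, B, C, ...
#'
#' @param monomer single-chain [assembly_model].
#' @param fit a [fit_cyclic_axis] result (or a list with `order`,
#'   `axis_direction`, `axis_point`).
#' @return An [assembly_model] of the ideal ring.
#' @export
apply_cyclic <- function(monomer, fit) {
  if (length(chain_ids(monomer)) != 1L) stop("monomer must be a single chain")
  n <- fit$order
  copies <- lapply(seq_len(n) - 1L, function(k) {
    R <- rotation_about_axis(fit$axis_direction, k * 2 * pi / n)
    tf <- rigid_transform(R, fit$axis_point - as.numeric(R %*% fit$axis_point))
    transform_model(monomer, tf)
  })
  out <- merge_models(copies, name = sprintf("C%d_ring", n))
  relabel_chains(out)
}

#' Deviation of a ring from ideal cyclic symmetry
#'
#' Regenerates an ideal ring from subunit 1 under the fit and reports the
#' direct (no refit) rmsd of every subunit to its ideal copy; subunit 1
#' deviates 0 by construction.
#'
#' @param ring [assembly_model].
#' @param fit a [fit_cyclic_axis] result.
#' @param selection atoms used, default "CA".
#' @return list with `per_subunit` (named by chain, in fit order) and
#'   `mean` rmsd (Angstrom).
#' @export
symmetry_deviation <- function(ring, fit, selection = "CA") {
  ids <- fit$chain_order
  if (is.null(ids)) ids <- chain_ids(ring)
  xyz <- lapply(ids, function(ch)
    as.matrix(filter_selection(ring$atoms[ring$atoms$chain == ch, ],
                               selection)[, c("x", "y", "z")]))
  per <- numeric(length(ids))
  names(per) <- ids
  for (k in seq_along(ids)) {
    R <- rotation_about_axis(fit$axis_direction, (k - 1L) * 2 * pi / fit$order)
    ideal <- sweep(sweep(xyz[[1L]], 2, fit$axis_point) %*% t(R), 2,
                   fit$axis_point, "+")
    per[k] <- sqrt(mean(rowSums((xyz[[k]] - ideal)^2)))
  }
  list(per_subunit = per, mean = mean(per))
}
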