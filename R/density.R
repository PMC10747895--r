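atomic_numbers <- function(elements) {
  tab <- c(H = 1, D = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34)
  el <- toupper(elements)
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown))
    stop("no atomic number for element(s): ", paste(unknown, collapse = ", "))
  unname(tab[el])
}

#' Simulate a density map from an atomic model
#'
#' Each heavy atom contributes an isotropic 3-D Gaussian of amplitude
#' proportional to its atomic number, with sigma = `sigma_factor` x
#' resolution (0.225 by default, the common molmap-style convention for
#' low-resolution EM). The grid extends `pad = 3 sigma` beyond the model on
#' every side; Gaussians are evaluated out to 4 sigma. Intended to emulate
#' negative-stain reconstructions in the 15-25 Angstrom range as fitting
#' targets.
#'
#' @param model an [assembly_model].
#' @param resolution nominal resolution in Angstrom; must be at least
#'   2 x voxel_size (Nyquist).
#' @param voxel_size voxel edge in Angstrom (cubic voxels).
#' @param sigma_factor Gaussian width per resolution unit, default 0.225.
#' @param grid_like optional [density_map]: simulate on that exact grid
#'   instead of a model-fitted one.
#' @return A [density_map] with `resolution` attached.
#' @export
simulate_map <- function(model, resolution, voxel_size,
                         sigma_factor = 0.225, grid_like = NULL) {
  if (resolution < 2 * voxel_size)
    stop(sprintf("Nyquist violation: resolution %.2f A < 2 x voxel %.2f A",
                 resolution, voxel_size))
  sigma <- sigma_factor * resolution
  xyz <- coords(model)
  z <- atomic_numbers(model$atoms$element)
  if (is.null(grid_like)) {
    pad <- 3 * sigma
    lo <- apply(xyz, 2, min) - pad
    hi <- apply(xyz, 2, max) + pad
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
    origin <- lo
    voxel <- rep(voxel_size, 3)
  } else {
    dims <- dim(grid_like$grid)
    origin <- grid_like$origin
    voxel <- grid_like$voxel_size
  }
  grid <- array(0, dims)
  cut <- 4 * sigma
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * voxel[k])
  inv2s2 <- 1 / (2 * sigma^2)
  for (i in seq_len(nrow(xyz))) {
    p <- xyz[i, ]
    ir <- lapply(1:3, function(k) {
      which(ax[[k]] >= p[k] - cut & ax[[k]] <= p[k] + cut)
    })
    if (any(lengths(ir) == 0L)) next
    gx <- exp(-(ax[[1]][ir[[1]]] - p[1])^2 * inv2s2)
    gy <- exp(-(ax[[2]][ir[[2]]] - p[2])^2 * inv2s2)
    gz <- exp(-(ax[[3]][ir[[3]]] - p[3])^2 * inv2s2)
    blk <- (z[i] * gx) %o% gy %o% gz
    grid[ir[[1]], ir[[2]], ir[[3]]] <-
      grid[ir[[1]], ir[[2]], ir[[3]]] + blk
  }
  density_map(grid, voxel, origin, resolution = resolution)
}

#' Cross-correlation between two density maps
#'
#' Pearson correlation about the mean, computed after resampling `map_b`
#' onto `map_a`'s grid (trilinear). With the default footprint mask only
#' voxels where the second (simulated/model) map exceeds 1% of its maximum
#' enter the correlation — low-resolution EM maps are mostly empty box, and
#' a global CC rewards agreeing on emptiness. The global variant uses every
#' voxel.
#'
#' @param map_a reference map (e.g. experimental).
#' @param map_b comparison map (e.g. simulated from a model).
#' @param mask "footprint" or "global".
#' @return Correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(map_a, map_b, mask = c("footprint", "global")) {
  mask <- match.arg(mask)
  b <- resample_map(map_b, map_a)
  va <- as.numeric(map_a$grid)
  vb <- as.numeric(b$grid)
  if (mask == "footprint") {
    keep <- vb > 0.01 * max(vb)
    if (sum(keep) < 2L) stop("footprint mask is empty: maps do not overlap")
    va <- va[keep]; vb <- vb[keep]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant map values under the mask: correlation undefined")
  stats::cor(va, vb)
}

#' Mirror a map along one axis (hand flip)
#'
#' Reverses the grid along the axis so that physical coordinates mirror
#' about the map's center plane — the standard fix when a low-resolution
#' reconstruction has the wrong hand.
#'
#' @param map a [density_map].
#' @param axis "x", "y" or "z".
#' @return The flipped [density_map].
#' @export
flip_map <- function(map, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  d <- dim(map$grid)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[k]] <- rev(idx[[k]])
  out <- map
  out$grid <- map$grid[idx[[1]], idx[[2]], idx[[3]]]
  out
}

#' Fit an atomic model into a density map
#'
#' Local rigid-body optimization of the footprint cross-correlation between
#' the experimental map and a map simulated from the model, starting from
#' `initial` (identity = the model as placed). Gradient-free coordinate
#' cycling over the 6 rigid parameters (rotations about the model centroid)
#' with shrinking steps: start 2 Angstrom / 5 degrees, floor 0.05 Angstrom /
#' 0.1 degree. No global search: models are assumed roughly pre-placed, as
#' in interactive fitting. With `try_flip` the whole optimization is
#' repeated against the z-flipped map and the better CC wins.
#'
#' During optimization the simulated density is interpolated from a single
#' precomputed model map (cheap); the reported CCs are recomputed exactly
#' on the experimental grid at the final transform. The returned CC is
#' never below the CC of the initial placement.
#'
#' @param model an [assembly_model].
#' @param map target [density_map].
#' @param resolution simulation resolution in Angstrom (defaults to the
#'   map's stated resolution).
#' @param initial optional starting [rigid_transform].
#' @param try_flip also search the z-flipped map, default FALSE.
#' @param sigma_factor passed to [simulate_map].
#' @param step_trans,step_rot initial steps (Angstrom, degrees).
#' @param min_trans,min_rot step floors.
#' @return An object of class `fit_result`: `transform`, `cc` (footprint),
#'   `cc_global`, `cc_initial`, `flipped`, `flip_axis`, `n_voxels_scored`,
#'   `model` (the fitted, transformed model).
#' @export
fit_in_map <- function(model, map, resolution = NULL, initial = NULL,
                       try_flip = FALSE, sigma_factor = 0.225,
                       step_trans = 2, step_rot = 5,
                       min_trans = 0.05, min_rot = 0.1) {
  if (is.null(resolution)) resolution <- map$resolution
  if (!is.finite(resolution))
    stop("no resolution: pass `resolution` or attach it to the map")
  if (is.null(initial)) initial <- identity_transform()
  fits <- list(run_map_fit(model, map, resolution, initial, sigma_factor,
                           step_trans, step_rot, min_trans, min_rot))
  fits[[1]]$flipped <- FALSE
  if (try_flip) {
    f <- run_map_fit(model, flip_map(map, "z"), resolution, initial,
                     sigma_factor, step_trans, step_rot, min_trans, min_rot)
    f$flipped <- TRUE
    f$flip_axis <- "z"
    fits[[2]] <- f
  }
  best <- fits[[which.max(vapply(fits, function(f) f$cc, numeric(1)))]]
  class(best) <- "fit_result"
  best
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: CC %.4f (footprint), %.4f (global)%s, %d voxels scored\n",
              x$cc, x$cc_global,
              if (x$flipped) sprintf(", map flipped about %s", x$flip_axis) else "",
              x$n_voxels_scored))
  invisible(x)
}

run_map_fit <- function(model, map, resolution, initial, sigma_factor,
                        step_trans, step_rot, min_trans, min_rot) {
  voxel <- min(map$voxel_size)
  sim <- simulate_map(model, resolution, voxel, sigma_factor)
  sigma <- sigma_factor * resolution
  centroid <- colMeans(coords(model))
  grid_xyz <- map_voxel_coords(map)
  exp_vals_all <- as.numeric(map$grid)
  score <- function(tf) {
    inv <- invert_transform(tf)
    # restrict to voxels near the transformed model
    pmodel <- apply_transform(tf, coords(model))
    lo <- apply(pmodel, 2, min) - 3 * sigma
    hi <- apply(pmodel, 2, max) + 3 * sigma
    keep <- grid_xyz[, 1] >= lo[1] & grid_xyz[, 1] <= hi[1] &
            grid_xyz[, 2] >= lo[2] & grid_xyz[, 2] <= hi[2] &
            grid_xyz[, 3] >= lo[3] & grid_xyz[, 3] <= hi[3]
    if (sum(keep) < 10L) return(-Inf)
    sim_vals <- map_interpolate(sim, apply_transform(inv, grid_xyz[keep, , drop = FALSE]))
    m <- sim_vals > 0.01 * max(sim$grid)
    if (sum(m) < 10L) return(-Inf)
    ev <- exp_vals_all[keep][m]
    sv <- sim_vals[m]
    if (stats::sd(ev) == 0 || stats::sd(sv) == 0) return(-Inf)
    stats::cor(ev, sv)
  }
  if (!is.finite(score(initial)))
    stop("model does not overlap the map at the initial placement: ",
         "supply `initial` to pre-place it")
  cur <- initial
  cur_cc <- score(cur)
  st <- step_trans
  sr <- step_rot * pi / 180
  min_sr <- min_rot * pi / 180
  axes <- diag(3)
  while (st >= min_trans || sr >= min_sr) {
    improved <- FALSE
    for (k in 1:3) for (s in c(1, -1)) {
      if (st >= min_trans) {
        cand <- rigid_transform(cur$rotation, cur$translation + s * st * axes[, k])
        cc <- score(cand)
        if (cc > cur_cc) { cur <- cand; cur_cc <- cc; improved <- TRUE }
      }
      if (sr >= min_sr) {
        R <- rotation_about_axis(axes[, k], s * sr)
        # rotate about the current model centroid
        c_now <- apply_transform(cur, centroid)
        cand <- compose_transforms(
          rigid_transform(R, c_now - as.numeric(R %*% c_now)), cur)
        cc <- score(cand)
        if (cc > cur_cc) { cur <- cand; cur_cc <- cc; improved <- TRUE }
      }
    }
    if (!improved) { st <- st / 2; sr <- sr / 2 }
  }
  # exact rescoring on the experimental grid; never report below the start
  exact <- function(tf) {
    sim_exact <- simulate_map(transform_model(model, tf), resolution,
                              min(map$voxel_size), sigma_factor,
                              grid_like = map)
    c(foot = cross_correlation(map, sim_exact, "footprint"),
      glob = cross_correlation(map, sim_exact, "global"))
  }
  cc_init <- exact(initial)
  cc_fin <- exact(cur)
  if (cc_fin["foot"] < cc_init["foot"]) { cur <- initial; cc_fin <- cc_init }
  n_scored <- sum(map_interpolate(sim, apply_transform(invert_transform(cur),
                                                       grid_xyz)) >
                  0.01 * max(sim$grid))
  list(transform = cur, cc = unname(cc_fin["foot"]),
       cc_global = unname(cc_fin["glob"]), cc_initial = unname(cc_init["foot"]),
       flipped = FALSE, flip_axis = NA_character_,
       n_voxels_scored = n_scored, model = transform_model(model, cur))
}
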