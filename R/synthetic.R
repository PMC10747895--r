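#' Idealized poly-alanine multi-helix monomer
#'
#' Deterministic compact test monomer: alpha-helical segments (rise 1.5
#' Angstrom per residue, helix radius 2.3 Angstrom, 100 degrees per
#' residue) packed as an antiparallel bundle, with N, CA, C, O and CB
#' atoms per residue. No physical realism beyond rigid-body and
#' surface-area behavior is intended — or needed — for pipeline fixtures.
#'
#' @param n_residues residue count.
#' @param helix_length residues per helix segment, default 20.
#' @param chain_id chain id, default "A".
#' @return A single-chain [assembly_model] centered at the origin.
#' @export
build_helical_monomer <- function(n_residues, helix_length = 20L,
                                  chain_id = "A") {
  stopifnot(n_residues >= 3L)
  n_hel <- max(1L, ceiling(n_residues / helix_length))
  rows <- vector("list", n_residues)
  for (res in seq_len(n_residues)) {
    h <- (res - 1L) %/% helix_length          # helix index, 0-based
    t0 <- (res - 1L) %% helix_length          # position within helix
    up <- h %% 2L == 0L
    len <- min(helix_length, n_residues - h * helix_length)
    cx <- h * 6.0
    curve <- function(t, radius = 2.3) {
      ang <- t * 100 * pi / 180
      zz <- if (up) 1.5 * t else 1.5 * (len - 1 - t)
      c(cx + radius * cos(ang), radius * sin(ang), zz)
    }
    ca <- curve(t0)
    at <- rbind(
      data.frame(name = "N",  element = "N", p = I(list(curve(t0 - 0.35)))),
      data.frame(name = "CA", element = "C", p = I(list(ca))),
      data.frame(name = "C",  element = "C", p = I(list(curve(t0 + 0.35)))),
      data.frame(name = "O",  element = "O", p = I(list(curve(t0 + 0.45, 3.5)))),
      data.frame(name = "CB", element = "C", p = I(list(curve(t0, 3.83)))))
    xyz <- do.call(rbind, at$p)
    rows[[res]] <- data.frame(name = at$name, element = at$element,
                              resno = res, resid = "ALA", chain = chain_id,
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              occ = 1, b = 90, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  ctr <- colMeans(atoms[, c("x", "y", "z")])
  atoms$x <- atoms$x - ctr[1]; atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  assembly_model(atoms, name = sprintf("helix_monomer_%d", n_residues))
}

#' Ground-truth Cn ring / stacked-tube fixture
#'
#' Builds a cyclic ring (or a tube of stacked rings) of helical monomers
#' with exactly known axis, order, per-chain transforms and screw
#' parameters, then optionally perturbs it with seeded Gaussian coordinate
#' noise. `noise_sd` is the RMS 3-D displacement per atom (each coordinate
#' drawn with sd `noise_sd / sqrt(3)`), so an injected 0.3 Angstrom
#' translates directly into ~0.3 Angstrom recovered rmsd.
#'
#' @param order subunits per ring.
#' @param radius ring radius (Angstrom); default places adjacent monomer
#'   centroids 10.5 Angstrom apart so that neighbors are in contact.
#' @param monomer_n_residues residues per monomer, default 60.
#' @param noise_sd per-atom RMS displacement (Angstrom), default 0.
#' @param seed RNG seed for the noise.
#' @param n_rings stacked ring count, default 1.
#' @param rise axial rise between rings (Angstrom), default 40.
#' @param twist azimuthal twist between rings (degrees), default 0.
#' @return list with `model` (the noisy fixture), `truth`: list holding
#'   `axis`, `axis_point`, `order`, `n_rings`, `rise`, `twist`,
#'   `per_chain_transforms`, `model_noiseless`, `monomer` (noiseless
#'   placed chain 1), `spec` (the arguments) and `seed`.
#' @export
make_ring_fixture <- function(order, radius = NULL, monomer_n_residues = 60L,
                              noise_sd = 0, seed = 1L, n_rings = 1L,
                              rise = 40, twist = 0) {
  stopifnot(order >= 1L, n_rings >= 1L, noise_sd >= 0)
  if (is.null(radius))
    radius <- if (order == 1L) 0 else 10.5 / (2 * sin(pi / order))
  mono <- build_helical_monomer(monomer_n_residues)
  mono <- transform_model(mono, rigid_transform(diag(3), c(radius, 0, 0)))
  ids <- chain_id_pool()
  tfs <- list()
  parts <- list()
  idx <- 0L
  for (j in seq_len(n_rings) - 1L) {
    Sj <- rigid_transform(rotation_about_axis(c(0, 0, 1), j * twist * pi / 180),
                          c(0, 0, j * rise))
    for (k in seq_len(order) - 1L) {
      idx <- idx + 1L
      Rk <- rigid_transform(rotation_about_axis(c(0, 0, 1), k * 2 * pi / order),
                            c(0, 0, 0))
      tf <- compose_transforms(Sj, Rk)
      ch <- transform_model(mono, tf)
      ch$atoms$chain <- ids[idx]
      parts[[idx]] <- ch
      tfs[[ids[idx]]] <- tf
    }
  }
  clean <- merge_models(parts, name = sprintf("C%d_fixture", order))
  noisy <- clean
  if (noise_sd > 0) {
    set.seed(seed)
    xyz <- coords(clean)
    noisy <- set_coords(clean, xyz + matrix(
      stats::rnorm(length(xyz), sd = noise_sd / sqrt(3)), ncol = 3))
  }
  list(model = noisy,
       truth = list(axis = c(0, 0, 1), axis_point = c(0, 0, 0),
                    order = as.integer(order), n_rings = as.integer(n_rings),
                    rise = rise, twist = twist,
                    per_chain_transforms = tfs,
                    model_noiseless = clean,
                    monomer = select_atoms(clean, chains = ids[1]),
                    spec = list(order = order, radius = radius,
                                monomer_n_residues = monomer_n_residues,
                                noise_sd = noise_sd, n_rings = n_rings,
                                rise = rise, twist = twist),
                    seed = seed))
}

#' Truncated-ring / full-length-monomer pair
#'
#' Emulates the predictor size-limit workaround inputs: a "short" ring with
#' residues outside `keep_range` deleted from every chain, plus the
#' noiseless full-length monomer (chain 1 of the truth), sharing
#' `keep_range` exactly. [graft_full_length] on this pair must reconstruct
#' the truth ring to within the fixture's noise.
#'
#' @param fixture a [make_ring_fixture] result.
#' @param keep_range residue interval `c(lo, hi)` to keep in the ring.
#' @return list with `short_ring`, `full_monomer`, `shared_range`.
#' @export
make_truncated_pair <- function(fixture, keep_range) {
  keep <- expand_range(keep_range)
  short <- select_atoms(fixture$model, residues = keep_range)
  list(short_ring = short,
       full_monomer = fixture$truth$monomer,
       shared_range = c(min(keep), max(keep)))
}

#' Designed confidence (pLDDT + PAE) fixture
#'
#' Writes a designed per-residue confidence profile into a model's B-factor
#' column — "folded" segments drawn around `high_mean`, "disordered"
#' segments around `low_mean` (seeded normals, sd `b_sd`, truncated to
#' [0, 100], constant within a residue) — and builds a matching PAE matrix
#' with controllable intra- and inter-chain block magnitudes.
#'
#' @param model an [assembly_model].
#' @param low_ranges list of residue intervals (applied in every chain) to
#'   set low; everything else is high unless `high_ranges` is given.
#' @param high_ranges optional explicit high intervals.
#' @param high_mean,low_mean segment means, defaults 90 / 40.
#' @param b_sd per-residue jitter sd, default 3.
#' @param pae_intra,pae_inter intra-/inter-chain PAE block levels
#'   (Angstrom), defaults 3 / 25.
#' @param seed RNG seed.
#' @return list with `model` (b_iso set), `pae` (a [pae_matrix]) and
#'   `truth` (the design).
#' @export
make_confidence_fixture <- function(model, low_ranges = list(),
                                    high_ranges = NULL, high_mean = 90,
                                    low_mean = 40, b_sd = 3, pae_intra = 3,
                                    pae_inter = 25, seed = 1L) {
  set.seed(seed)
  a <- model$atoms
  low_set <- if (length(low_ranges))
    sort(unique(unlist(lapply(low_ranges, expand_range)))) else integer(0)
  high_set <- if (!is.null(high_ranges))
    sort(unique(unlist(lapply(high_ranges, expand_range)))) else NULL
  for (ch in chain_ids(model)) {
    resn <- sort(unique(a$resno[a$chain == ch]))
    for (r in resn) {
      mu <- if (r %in% low_set) low_mean
            else if (is.null(high_set) || r %in% high_set) high_mean
            else low_mean
      b <- min(100, max(0, stats::rnorm(1, mu, b_sd)))
      a$b[a$chain == ch & a$resno == r] <- b
    }
  }
  out <- model
  out$atoms <- a
  ranges <- model_chain_ranges(out)
  n <- max(vapply(ranges, `[`, integer(1), 2))
  vals <- matrix(0, n, n)
  for (ci in names(ranges)) for (cj in names(ranges)) {
    ii <- seq.int(ranges[[ci]][1], ranges[[ci]][2])
    jj <- seq.int(ranges[[cj]][1], ranges[[cj]][2])
    level <- if (ci == cj) pae_intra else pae_inter
    vals[ii, jj] <- pmax(0, level + stats::rnorm(length(ii) * length(jj),
                                                 0, 0.5))
  }
  diag(vals) <- 0.2
  list(model = out, pae = pae_matrix(vals, chain_ranges = ranges),
       truth = list(low_ranges = low_ranges, high_ranges = high_ranges,
                    high_mean = high_mean, low_mean = low_mean,
                    pae_intra = pae_intra, pae_inter = pae_inter,
                    seed = seed))
}

#' Simulated density-map fixture
#'
#' A stand-in for a low-resolution EM reconstruction: the model's simulated
#' map, optionally hand-flipped about z and/or degraded with seeded voxel
#' noise at a stated signal-to-noise ratio (signal = sd of the footprint
#' density).
#'
#' @param model an [assembly_model].
#' @param resolution simulation resolution (Angstrom), default 20.
#' @param voxel voxel size (Angstrom), default resolution / 4.
#' @param flip hand-flip the map about z, default FALSE.
#' @param snr signal-to-noise ratio; Inf (default) adds no noise.
#' @param seed RNG seed for the noise.
#' @return list with `map` (a [density_map]) and `truth` (`flipped`,
#'   `snr`, `seed`, `resolution`).
#' @export
make_map_fixture <- function(model, resolution = 20, voxel = NULL,
                             flip = FALSE, snr = Inf, seed = 1L) {
  if (is.null(voxel)) voxel <- resolution / 4
  map <- simulate_map(model, resolution, voxel)
  if (flip) map <- flip_map(map, "z")
  if (is.finite(snr)) {
    set.seed(seed)
    sig <- stats::sd(map$grid[map$grid > 0.01 * max(map$grid)])
    map$grid <- map$grid + array(stats::rnorm(length(map$grid),
                                              sd = sig / snr),
                                 dim(map$grid))
  }
  list(map = map, truth = list(flipped = flip, snr = snr, seed = seed,
                               resolution = resolution))
}
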