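# shared fixtures and independent oracles, all built in code at test time

# random heavy-atom toy molecule in a compact box
make_toy_molecule <- function(n_atoms = 50L, seed = 42L, box = 8) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE)
  assembly_model(data.frame(
    name = paste0("X", seq_len(n_atoms)), element = els,
    resno = seq_len(n_atoms), resid = "UNK", chain = "A",
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box), occ = 1, b = 90))
}

# independent SASA oracle: latitude/longitude quadrature grid with area
# weights (different point construction and accounting than the
# golden-spiral implementation it checks)
sasa_grid_oracle <- function(model, probe = 1.4, n_theta = 60L,
                             n_phi = 120L) {
  a <- model$atoms
  r <- vdw_radii(a$element) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- cbind(rep(sin(theta), times = n_phi) * cos(rep(phi, each = n_theta)),
                rep(sin(theta), times = n_phi) * sin(rep(phi, each = n_theta)),
                rep(cos(theta), times = n_phi))
  w0 <- rep(sin(theta), times = n_phi) * (pi / n_theta) * (2 * pi / n_phi)
  vapply(seq_len(nrow(xyz)), function(i) {
    p <- sweep(grid * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & d2 > r[j]^2
    }
    r[i]^2 * sum(w0[acc])
  }, numeric(1))
}

# brute-force residue-contact oracle: all-pairs heavy-atom distance scan
contact_bruteforce <- function(model, chain_a, chain_b, cutoff = 4.0) {
  aa <- model$atoms[model$atoms$chain == chain_a &
                    !model$atoms$element %in% c("H", "D"), ]
  ab <- model$atoms[model$atoms$chain == chain_b &
                    !model$atoms$element %in% c("H", "D"), ]
  out <- NULL
  for (ra in unique(aa$resno)) for (rb in unique(ab$resno)) {
    pa <- as.matrix(aa[aa$resno == ra, c("x", "y", "z")])
    pb <- as.matrix(ab[ab$resno == rb, c("x", "y", "z")])
    dmin <- sqrt(min(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                     2 * tcrossprod(pa, pb)))
    if (dmin <= cutoff) out <- rbind(out, c(ra, rb))
  }
  out
}

# tiny hand-written PDB text (1 atom), written to a temp file
write_one_atom_pdb <- function(b = 77.70) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM      1  CA  ALA A   1      11.104  13.207   9.571  1.00%6.2f           C", b),
    "END"), path)
  path
}

# expand a list of residue intervals into a residue set
mask_residues_for_test <- function(mask) {
  if (!length(mask)) return(integer(0))
  sort(unique(unlist(lapply(mask, function(r) seq.int(r[1], r[2])))))
}

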