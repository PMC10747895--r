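test_that("match_atoms pairs identical chains completely and refuses disjoint ones", {
  m <- build_helical_monomer(25)
  p <- match_atoms(m, m, selection = "CA")
  expect_equal(nrow(p$pairing), 25L)
  expect_equal(p$ref_xyz, p$mov_xyz)

  # renumbered copy: residue-number pairing collapses, alignment recovers it
  shifted <- m
  shifted$atoms$resno <- shifted$atoms$resno + 500L
  expect_error(match_atoms(m, shifted, by = "residue_number"),
               "fewer than 3")
  pa <- match_atoms(m, shifted, by = "sequence_alignment")
  expect_equal(nrow(pa$pairing), 25L)
  expect_equal(pa$pairing$mov_resno, pa$pairing$ref_resno + 500L)
})

test_that("kabsch recovers constructed transforms and rejects reflections", {
  m <- build_helical_monomer(20)
  x <- coords(m)
  expect_equal(kabsch(x, x)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch(x, x)$transform$rotation, diag(3), tolerance = 1e-10)

  R90 <- rotation_about_axis(c(0, 0, 1), pi / 2)
  tf <- rigid_transform(R90, c(1, 2, 3))
  res <- kabsch(x, apply_transform(tf, x))
  expect_lt(res$rmsd, 1e-10)
  expect_equal(res$transform$rotation, t(R90), tolerance = 1e-10)

  # chiral 4-point set vs its mirror: only proper rotations allowed
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  M <- P %*% diag(c(1, 1, -1))
  res_m <- kabsch(P, M)
  expect_equal(det(res_m$transform$rotation), 1, tolerance = 1e-10)
  expect_gt(res_m$rmsd, 0.5)
  # brute force over seeded random proper rotations cannot beat it
  set.seed(99)
  best <- Inf
  Mc <- sweep(M, 2, colMeans(M)); Pc <- sweep(P, 2, colMeans(P))
  for (i in 1:4000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- rigid_transform(matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE))$rotation
    best <- min(best, sqrt(mean(rowSums((Mc %*% t(R) - Pc)^2))))
  }
  expect_lte(res_m$rmsd, best + 1e-9)

  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch(line, line), "degenerate")
  expect_error(kabsch(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("kabsch agrees with an independent superposition implementation", {
  set.seed(7)
  m <- build_helical_monomer(30)
  x <- coords(m)
  y <- apply_transform(random_rigid_transform(), x) +
    matrix(rnorm(length(x), sd = 0.2), ncol = 3)
  ours <- kabsch(x, y)
  inds <- seq_len(length(x))
  moved <- bio3d::fit.xyz(fixed = as.vector(t(x)), mobile = as.vector(t(y)),
                          fixed.inds = inds, mobile.inds = inds)
  ref_rmsd <- sqrt(mean(colSums(matrix(moved - as.vector(t(x)), nrow = 3)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("kabsch rmsd is invariant under rigid pre-transformation", {
  m <- build_helical_monomer(24)
  x <- coords(m)
  set.seed(31)
  y <- x + matrix(rnorm(length(x), sd = 0.5), ncol = 3)
  base <- kabsch(x, y)$rmsd
  for (i in 1:5) {
    expect_equal(kabsch(apply_transform(random_rigid_transform(), x), y)$rmsd,
                 base, tolerance = 1e-9)
    expect_equal(kabsch(x, apply_transform(random_rigid_transform(), y))$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("superpose_chains leaves the input untouched and reports fixture noise", {
  fx <- make_ring_fixture(6, monomer_n_residues = 40, noise_sd = 0.3,
                          seed = 21)
  mono <- fx$truth$monomer
  before <- coords(mono)
  sp <- superpose_chains(ref = fx$model, mov = mono, ref_chain = "B",
                         shared_range = c(1, 40))
  expect_identical(coords(mono), before)
  expect_equal(sp$result$rmsd, 0.3, tolerance = 0.12)
  sp0 <- superpose_chains(ref = mono, mov = mono)
  expect_equal(sp0$result$rmsd, 0, tolerance = 1e-10)
  expect_equal(coords(sp0$model), coords(mono), tolerance = 1e-10)
})

test_that("graft inverts truncation exactly on noiseless rings", {
  fx <- make_ring_fixture(12, monomer_n_residues = 60, seed = 5)
  tp <- make_truncated_pair(fx, c(13, 48))
  g <- graft_full_length(tp$short_ring, tp$full_monomer, tp$shared_range)
  expect_length(chain_ids(g), 12L)
  expect_true(all(g$graft$per_chain_rmsd <= 1e-8))
  expect_lt(max(abs(coords(g) - coords(fx$truth$model_noiseless))), 1e-8)
})

test_that("graft on noisy rings recovers the ring to within the injected noise", {
  fx <- make_ring_fixture(12, monomer_n_residues = 60, noise_sd = 0.3,
                          seed = 17)
  tp <- make_truncated_pair(fx, c(13, 48))
  g <- graft_full_length(tp$short_ring, tp$full_monomer, tp$shared_range)
  expect_equal(mean(g$graft$per_chain_rmsd), 0.3, tolerance = 0.1)
  # grafted chains sit within noise of the truth ring
  dev <- sqrt(mean(rowSums((coords(g) -
                            coords(fx$truth$model_noiseless))^2)))
  expect_lt(dev, 0.5)
})

test_that("graft refuses subunits missing too much of the shared range", {
  fx <- make_ring_fixture(4, monomer_n_residues = 40, seed = 6)
  tp <- make_truncated_pair(fx, c(11, 30))
  # delete residues 11-18 from chain C: 40% of the shared range gone
  short <- tp$short_ring
  short$atoms <- short$atoms[!(short$atoms$chain == "C" &
                               short$atoms$resno <= 18), ]
  expect_error(graft_full_length(short, tp$full_monomer, tp$shared_range),
               "chain C")
  # 2-residue shared range: under the 3-pair minimum for CA pairing
  tp2 <- make_truncated_pair(fx, c(20, 21))
  expect_error(graft_full_length(tp2$short_ring, tp2$full_monomer,
                                 tp2$shared_range),
               "fewer than 3")
})

test_that("extend_stack appends rings by the exact screw generator", {
  t2 <- make_ring_fixture(6, monomer_n_residues = 30, n_rings = 2,
                          rise = 40, twist = 0, seed = 2)
  e <- extend_stack(t2$model, n_extra = 1)
  expect_equal(e$stack$rise, 40, tolerance = 1e-8)
  expect_equal(e$stack$twist %% 360, 0, tolerance = 1e-6)
  # third ring sits exactly one rise above the second
  zc <- chain_centroids(e)[e$stack$added_chains, 3]
  z2 <- chain_centroids(t2$model)[c("G", "H", "I", "J", "K", "L"), 3]
  expect_equal(sort(unname(zc)), sort(unname(z2) + 40), tolerance = 1e-8)
  # deleting the added ring returns the input coordinates
  kept <- select_atoms(e, chains = setdiff(chain_ids(e), e$stack$added_chains))
  expect_equal(coords(kept), coords(t2$model), ignore_attr = TRUE)
})

test_that("extend_stack recovers rise and twist from noisy tubes", {
  rises <- numeric(0); twists <- numeric(0)
  for (seed in 1:5) {
    tn <- make_ring_fixture(6, monomer_n_residues = 30, n_rings = 3,
                            rise = 38, twist = 17, noise_sd = 0.2,
                            seed = seed)
    en <- extend_stack(tn$model, n_extra = 1)
    rises <- c(rises, en$stack$rise)
    twists <- c(twists, en$stack$twist)
  }
  expect_equal(mean(rises), 38, tolerance = 0.01)
  expect_equal(mean(twists), 17, tolerance = 0.01)

  t2 <- make_ring_fixture(6, monomer_n_residues = 30, n_rings = 2,
                          rise = 40, seed = 3)
  uneven <- select_atoms(t2$model,
                         chains = setdiff(chain_ids(t2$model), "B"))
  expect_error(extend_stack(uneven, rings = list(c("A", "C", "D", "E", "F"),
                                                 c("G", "H", "I", "J", "K", "L"))),
               "unequal")
})

test_that("compose_assembly chains parts onto shared components", {
  fx <- make_ring_fixture(6, monomer_n_residues = 30, seed = 1)
  ringA <- fx$model
  # self-composition on the full chain set is the identity
  same <- compose_assembly(list(
    list(model = ringA),
    list(model = ringA, junction = list(chains = chain_ids(ringA)))))
  expect_equal(coords(same), coords(ringA), ignore_attr = TRUE)

  # ground truth: second ring at a known pose sharing chain G with part 1
  ringB <- transform_model(ringA, rigid_transform(
    rotation_about_axis(c(0, 0, 1), 0.3), c(0, 0, 25)))
  ringB <- relabel_chains(ringB, c("G", "H", "I", "J", "K", "L"))
  truth <- merge_models(ringA, ringB)
  part1 <- merge_models(ringA, select_atoms(truth, chains = "G"))
  set.seed(8)
  part2 <- transform_model(select_atoms(truth, chains = chain_ids(ringB)),
                           random_rigid_transform())
  cmp <- compose_assembly(list(list(model = part1),
                               list(model = part2,
                                    junction = list(chains = "G"))))
  expect_lt(max(abs(coords(cmp) - coords(truth))), 1e-8)
  expect_lt(cmp$junctions[[1]]$rmsd, 1e-8)

  # junction gate: a grossly incompatible shared component aborts
  broken <- part2
  broken$atoms$x <- broken$atoms$x + rnorm(nrow(broken$atoms), sd = 8)
  expect_error(compose_assembly(list(list(model = part1),
                                     list(model = broken,
                                          junction = list(chains = "G")))),
               "gate")
})

test_that("composition outcome does not depend on junction grouping", {
  fx <- make_ring_fixture(4, monomer_n_residues = 24, seed = 9)
  A <- fx$model
  B <- transform_model(A, rigid_transform(rotation_about_axis(c(1, 0, 0), 0.2),
                                          c(5, 0, 18)))
  B <- relabel_chains(B, c("E", "F", "G", "H"))
  C <- transform_model(B, rigid_transform(rotation_about_axis(c(0, 1, 0), -0.1),
                                          c(0, 4, 18)))
  C <- relabel_chains(C, c("I", "J", "K", "L"))
  truth <- merge_models(A, B, C)
  partAB <- merge_models(A, select_atoms(truth, chains = "E"))
  partB <- select_atoms(truth, chains = chain_ids(B))
  partBC <- merge_models(select_atoms(truth, chains = "H"),
                         select_atoms(truth, chains = chain_ids(C)))
  set.seed(12)
  one <- compose_assembly(list(
    list(model = partAB),
    list(model = transform_model(partB, random_rigid_transform()),
         junction = list(chains = "E")),
    list(model = transform_model(partBC, random_rigid_transform()),
         junction = list(chains = "H"))))
  expect_lt(max(abs(coords(one) - coords(truth))), 1e-8)
})
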