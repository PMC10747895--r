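test_that("an isolated atom reproduces the closed-form sphere area", {
  one <- assembly_model(data.frame(name = "C1", element = "C", resno = 1,
                                   resid = "UNK", chain = "A", x = 0, y = 0,
                                   z = 0, occ = 1, b = 0))
  s <- sasa(one)
  expect_equal(sum(s$per_atom_area), 4 * pi * (1.70 + 1.40)^2,
               tolerance = 0.01)
  # every supported element, against its own closed form
  for (el in c("C", "N", "O", "S", "P", "SE")) {
    m <- one; m$atoms$element <- el
    r <- vdw_radii(el) + 1.4
    expect_equal(sum(sasa(m)$per_atom_area), 4 * pi * r^2, tolerance = 0.01)
  }
})

test_that("atoms beyond solvent contact do not occlude each other", {
  two <- assembly_model(data.frame(name = c("C1", "C2"), element = "C",
                                   resno = 1:2, resid = "UNK",
                                   chain = c("A", "B"),
                                   x = c(0, 10), y = 0, z = 0, occ = 1, b = 0))
  s <- sasa(two)
  iso <- 4 * pi * (1.70 + 1.40)^2
  expect_equal(s$per_atom_area, c(iso, iso), tolerance = 0.01)
})

test_that("Shrake-Rupley areas agree with an independent dense-grid oracle", {
  toy <- make_toy_molecule(50, seed = 42)
  ours <- sasa(toy)$per_atom_area
  oracle <- sasa_grid_oracle(toy)
  scale <- 4 * pi * (vdw_radii(toy$atoms$element) + 1.4)^2
  expect_true(all(abs(ours - oracle) <= 0.02 * scale))
})

test_that("unknown elements are a hard error, not a silent default", {
  m <- assembly_model(data.frame(name = "X", element = "XX", resno = 1,
                                 resid = "UNK", chain = "A", x = 0, y = 0,
                                 z = 0, occ = 1, b = 0))
  expect_error(sasa(m), "XX")
})

test_that("quadrature converges: doubling the point count moves areas < 1%", {
  toy <- make_toy_molecule(30, seed = 8)
  a1 <- sasa(toy, n_points = 960)$per_atom_area
  a2 <- sasa(toy, n_points = 1920)$per_atom_area
  scale <- 4 * pi * (vdw_radii(toy$atoms$element) + 1.4)^2
  expect_true(all(abs(a1 - a2) < 0.01 * scale))
})

test_that("union SASA never exceeds the sum of isolated-chain SASAs", {
  fx <- make_ring_fixture(3, monomer_n_residues = 20, seed = 4)
  total <- sum(sasa(fx$model, n_points = 240)$per_atom_area)
  parts <- sum(vapply(chain_ids(fx$model), function(ch)
    sum(sasa(select_atoms(fx$model, chains = ch),
             n_points = 240)$per_atom_area), numeric(1)))
  expect_lte(total, parts + 1e-6)
})

test_that("buried area vanishes without contact and is symmetric for dimers", {
  far <- assembly_model(data.frame(
    name = c("C1", "C2"), element = "C", resno = c(1, 1), resid = "UNK",
    chain = c("A", "B"), x = c(0, 50), y = 0, z = 0, occ = 1, b = 0))
  expect_equal(unname(buried_area(far, "A", "B")), c(0, 0))

  # C2 homodimer: two copies of a monomer related by a proper two-fold
  mono <- build_helical_monomer(20)
  a <- transform_model(mono, rigid_transform(diag(3), c(5.2, 0, 0)))
  b <- transform_model(a, rigid_transform(
    rotation_about_axis(c(0, 0, 1), pi), c(0, 0, 0)))
  b$atoms$chain <- "B"
  dimer <- merge_models(a, b)
  ba <- buried_area(dimer, "A", "B", n_points = 960)
  expect_gt(ba[1], 0)
  expect_equal(unname(ba[1]), unname(ba[2]), tolerance = 1e-6)
  expect_error(buried_area(dimer, "A", "A"), "overlap")
})

test_that("buried area decreases monotonically to zero as chains separate", {
  mono <- build_helical_monomer(16)
  prev <- Inf
  for (gap in c(0, 2, 4, 8, 40)) {
    a <- transform_model(mono, rigid_transform(diag(3), c(4 + gap / 2, 0, 0)))
    b <- transform_model(mono, rigid_transform(
      rotation_about_axis(c(0, 0, 1), pi), c(-(4 + gap / 2), 0, 0)))
    b$atoms$chain <- "B"
    dimer <- merge_models(a, b)
    cur <- sum(buried_area(dimer, "A", "B", n_points = 480))
    expect_lte(cur, prev + 1e-6)
    prev <- cur
  }
  expect_equal(prev, 0)
})

test_that("interface reports list exactly the touching neighbor pairs of a ring", {
  fx <- make_ring_fixture(3, monomer_n_residues = 30, seed = 4)
  rep3 <- interface_report(fx$model, n_points = 240)
  expect_equal(nrow(rep3$pairs), 3L)
  expect_true(all(rep3$per_chain$buried_total <=
                  rep3$per_chain$total_area))
  expect_equal(rep3$per_chain$percent_buried,
               100 * rep3$per_chain$buried_total / rep3$per_chain$total_area)
  # rotational symmetry up to quadrature jitter across subunits
  expect_lt(max(rep3$per_chain$buried_total) -
            min(rep3$per_chain$buried_total),
            0.02 * mean(rep3$per_chain$buried_total))

  far <- assembly_model(data.frame(
    name = c("C1", "C2"), element = "C", resno = c(1, 1), resid = "UNK",
    chain = c("A", "B"), x = c(0, 99), y = 0, z = 0, occ = 1, b = 0))
  expect_equal(nrow(interface_report(far)$pairs), 0L)
})

test_that("chain groups roll up into component-level interfaces", {
  t2 <- make_ring_fixture(3, monomer_n_residues = 20, n_rings = 2,
                          rise = 14, seed = 6)
  groups <- c(A = "lower", B = "lower", C = "lower",
              D = "upper", E = "upper", F = "upper")
  repg <- interface_report(t2$model, group_map = groups, n_points = 240)
  expect_setequal(repg$per_chain$chain, c("lower", "upper"))
  expect_equal(nrow(repg$pairs), 1L)
  ungrouped <- interface_report(t2$model, n_points = 240)
  # per-component buried totals cannot exceed the summed per-chain ones
  low_pair <- repg$pairs$buried_a[1] + repg$pairs$buried_b[1]
  expect_gt(low_pair, 0)
})

test_that("contact_residues matches a brute-force all-pairs scan", {
  far <- assembly_model(data.frame(
    name = c("C1", "C2"), element = "C", resno = c(1, 1), resid = "UNK",
    chain = c("A", "B"), x = c(0, 99), y = 0, z = 0, occ = 1, b = 0))
  expect_equal(nrow(contact_residues(far, "A", "B")), 0L)

  pair <- assembly_model(data.frame(
    name = c("C1", "C2", "C3"), element = "C", resno = c(1, 2, 1),
    resid = "UNK", chain = c("A", "A", "B"),
    x = c(0, 20, 3.5), y = 0, z = 0, occ = 1, b = 0))
  cr <- contact_residues(pair, "A", "B")
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$resno_a, 1L)
  expect_equal(cr$min_dist, 3.5)

  fx <- make_ring_fixture(2, radius = 5.5, monomer_n_residues = 15, seed = 3)
  ours <- contact_residues(fx$model, "A", "B")
  brute <- contact_bruteforce(fx$model, "A", "B")
  expect_equal(nrow(ours), nrow(brute))
  expect_equal(as.matrix(ours[, c("resno_a", "resno_b")]),
               brute, ignore_attr = TRUE)
})
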