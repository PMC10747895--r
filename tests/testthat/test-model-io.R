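test_that("a minimal one-atom PDB parses with its B-factor preserved", {
  path <- write_one_atom_pdb(b = 77.70)
  m <- read_structure(path)
  expect_length(chain_ids(m), 1L)
  expect_equal(n_residues(m), 1L)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$b, 77.70)
  expect_equal(unname(coords(m)[1, ]), c(11.104, 13.207, 9.571))
})

test_that("structure round-trips are idempotent in both formats", {
  fx <- make_ring_fixture(2, monomer_n_residues = 15, seed = 1)
  for (fmt in c("pdb", "mmcif")) {
    path <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(fx$model, path, format = fmt)
    back <- read_structure(path)
    expect_equal(nrow(back$atoms), nrow(fx$model$atoms))
    expect_equal(coords(back), coords(fx$model), tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(back$atoms$b, round(fx$model$atoms$b, 2))
    # second round trip is exact: format precision already applied
    path2 <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(back, path2, format = fmt)
    back2 <- read_structure(path2)
    expect_identical(back2$atoms[, c("x", "y", "z", "b")],
                     back$atoms[, c("x", "y", "z", "b")])
  }
})

test_that("B-factors are written at 2-decimal PDB precision", {
  m <- build_helical_monomer(3)
  m$atoms$b <- 88.8
  path <- tempfile(fileext = ".pdb")
  write_structure(m, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  expect_true(all(substr(lines, 61, 66) == " 88.80"))
})

test_that("a 12-chain grafted ring survives mmCIF", {
  fx <- make_ring_fixture(12, monomer_n_residues = 12, seed = 2)
  path <- tempfile(fileext = ".cif")
  write_structure(fx$model, path)
  back <- read_structure(path)
  expect_length(chain_ids(back), 12L)
  expect_equal(coords(back), coords(fx$model), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("models beyond the PDB chain-id dialect are refused with advice", {
  fx <- make_ring_fixture(63, radius = 200, monomer_n_residues = 3, seed = 3)
  expect_error(write_structure(fx$model, tempfile(fileext = ".pdb")),
               "mmCIF")
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70 20.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 5.0)
})

test_that("PAE payloads parse in both dialects and invalid ones are refused", {
  p1 <- tempfile(fileext = ".json")
  writeLines('{"predicted_aligned_error": [[0,0,0],[0,0,0],[0,0,0]]}', p1)
  pae <- read_pae(p1)
  expect_equal(dim(pae$values), c(3L, 3L))
  expect_true(all(pae$values == 0))

  p2 <- tempfile(fileext = ".json")
  writeLines("[[1,2],[3,4]]", p2)
  expect_equal(read_pae(p2)$values, matrix(c(1, 3, 2, 4), 2))

  p3 <- tempfile(fileext = ".json")
  writeLines('{"predicted_aligned_error": [[1,-2],[3,4]]}', p3)
  expect_error(read_pae(p3), "non-negative")

  p4 <- tempfile(fileext = ".json")
  writeLines('{"predicted_aligned_error": [[1,2,3],[4,5]]}', p4)
  expect_error(read_pae(p4))
})

test_that("generated PAE fixtures round-trip through JSON", {
  fx <- make_ring_fixture(2, monomer_n_residues = 10, seed = 4)
  cf <- make_confidence_fixture(fx$model, pae_inter = 20, seed = 5)
  path <- tempfile(fileext = ".json")
  write_pae(cf$pae, path)
  back <- read_pae(path, model = fx$model)
  expect_equal(back$values, cf$pae$values, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$chain_ranges, cf$pae$chain_ranges)
})

test_that("MRC maps round-trip with grid statistics intact", {
  m4 <- density_map(array(7, c(4, 4, 4)), voxel_size = 3.5)
  path <- tempfile(fileext = ".mrc")
  write_map(m4, path)
  back <- read_map(path)
  expect_equal(back$grid, m4$grid, tolerance = 1e-6)
  expect_equal(back$voxel_size, c(3.5, 3.5, 3.5), tolerance = 1e-6)

  sim <- simulate_map(build_helical_monomer(10), 18, 4.5)
  path2 <- tempfile(fileext = ".mrc")
  write_map(sim, path2)
  back2 <- read_map(path2)
  expect_lt(max(abs(back2$grid - sim$grid)), 1e-5 * max(sim$grid))
  for (f in c(min, max, mean))
    expect_equal(f(back2$grid), f(sim$grid), tolerance = 1e-5)
  expect_equal(back2$origin, sim$origin, tolerance = 1e-4)
})

test_that("maps with permuted axis order are normalized on read", {
  sim <- simulate_map(build_helical_monomer(8), 18, 4.5)
  path <- tempfile(fileext = ".mrc")
  write_map(sim, path)
  # rewrite the file with swapped MAPC/MAPR words and matching data layout
  raw <- readBin(path, "raw", file.info(path)$size)
  con <- rawConnection(raw, "r+")
  seek(con, 64)  # word 17 (MAPC), 0-based byte 64
  writeBin(c(2L, 1L, 3L), con, size = 4L, endian = "little")
  d <- dim(sim$grid)
  seek(con, 0)
  writeBin(c(d[2], d[1], d[3]), con, size = 4L, endian = "little")
  seek(con, 28)  # MX MY MZ stay in physical X,Y,Z order
  writeBin(d, con, size = 4L, endian = "little")
  seek(con, 1024)
  writeBin(as.numeric(aperm(sim$grid, c(2, 1, 3))), con, size = 4L,
           endian = "little")
  out <- rawConnectionValue(con)
  close(con)
  writeBin(out, path)
  back <- read_map(path)
  expect_equal(back$grid, sim$grid, tolerance = 1e-6)
})

test_that("unsupported MRC modes are refused by name", {
  m4 <- density_map(array(1, c(4, 4, 4)), 2)
  path <- tempfile(fileext = ".mrc")
  write_map(m4, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  con <- rawConnection(raw, "r+")
  seek(con, 12)
  writeBin(99L, con, size = 4L, endian = "little")
  out <- rawConnectionValue(con); close(con)
  writeBin(out, path)
  expect_error(read_map(path), "mode.*99")
})

test_that("empty or absent inputs raise explicit errors", {
  expect_error(read_structure(tempfile()), "not found")
  p <- tempfile(fileext = ".pdb")
  writeLines("END", p)
  expect_error(read_structure(p), "atoms|parse")
  expect_error(assembly_model(data.frame(name = character(0),
                                         element = character(0),
                                         resno = integer(0),
                                         resid = character(0),
                                         chain = character(0),
                                         x = numeric(0), y = numeric(0),
                                         z = numeric(0))),
               "no atoms")
})
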