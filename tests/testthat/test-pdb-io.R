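test_that("a small hand-written PDB reads as a one-model ensemble", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   22.000   24.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  N   ALA A   2       4.500   5.250   6.125  0.80 12.00           N",
    "ATOM      3  O   ALA A   3       7.000   8.000   9.000  1.00 14.00           O",
    "END"), path)
  ens <- read_pdb_multimodel(path)
  expect_equal(n_models(ens), 1)
  expect_equal(nrow(ens), 3)
  expect_equal(ens$x, c(1, 4.5, 7))
  expect_equal(ens$occ, c(1, 0.8, 1))
  expect_equal(ens$element, c("C", "N", "O"))
  expect_equal(get_cell(ens)$b, 22)
})

test_that("read/write round-trips preserve everything up to 3-decimal quantization", {
  bm <- make_two_group_benchmark(toy_spec(n_atoms = 14, seed = 21))
  ens <- generate_ensemble(bm$model, bm$cell, bm$groups, n_models = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(ens, path)
  back <- read_pdb_multimodel(path)
  expect_equal(n_models(back), 4)
  expect_lt(max(abs(back$x - ens$x), abs(back$y - ens$y), abs(back$z - ens$z)), 5.01e-4)
  expect_equal(back$occ, ens$occ)
  expect_equal(back$b, ens$b)
  expect_equal(back$chain, ens$chain)
  # one MODEL/ENDMDL pair per model
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 4)
  expect_equal(sum(grepl("^ENDMDL", lines)), 4)
})

test_that("a 1000-model file reads back with every model intact", {
  model <- make_toy_structure(toy_spec(n_atoms = 2, n_groups = 1, seed = 3))
  atoms <- dplyr::bind_rows(lapply(1:1000, function(m) {
    df <- model
    df$model <- m
    df$x <- df$x + 0.001 * m
    df
  }))
  ens <- as_ensemble(atoms, get_cell(model))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(ens, path)
  expect_equal(n_models(read_pdb_multimodel(path)), 1000)
})

test_that("roster mismatches, missing CRYST1 and unknown elements are hard errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END"), path)
  expect_error(read_pdb_multimodel(path), "CRYST1")

  writeLines(c(
    "CRYST1   20.000   22.000   24.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   2       1.000   2.000   3.000  1.00 10.00           C",
    "ENDMDL"), path)
  expect_error(read_pdb_multimodel(path), "roster mismatch.*A 1 CA")

  writeLines(c(
    "CRYST1   20.000   22.000   24.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  XX  ALA A   1       1.000   2.000   3.000  1.00 10.00          Xx",
    "END"), path)
  expect_error(read_pdb_multimodel(path), "unknown element")
})

test_that("waters, hydrogens and alternate conformers follow the filtering rules", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   22.000   24.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  CA BALA A   2       2.000   2.000   3.000  0.50 10.00           C",
    "ATOM      3  CA AALA A   3       3.000   2.000   3.000  0.50 10.00           C",
    "ATOM      4  H   ALA A   1       1.500   2.000   3.000  1.00 10.00           H",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00 20.00           O",
    "END"), path)
  ens <- read_pdb_multimodel(path)
  expect_equal(nrow(ens), 2)            # altloc B, H and water dropped
  expect_equal(ens$resno, c(1, 3))
  expect_equal(nrow(read_pdb_multimodel(path, keep_waters = TRUE)), 3)
  expect_equal(nrow(read_pdb_multimodel(path, keep_waters = TRUE, keep_hydrogens = TRUE)), 4)
})

test_that("coordinate parsing agrees with bio3d on a single-model file", {
  skip_if_not_installed("bio3d")
  model <- make_toy_structure(toy_spec(n_atoms = 12, seed = 5))
  ens <- as_ensemble(model, get_cell(model))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_multimodel(ens, path)
  ref <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  back <- ens_model(read_pdb_multimodel(path), 1)
  expect_equal(back$x, ref$atom$x, tolerance = 1e-12)
  expect_equal(back$y, ref$atom$y, tolerance = 1e-12)
  expect_equal(back$z, ref$atom$z, tolerance = 1e-12)
  expect_equal(back$occ, ref$atom$o, tolerance = 1e-12)
  expect_equal(back$resno, ref$atom$resno)
})

test_that("TLS parsing: absent blocks, unit conversion, multiple groups", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("CRYST1   20.000   22.000   24.000  90.00  90.00  90.00 P 1           1", path)
  expect_identical(parse_tls_records(path), list())

  # hand-written block with L on the PDB (deg^2) scale
  writeLines(c(
    "REMARK   3   TLS GROUP :     1",
    "REMARK   3    RESIDUE RANGE :   A     1        A     4",
    "REMARK   3    ORIGIN FOR THE GROUP (A):    1.0000    2.0000    3.0000",
    "REMARK   3    T TENSOR",
    "REMARK   3      T11:    0.0100 T22:    0.0200",
    "REMARK   3      T33:    0.0300 T12:    0.0000",
    "REMARK   3      T13:    0.0000 T23:    0.0000",
    "REMARK   3    L TENSOR",
    "REMARK   3      L11:    4.0000 L22:    9.0000",
    "REMARK   3      L33:    1.0000 L12:    0.0000",
    "REMARK   3      L13:    0.0000 L23:    0.0000",
    "REMARK   3    S TENSOR",
    "REMARK   3      S11:    0.0000 S12:    0.1000 S13:    0.0000",
    "REMARK   3      S21:    0.0000 S22:    0.0000 S23:    0.0000",
    "REMARK   3      S31:    0.0000 S32:    0.0000 S33:    0.0000"), path)
  g <- parse_tls_records(path)
  expect_length(g, 1)
  deg2rad <- pi / 180
  expect_equal(diag(g[[1]]$L), c(4, 9, 1) * deg2rad^2, tolerance = 1e-12)
  expect_equal(g[[1]]$S[1, 2], 0.1 * deg2rad, tolerance = 1e-12)
  expect_equal(sum(diag(g[[1]]$S)), 0, tolerance = 1e-15)
  expect_equal(g[[1]]$selection$resno, 1:4)

  # three sub-domain style groups with disjoint selections
  model <- make_toy_structure(toy_spec(n_atoms = 30, n_groups = 3, seed = 6))
  groups <- lapply(1:3, function(i) {
    sel <- dplyr::distinct(model[model$chain == LETTERS[i], c("chain", "resno")])
    make_random_tls(sel, c(5, 5, 5), seed = i)
  })
  write_pdb_multimodel(as_ensemble(model, get_cell(model)), path, tls = groups)
  back <- parse_tls_records(path)
  expect_length(back, 3)
  keys <- lapply(back, function(g) paste(g$selection$chain, g$selection$resno))
  expect_equal(anyDuplicated(unlist(keys)), 0L)
})

test_that("TLS block parsing is invariant to tensor-line order and flags bad lines", {
  base <- c(
    "REMARK   3   TLS GROUP :     1",
    "REMARK   3    RESIDUE RANGE :   A     1        A     2",
    "REMARK   3    ORIGIN FOR THE GROUP (A):    0.0000    0.0000    0.0000",
    "REMARK   3      T11:    0.0100 T22:    0.0200",
    "REMARK   3      T33:    0.0300 T12:    0.0040",
    "REMARK   3      T13:    0.0050 T23:    0.0060",
    "REMARK   3      L11:    4.0000 L22:    9.0000",
    "REMARK   3      L33:    1.0000 L12:    0.5000",
    "REMARK   3      L13:    0.2000 L23:    0.1000",
    "REMARK   3      S11:    0.0100 S12:    0.1000 S13:    0.0200",
    "REMARK   3      S21:    0.0300 S22:   -0.0200 S23:    0.0400",
    "REMARK   3      S31:    0.0500 S32:    0.0600 S33:    0.0100")
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(base, p1)
  set.seed(8)
  writeLines(c(base[1:3], sample(base[4:12])), p2)
  g1 <- parse_tls_records(p1)[[1]]
  g2 <- parse_tls_records(p2)[[1]]
  expect_equal(g1$T, g2$T)
  expect_equal(g1$L, g2$L)
  expect_equal(g1$S, g2$S)

  bad <- base
  bad[5] <- "REMARK   3      T33:     oops T12:    0.0040"
  writeLines(bad, p1)
  expect_error(parse_tls_records(p1), "line 5")
})

test_that("a TLS block with no residue ranges warns but is retained", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "REMARK   3   TLS GROUP :     1",
    "REMARK   3    ORIGIN FOR THE GROUP (A):    0.0000    0.0000    0.0000",
    "REMARK   3      T11:    0.0100 T22:    0.0200",
    "REMARK   3      T33:    0.0300 T12:    0.0000",
    "REMARK   3      T13:    0.0000 T23:    0.0000",
    "REMARK   3      L11:    0.0000 L22:    0.0000",
    "REMARK   3      L33:    0.0000 L12:    0.0000",
    "REMARK   3      L13:    0.0000 L23:    0.0000",
    "REMARK   3      S11:    0.0000 S12:    0.0000 S13:    0.0000",
    "REMARK   3      S21:    0.0000 S22:    0.0000 S23:    0.0000",
    "REMARK   3      S31:    0.0000 S32:    0.0000 S33:    0.0000"), path)
  expect_warning(g <- parse_tls_records(path), "empty selection")
  expect_length(g, 1)
  expect_equal(nrow(g[[1]]$selection), 0)
})
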