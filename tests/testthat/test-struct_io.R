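test_that("XYZ write/read round-trips coordinates exactly", {
  s <- mol_structure(
    data.frame(element = c("C", "N", "O"), name = c("C1", "N1", "O1"),
               resname = "MOL", resid = 1L, chain = "A"),
    rbind(c(0.1, -2.345678, 3), c(1, 1, 1), c(-0.5, 0.25, 9.125)),
    title = "three atoms")
  path <- withr::local_tempfile(fileext = ".xyz")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-7)
  expect_identical(s2$atoms$element, s$atoms$element)
})

test_that("PDB HETATM records map to retrievable named atoms", {
  lines <- c(
    "HETATM    1  N5  FMN A 500       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  C4A FMN A 500      -1.250   0.720   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  idx <- select_atoms(s, "resname FMN and name N5")
  expect_length(idx, 1L)
  expect_equal(s$xyz[idx, ], c(0, 0, 0))
  expect_identical(s$atoms$element[idx], "N")
})

test_that("PDB element inference falls back to the atom-name field", {
  lines <- c(
    "HETATM    1  N5  FMN A 500       0.000   0.000   0.000",
    "HETATM    2  CA  TYR A  65       1.000   0.000   0.000",
    "HETATM    3  OH  TYR A  65       2.000   0.000   0.000",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_structure(path)
  expect_identical(s$atoms$element, c("N", "C", "O"))
})

test_that("malformed PDB coordinates raise an error naming the line", {
  lines <- c(
    "HETATM    1  N5  FMN A 500       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  C1  LIG A   1       xx.xx   0.000   0.000  1.00  0.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_structure(path), "line 2")
})

test_that("our PDB dialect agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  s <- make_pocket_complex()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(matrix(ref$xyz, ncol = 3, byrow = TRUE), s$xyz,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(ref$atom$resid[1], s$atoms$resname[1])
})

test_that("multi-model PDB trajectories keep frame count and order", {
  traj <- make_complex_trajectory(complex_recipe(n_frames = 5L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, path)
  t2 <- read_trajectory(path)
  expect_identical(n_frames(t2), 5L)
  expect_equal(t2$coords, traj$coords, tolerance = 1e-3, ignore_attr = TRUE)
  ## a single-model file degenerates to one frame equal to read_structure
  s <- frame_structure(traj, 1L)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, p1)
  t1 <- read_trajectory(p1)
  expect_identical(n_frames(t1), 1L)
  expect_equal(t1$coords[, , 1], read_structure(p1)$xyz)
})

test_that("inconsistent atom counts across frames name the offending frame", {
  lines <- c("MODEL        1",
             "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
             "HETATM    2  C2  LIG A   1       1.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL",
             "MODEL        2",
             "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
             "ENDMDL", "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_trajectory(path), "frame 2")
})

test_that("selection grammar matches, negates and fails loudly", {
  s <- make_pocket_complex()
  ## unique match
  expect_length(select_atoms(s, "resname FMN and name N5"), 1L)
  ## heavy atoms of the ligand template: 7 C + 3 N + 6 O = 16 (C7H5N3O6)
  heavy <- select_atoms(s, "resname TNT and not element H")
  expect_length(heavy, 16L)
  expect_length(select_atoms(s, "resname TNT"), 21L)
  ## empty match is empty, not an error
  expect_length(select_atoms(s, "resname XYZ"), 0L)
  ## invalid expressions echo the expression
  expect_error(select_atoms(s, "within 3 of resname TNT"), "within 3")
  expect_error(select_atoms(s, "resname"), "resname")
})

test_that("selections are idempotent and element complements partition atoms", {
  s <- make_pocket_complex()
  h <- select_atoms(s, "element H")
  noth <- select_atoms(s, "not element H")
  expect_identical(sort(c(h, noth)), seq_len(nrow(s$atoms)))
  expect_length(intersect(h, noth), 0L)
  ## applying the same predicate twice changes nothing (indices in order)
  expect_identical(h, h[order(h)])
})

test_that("cube files round-trip origin, axes and values", {
  g <- volumetric_grid(c(-1, -1, -1), diag(rep(0.5, 3)), c(2L, 2L, 2L),
                       rep(1, 8))
  s <- h_atom()
  path <- withr::local_tempfile(fileext = ".cube")
  write_grid(g, s, path)
  rt <- read_grid(path)
  expect_equal(rt$grid$values, rep(1, 8))
  expect_equal(rt$grid$origin, g$origin, tolerance = 1e-5)
  expect_equal(rt$grid$axes, g$axes, tolerance = 1e-5)
  ## non-trivial values at format precision
  g2 <- volumetric_grid(c(0, 0, 0), diag(rep(0.3, 3)), c(3L, 2L, 2L),
                        seq(-0.5, 0.6, length.out = 12))
  write_grid(g2, s, path)
  expect_equal(read_grid(path)$grid$values, g2$values, tolerance = 1e-6)
})

test_that("grids reject mismatched value lengths", {
  expect_error(volumetric_grid(c(0, 0, 0), diag(3), c(2L, 2L, 2L), rep(1, 7)),
               "values length")
  g <- volumetric_grid(c(0, 0, 0), diag(3), c(2L, 2L, 2L))
  expect_error(write_grid(g, h_atom(), tempfile()), "no values")
})

test_that("the packaged orbital fixture carries the seven compounds", {
  orb <- nitroaromatic_orbitals()
  expect_identical(nrow(orb), 7L)
  tnt <- orb[orb$compound == "TNT", ]
  expect_equal(c(tnt$eps_homo, tnt$eps_lumo), c(-9.0, -3.5))
  fourad <- orb[orb$compound == "4AD", ]
  expect_equal(c(fourad$eps_homo, fourad$eps_lumo), c(-7.0, -2.6))
  expect_true(all(orb$eps_lumo > orb$eps_homo))
})

test_that("orbital tables with LUMO below HOMO are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,eps_homo,eps_lumo", "BAD,-3.0,-9.0"), path)
  expect_error(read_orbital_table(path), "unphysical")
})
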