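test_that("identical frames give an all-zero RMSD matrix", {
  base <- make_pocket_complex()
  coords <- array(rep(base$xyz, 4), c(nrow(base$xyz), 3, 4))
  traj <- mol_trajectory(base, coords)
  m <- ligand_rmsd_matrix(traj, "resname TNT and not element H",
                          "not resname TNT")
  expect_equal(max(abs(m$values)), 0, tolerance = 1e-10)
})

test_that("a pure ligand translation with fixed protein reads off directly", {
  base <- make_pocket_complex()
  lig <- select_atoms(base, "resname TNT and not element H")
  coords <- array(rep(base$xyz, 2), c(nrow(base$xyz), 3, 2))
  coords[lig, 1, 2] <- coords[lig, 1, 2] + 2.0
  traj <- mol_trajectory(base, coords)
  m <- ligand_rmsd_matrix(traj, lig, select_atoms(base, "not resname TNT"))
  expect_equal(m$values[1, 2], 2.0, tolerance = 1e-9)
  expect_equal(m$values, t(m$values), tolerance = 1e-9)
})

test_that("hydrogens in the ligand selection are rejected", {
  traj <- make_complex_trajectory(complex_recipe(n_frames = 2L, seed = 1L))
  expect_error(
    ligand_rmsd_matrix(traj, "resname TNT", "not resname TNT"),
    "hydrogens")
})

test_that("dbscan finds two well-separated dense groups with no noise", {
  ## 6 + 6 points: within-group < 0.5, between-group > 5
  set.seed(4)
  d <- matrix(6 + runif(144), 12, 12)
  for (g in list(1:6, 7:12)) d[g, g] <- runif(36, 0, 0.5)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  cl <- dbscan_poses(d, eps = 1.5, min_points = 5)
  expect_identical(length(cl$medoid_frames), 2L)
  expect_identical(sum(cl$labels == 0L), 0L)
  expect_identical(unique(cl$labels[1:6]), 1L)
  expect_identical(unique(cl$labels[7:12]), 2L)
})

test_that("too few points for the density threshold are all noise", {
  d <- random_distance_matrix(4)
  cl <- dbscan_poses(d, eps = 1.5, min_points = 5)
  expect_identical(cl$labels, rep(0L, 4))
  expect_length(cl$medoid_frames, 0L)
})

test_that("dbscan defaults match the standard pose-clustering parameters", {
  expect_identical(formals(dbscan_poses)$eps, 1.5)
  expect_identical(formals(dbscan_poses)$min_points, 5L)
  expect_error(dbscan_poses(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dbscan equals the direct-definition oracle on random instances", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  for (i in 1:30) {
    n <- sample(5:120, 1)
    d <- random_distance_matrix(n, scale = sample(2:5, 1))
    eps <- runif(1, 0.5, 2.5)
    mp <- sample(2:6, 1)
    ours <- dbscan_poses(d, eps = eps, min_points = mp)$labels
    ref <- oracle_dbscan(d, eps, mp)
    expect_identical(ours, ref)
  }
})

test_that("cluster labels are invariant to frame order up to relabeling", {
  set.seed(55)
  d <- matrix(8 + runif(400), 20, 20)
  for (g in list(1:7, 8:14)) d[g, g] <- runif(49, 0, 0.8)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  perm <- sample(20)
  l1 <- dbscan_poses(d, eps = 1.5, min_points = 5)$labels
  l2 <- dbscan_poses(d[perm, perm], eps = 1.5, min_points = 5)$labels
  ## same partition: co-membership matrices agree under the permutation
  co1 <- outer(l1, l1, function(a, b) a == b & a != 0)
  co2 <- outer(l2, l2, function(a, b) a == b & a != 0)
  expect_identical(co2, co1[perm, perm])
  expect_identical(l2 == 0L, (l1 == 0L)[perm])
})

test_that("medoids minimize summed distance with deterministic ties", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 1
  d[2, 3] <- d[3, 2] <- 2
  expect_identical(medoid(d, 1:3), 1L)      # sums: 2, 3, 3
  expect_identical(medoid(d, 2L), 2L)       # singleton
  ## perfect symmetry: tie broken by lowest frame id
  dsym <- matrix(1, 2, 2); diag(dsym) <- 0
  expect_identical(medoid(dsym, c(2L, 1L)), 1L)
  expect_error(medoid(d, c(1L, 9L)), "not present")
})

test_that("contact residues respect the cutoff boundary", {
  mk <- function(dist) {
    atoms <- data.frame(element = c("C", "C"), name = c("C1", "CB"),
                        resname = c("LIG", "ALA"), resid = c(1L, 2L),
                        chain = "A")
    mol_structure(atoms, rbind(c(0, 0, 0), c(dist, 0, 0)))
  }
  inside <- contact_residues(mk(2.9), "resname LIG", cutoff = 3.0)
  expect_identical(inside$resname, "ALA")
  outside <- contact_residues(mk(3.1), "resname LIG", cutoff = 3.0)
  expect_identical(nrow(outside), 0L)
  expect_error(contact_residues(mk(2), "resname ZZZ"), "empty")
})

test_that("the synthetic pocket has exactly its three built-in contacts", {
  s <- make_pocket_complex()
  cs <- contact_residues(s, "resname TNT", cutoff = 3.0)
  expect_identical(nrow(cs), 3L)
  expect_identical(cs$resid, c(65L, 129L, 335L))
  expect_identical(cs$resname, c("TYR", "LEU", "TYR"))
  ## the cofactor plane sits 3.3 A below the ligand: outside the 3 A shell
  expect_false("FMN" %in% cs$resname)
})

test_that("planted pose modes are recovered at standard parameters", {
  for (k in 1:3) {
    traj <- make_complex_trajectory(
      complex_recipe(n_frames = 30L * k, pose_modes = separated_pose_modes(k),
                     seed = 100L + k))
    m <- ligand_rmsd_matrix(traj, "resname TNT and not element H",
                            "not resname TNT and not element H")
    cl <- dbscan_poses(m)
    expect_identical(length(cl$medoid_frames), k)
    expect_lte(sum(cl$labels == 0L), 0.05 * n_frames(traj))
    ## medoids land within one within-mode sd of a planted center
    n2 <- select_atoms(traj$topology, "resname TNT and name N2")
    centers <- mode_centers(k)
    for (mf in cl$medoid_frames) {
      p <- traj$coords[n2, , mf]
      dmin <- min(vapply(centers, function(cc) sqrt(sum((p - cc)^2)), 0))
      expect_lt(dmin, 0.4)
    }
  }
})
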