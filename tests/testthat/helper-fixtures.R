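## Shared fixtures and independent oracles for the test suite.

## Single hydrogen proatom at the origin.
h_atom <- function() {
  mol_structure(data.frame(element = "H", name = "H1", resname = "MOL",
                           resid = 1L, chain = "A", stringsAsFactors = FALSE),
                matrix(0, 1, 3))
}

two_atoms <- function(elements = c("H", "H"), sep = 2.0) {
  mol_structure(data.frame(element = elements,
                           name = paste0(elements, 1:2), resname = "MOL",
                           resid = 1L, chain = "A", stringsAsFactors = FALSE),
                rbind(c(-sep / 2, 0, 0), c(sep / 2, 0, 0)))
}

## Asymmetric 4-point cloud (no special symmetry, not coplanar).
toy_points <- function() {
  rbind(c(0, 0, 0), c(1.7, 0.2, -0.1), c(0.4, 1.3, 0.6), c(-0.5, 0.8, 1.9))
}

rotation_xyz <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

## Brute-force minimum RMSD over a rotation-angle grid (independent of the
## SVD path): centers both sets, scans Euler angles at `step` radians.
grid_min_rmsd <- function(P, Q, step = pi / 15) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  angles <- seq(0, 2 * pi - step / 2, by = step)
  half <- seq(0, pi, by = step)
  best <- Inf
  for (a in angles) for (b in half) for (c in angles) {
    R <- rotation_xyz(a, b, c)
    v <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    if (v < best) best <- v
  }
  best
}

## Direct-definition DBSCAN oracle on a distance matrix, using igraph
## connected components over the core-core eps graph. Clusters are numbered
## by the smallest core-point index they contain (the same canonical order
## the package's scan produces), so labelings are directly comparable.
oracle_dbscan <- function(d, eps, min_points) {
  n <- nrow(d)
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_points,
                 TRUE)
  labels <- rep(0L, n)
  if (any(core)) {
    adj <- (d <= eps) & outer(core, core, "&")
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    new_id <- integer(max(comp))
    next_id <- 0L
    for (i in which(core)) {          # number clusters by first core index
      cid <- comp[i]
      if (new_id[cid] == 0L) {
        next_id <- next_id + 1L
        new_id[cid] <- next_id
      }
      labels[i] <- new_id[cid]
    }
    for (i in which(!core)) {
      cn <- which(core & d[i, ] <= eps)
      if (length(cn)) labels[i] <- min(labels[cn])
    }
  }
  labels
}

## Random symmetric nonnegative "distance" matrix with planted structure.
random_distance_matrix <- function(n, scale = 3) {
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

## Acceptor-target centers used by separated_pose_modes (Angstrom).
mode_centers <- function(k, had_mean = 3.5) {
  lapply(separated_pose_modes(k), function(m) {
    q <- c(1.166, 0, 3.3) + m$displacement
    had_mean * q / sqrt(sum(q^2))
  })
}

expect_same_clustering <- function(a, b) {
  expect_identical(as.integer(a), as.integer(b))
}
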