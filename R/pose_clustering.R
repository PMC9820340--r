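## Pose clustering: pairwise ligand RMSD over trajectory frames, DBSCAN on
## the precomputed distance matrix, medoid representatives, and contact
## residues around the ligand.

#' Pairwise ligand RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the ligand RMSD between frames i and j after superposing
#' frame j onto frame i by the `fit` selection (typically protein heavy
#' atoms); the ligand is *not* re-fitted, so the matrix measures pose changes
#' relative to the binding site. Because the fit makes the raw entries
#' slightly asymmetric, the matrix is symmetrized by averaging (i, j) and
#' (j, i). Hydrogens are rejected from the ligand selection: pose RMSD is
#' conventionally computed over heavy atoms only.
#'
#' @param traj a `mol_trajectory`.
#' @param ligand selection of ligand heavy atoms (no hydrogens).
#' @param fit selection of atoms used for superposition (>= 3 atoms).
#' @return list of class `rmsd_matrix`: `frame_ids` and symmetric `values`
#'   matrix (Angstrom).
#' @export
ligand_rmsd_matrix <- function(traj, ligand, fit) {
  top <- traj$topology
  lig <- resolve_selection(top, ligand)
  fit_idx <- resolve_selection(top, fit)
  if (length(lig) == 0L) stop("empty ligand selection")
  if (length(fit_idx) < 3L) stop("fit selection needs at least 3 atoms")
  if (any(top$atoms$element[lig] == "H"))
    stop("ligand selection contains hydrogens; pose RMSD uses heavy atoms only")
  nf <- n_frames(traj)
  lig_xyz <- lapply(seq_len(nf), function(k)
    matrix(traj$coords[lig, , k], ncol = 3L))
  fit_xyz <- lapply(seq_len(nf), function(k)
    matrix(traj$coords[fit_idx, , k], ncol = 3L))
  one_direction <- function(i, j) {
    tf <- kabsch_superpose(fit_xyz[[j]], fit_xyz[[i]])
    rmsd(lig_xyz[[i]], apply_transform(lig_xyz[[j]], tf), fit = FALSE)
  }
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- (one_direction(i, j) + one_direction(j, i)) / 2
    }
  }
  structure(list(frame_ids = seq_len(nf), values = m), class = "rmsd_matrix")
}

as_distance_matrix <- function(x) {
  if (inherits(x, "rmsd_matrix")) return(x)
  m <- as.matrix(x)
  structure(list(frame_ids = seq_len(nrow(m)), values = m), class = "rmsd_matrix")
}

validate_distance_matrix <- function(m) {
  v <- m$values
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-9)
    stop("distance matrix must be symmetric")
  if (any(v < 0)) stop("distance matrix must be nonnegative")
  invisible(m)
}

#' DBSCAN on a precomputed distance matrix
#'
#' Classic density-based clustering: a core point has at least `min_points`
#' neighbors within `eps` (the point itself included in the count); clusters
#' are the connected components of core points under eps-adjacency, with
#' border points attached to a core neighbor; everything else is noise. A
#' border point reachable from several clusters is assigned to the cluster of
#' its lowest-labeled core neighbor, making the classic order-dependence
#' explicit and deterministic. The defaults, eps 1.5 Angstrom and 5 points,
#' are the standard choice for ligand-pose RMSD clustering.
#'
#' @param x an `rmsd_matrix` or symmetric nonnegative matrix (Angstrom).
#' @param eps neighborhood radius, Angstrom.
#' @param min_points minimum neighborhood size for a core point.
#' @return list of class `cluster_result`: `labels` (0 = noise, 1..k),
#'   `medoid_frames` (one frame id per cluster), `eps`, `min_points`.
#' @export
dbscan_poses <- function(x, eps = 1.5, min_points = 5L) {
  m <- validate_distance_matrix(as_distance_matrix(x))
  if (eps <= 0) stop("eps must be positive")
  if (min_points < 1L) stop("min_points must be >= 1")
  d <- m$values
  n <- nrow(d)
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= min_points
  labels <- integer(n)               # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      reach <- nbrs[[p]][core[nbrs[[p]]] & labels[nbrs[[p]]] == 0L]
      labels[reach] <- cl
      queue <- c(queue, reach)
    }
  }
  ## border points: non-core with a core neighbor -> lowest-labeled cluster
  for (i in seq_len(n)) {
    if (core[i]) next
    cn <- nbrs[[i]][core[nbrs[[i]]]]
    if (length(cn)) labels[i] <- min(labels[cn])
  }
  medoids <- if (cl > 0L)
    vapply(seq_len(cl), function(k)
      medoid(m, m$frame_ids[labels == k]), 1L)
  else integer(0)
  structure(list(labels = labels, medoid_frames = medoids,
                 eps = eps, min_points = as.integer(min_points)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(x$medoid_frames)
  cat(sprintf("DBSCAN (eps %.2f A, minPts %d): %d cluster%s, %d noise / %d frames\n",
              x$eps, x$min_points, k, if (k == 1) "" else "s",
              sum(x$labels == 0L), length(x$labels)))
  if (k) cat("medoid frames:", paste(x$medoid_frames, collapse = ", "), "\n")
  invisible(x)
}

#' Medoid of a set of frames
#'
#' The member minimizing the summed distance to all other members; ties are
#' broken by the lowest frame id.
#'
#' @param x an `rmsd_matrix` (or plain symmetric matrix).
#' @param members frame ids (must be present in the matrix).
#' @return The medoid frame id.
#' @export
medoid <- function(x, members) {
  m <- as_distance_matrix(x)
  if (length(members) < 1L) stop("medoid of an empty member set")
  if (anyNA(match(members, m$frame_ids)))
    stop("member not present in the distance matrix")
  members <- sort(members)
  pos <- match(members, m$frame_ids)
  sums <- rowSums(m$values[pos, pos, drop = FALSE])
  members[which.min(sums)]          # which.min takes the first (lowest id) tie
}

#' Residues in contact with a ligand
#'
#' Residues (other than the ligand's own) having any atom within `cutoff` of
#' any ligand atom, hydrogens included. The 3 Angstrom default matches the
#' contact shell conventionally highlighted around bound nitroaromatics.
#'
#' @param structure a `mol_structure`.
#' @param ligand ligand atom selection.
#' @param cutoff contact distance, Angstrom.
#' @return data.frame of class `contact_set` with columns `chain`, `resid`,
#'   `resname`, `min_dist`, sorted by residue id; attribute `cutoff`.
#' @export
contact_residues <- function(structure, ligand, cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  lig <- resolve_selection(structure, ligand)
  if (length(lig) == 0L) stop("empty ligand selection")
  a <- structure$atoms
  lig_res <- unique(paste(a$chain[lig], a$resid[lig], a$resname[lig]))
  res_key <- paste(a$chain, a$resid, a$resname)
  other <- which(!(res_key %in% lig_res))
  if (length(other) == 0L) {
    out <- data.frame(chain = character(), resid = integer(),
                      resname = character(), min_dist = numeric())
  } else {
    lx <- structure$xyz[lig, , drop = FALSE]
    ox <- structure$xyz[other, , drop = FALSE]
    ## min distance from each non-ligand atom to any ligand atom
    d2 <- outer(rowSums(ox^2), rep(1, nrow(lx))) +
      outer(rep(1, nrow(ox)), rowSums(lx^2)) - 2 * ox %*% t(lx)
    mind <- sqrt(pmax(apply(d2, 1L, min), 0))
    df <- data.frame(key = res_key[other], chain = a$chain[other],
                     resid = a$resid[other], resname = a$resname[other],
                     d = mind, stringsAsFactors = FALSE)
    agg <- stats::aggregate(d ~ key + chain + resid + resname, df, min)
    agg <- agg[agg$d <= cutoff, , drop = FALSE]
    agg <- agg[order(agg$resid), , drop = FALSE]
    out <- data.frame(chain = agg$chain, resid = agg$resid,
                      resname = agg$resname, min_dist = agg$d,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", "data.frame")
  out
}
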