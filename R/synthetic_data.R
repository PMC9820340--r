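## Synthetic enzyme-ligand fixtures.
##
## The generator emulates the geometry of a flavoenzyme binding pocket: a
## static scaffold holding an FMN-like cofactor (hydride donor atom "N5" at
## the origin, isoalloxazine-like plane at z = 0) and a few named pocket
## residues, plus a rigid planar TNT-like ligand stacked parallel to the
## cofactor plane. Per frame, a pose mode is drawn by weight; the target
## direction from N5 is jittered with isotropic Gaussian noise and the
## hydride-acceptor atom is then placed at a distance drawn from
## N(had_mean, had_sd) along that direction, so the realized HAD-distance
## distribution has exactly the requested first two moments while lateral
## mode structure drives pose clustering. Poses are sampled, not propagated:
## there is no force field, no solvent, no dynamics.

## TNT-like ligand template, local coordinates (Angstrom), ring in xy-plane.
## Ring C1-C6; methyl C7 on C1; nitro groups on C2/C4/C6 named by carbon
## (N2/O21/O22 etc.); ring hydrogens H3/H5; methyl hydrogens H71-H73.
## 16 heavy atoms + 5 hydrogens = 21 atoms (C7H5N3O6).
tnt_template <- function() {
  ring_r <- 1.39
  ang <- (0:5) * pi / 3                      # C1 at angle 0
  atoms <- list()
  add <- function(name, element, x, y) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      element = element, name = name, x = x, y = y, stringsAsFactors = FALSE)
  }
  for (i in 1:6) add(paste0("C", i), "C", ring_r * cos(ang[i]), ring_r * sin(ang[i]))
  add("C7", "C", 2.89 * cos(ang[1]), 2.89 * sin(ang[1]))          # methyl
  for (i in c(2L, 4L, 6L)) {                                       # nitro groups
    nr <- 2.86
    add(paste0("N", i), "N", nr * cos(ang[i]), nr * sin(ang[i]))
    for (s in c(-1, 1)) {
      a <- ang[i] + s * pi / 6
      add(paste0("O", i, if (s < 0) "1" else "2"), "O",
          nr * cos(ang[i]) + 1.21 * cos(a), nr * sin(ang[i]) + 1.21 * sin(a))
    }
  }
  for (i in c(3L, 5L)) add(paste0("H", i), "H", 2.47 * cos(ang[i]), 2.47 * sin(ang[i]))
  for (k in 1:3) {
    a <- ang[1] + (k - 2) * 0.35
    add(paste0("H7", k), "H", 2.89 * cos(ang[1]) + 1.0 * cos(a),
        2.89 * sin(ang[1]) + 1.0 * sin(a))
  }
  df <- do.call(rbind, atoms)
  df$resname <- "TNT"
  df$resid <- 900L
  df$chain <- "A"
  df
}

## Static pocket scaffold. All heavy atoms; FMN-like plane at z = 0 kept at
## x <= 0 so the +x half-space above the plane is free for pose modes.
pocket_scaffold <- function() {
  rows <- list()
  add <- function(resname, resid, name, element, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      element = element, name = name, resname = resname,
      resid = as.integer(resid), chain = "A", x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  }
  ## FMN-like cofactor: hydride donor N5 at the origin
  add("FMN", 500, "N5", "N", 0, 0, 0)
  add("FMN", 500, "C4A", "C", -1.25, 0.72, 0)
  add("FMN", 500, "C4", "C", -2.55, 1.40, 0)
  add("FMN", 500, "O4", "O", -2.70, 2.61, 0)
  add("FMN", 500, "N10", "N", -2.40, -0.70, 0)
  add("FMN", 500, "C10", "C", -1.20, -1.35, 0)
  ## Tyr-like residue: aromatic ring stacked parallel over the ligand plane
  ## (ring plane z = 6.7, i.e. 3.4 A above the ligand plane at z = 3.3),
  ## hydroxyl reaching down to 2.8 A of ligand atom C1.
  cx <- -0.264; cy <- -2.477                 # ligand-plane center (see below)
  for (i in 1:6) {
    a <- (i - 1) * pi / 3
    add("TYR", 65, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")[i], "C",
        cx + 1.39 * cos(a), cy + 1.39 * sin(a), 6.7)
  }
  add("TYR", 65, "OH", "O", 1.126, -2.477, 6.1)
  add("TYR", 65, "CB", "C", cx + 2.5, cy, 7.4)
  ## Leu-like residue: side-chain carbon 2.9 A below nitro nitrogen N4
  add("LEU", 129, "CD1", "C", -3.124, -2.477, 0.4)
  add("LEU", 129, "CG", "C", -4.3, -3.1, -0.3)
  add("LEU", 129, "CB", "C", -5.5, -2.5, -0.9)
  ## Second Tyr-like residue: hydroxyl 2.85 A from ring atom C6
  add("TYR", 335, "OH", "O", 0.431, -3.681, 6.15)
  add("TYR", 335, "CZ", "C", 0.431, -4.9, 6.9)
  add("TYR", 335, "CE1", "C", 1.6, -5.5, 7.2)
  ## Thr-like residue: outside the 3 A shell by construction
  add("THR", 24, "OG1", "O", 6.0, 2.5, 4.0)
  add("THR", 24, "CB", "C", 7.2, 3.0, 4.4)
  add("THR", 24, "CG2", "C", 8.3, 2.2, 4.9)
  do.call(rbind, rows)
}

## Nominal ligand placement: plane z = 3.3 (parallel stacking over the
## cofactor plane), translated so the acceptor nitro nitrogen "N2" sits at
## distance 3.5 A from donor N5 = origin. With N2 at local (1.43, 2.477),
## the in-plane offset sqrt(3.5^2 - 3.3^2) = 1.166 puts N2 at
## (1.166, 0, 3.3) and the ring center at (-0.264, -2.477, 3.3).
NOMINAL_ACCEPTOR <- c(1.166, 0, 3.3)

place_ligand_nominal <- function() {
  tpl <- tnt_template()
  n2 <- unlist(tpl[tpl$name == "N2", c("x", "y")])
  shift <- c(NOMINAL_ACCEPTOR[1] - n2[1], NOMINAL_ACCEPTOR[2] - n2[2],
             NOMINAL_ACCEPTOR[3])
  xyz <- cbind(tpl$x + shift[1], tpl$y + shift[2], rep(shift[3], nrow(tpl)))
  list(atoms = tpl[, c("element", "name", "resname", "resid", "chain")],
       xyz = xyz)
}

#' Deterministic toy pocket-ligand complex
#'
#' A single-structure fixture: the static pocket scaffold (an FMN-like
#' cofactor with donor atom "N5", two tyrosine-like residues, a leucine-like
#' and a threonine-like residue) plus the planar TNT-like ligand at its
#' nominal stacked pose. By construction exactly three scaffold residues
#' (Tyr65-, Leu129- and Tyr335-like) have an atom within 3 Angstrom of the
#' ligand, the Tyr65-like ring is parallel to the ligand ring at 3.4
#' Angstrom, and the acceptor atom "N2" sits 3.5 Angstrom from "N5".
#'
#' @return A `mol_structure`.
#' @export
make_pocket_complex <- function() {
  sc <- pocket_scaffold()
  lig <- place_ligand_nominal()
  atoms <- rbind(sc[, c("element", "name", "resname", "resid", "chain")],
                 lig$atoms)
  xyz <- rbind(as.matrix(sc[, c("x", "y", "z")]), lig$xyz)
  mol_structure(atoms, xyz, title = "synthetic pocket complex")
}

#' Recipe for a synthetic enzyme-ligand trajectory
#'
#' @param n_frames number of frames (>= 1). The default 500 keeps test-scale
#'   runs fast; see [recipe_full_production()] for the full-length preset.
#' @param frame_interval time between frames, ns (default 0.02 ns, i.e. 50
#'   frames per ns).
#' @param pose_modes list of modes, each `list(displacement, weight, sd)`:
#'   a 3-vector displacing the acceptor target point (Angstrom), a sampling
#'   weight, and the isotropic within-mode positional sd (Angstrom). Weights
#'   must sum to 1.
#' @param had_mean,had_sd mean and sd (Angstrom) of the realized hydride
#'   acceptor-donor distance.
#' @param escape NULL for a stable complex, or `list(frame, rate)`: after
#'   `frame`, the acceptor distance grows by `rate` Angstrom per frame
#'   (ligand leaving the pocket).
#' @param seed integer seed; generation is bitwise deterministic given the
#'   recipe.
#' @return list of class `complex_recipe`.
#' @export
complex_recipe <- function(n_frames = 500L, frame_interval = 0.02,
                           pose_modes = list(list(displacement = c(0, 0, 0),
                                                  weight = 1, sd = 0.2)),
                           had_mean = 3.5, had_sd = 0.2,
                           escape = NULL, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  w <- vapply(pose_modes, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("pose mode weights must sum to 1")
  if (any(vapply(pose_modes, `[[`, 0, "sd") <= 0))
    stop("pose mode sds must be positive")
  if (had_mean <= 0 || had_sd < 0) stop("had_mean must be > 0 and had_sd >= 0")
  if (!is.null(escape) &&
      (is.null(escape$frame) || is.null(escape$rate) || escape$rate <= 0))
    stop("escape must be list(frame, rate) with rate > 0")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pose_modes = pose_modes,
                 had_mean = had_mean, had_sd = had_sd, escape = escape,
                 seed = as.integer(seed)),
            class = "complex_recipe")
}

#' Full-length production recipe preset
#'
#' The study-scale trajectory: 200 ns recorded as 50 frames every 1 ns,
#' 10,000 frames in total.
#'
#' @param ... overrides passed to [complex_recipe()].
#' @export
recipe_full_production <- function(...) {
  complex_recipe(n_frames = 10000L, frame_interval = 0.02, ...)
}

#' Well-separated pose modes for cluster-recovery studies
#'
#' Builds `k` (1-3) pose modes by rotating the nominal acceptor direction
#' about the y axis through N5, keeping targets on the sphere of the nominal
#' HAD distance so that mode separations are chord lengths: ~4.0 Angstrom
#' for k = 2 (+/- 35 degrees) and >= 4.0 for k = 3 (-70/0/+70 degrees).
#'
#' @param k number of modes (1, 2 or 3).
#' @param sd within-mode positional sd, Angstrom.
#' @return list of pose modes for [complex_recipe()].
#' @export
separated_pose_modes <- function(k, sd = 0.4) {
  if (!(k %in% 1:3)) stop("k must be 1, 2 or 3")
  degs <- switch(k, `1` = 0, `2` = c(-35, 35), `3` = c(-70, 0, 70))
  lapply(degs, function(deg) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
                byrow = TRUE)
    list(displacement = as.numeric(R %*% NOMINAL_ACCEPTOR) - NOMINAL_ACCEPTOR,
         weight = 1 / length(degs), sd = sd)
  })
}

#' Generate a synthetic enzyme-ligand trajectory
#'
#' See [complex_recipe()] for the sampling model. The scaffold is static;
#' the ligand is rigidly translated per frame so that its acceptor atom
#' "N2" sits at the sampled distance from donor "N5" along the sampled
#' direction. Selections such as `"resname FMN and name N5"` or
#' `"resname TNT and not element H"` resolve on the topology.
#'
#' @param recipe a `complex_recipe`.
#' @return A `mol_trajectory` with frame times in ns.
#' @export
make_complex_trajectory <- function(recipe) {
  stopifnot(inherits(recipe, "complex_recipe"))
  base <- make_pocket_complex()
  n_sc <- nrow(pocket_scaffold())
  lig_rows <- (n_sc + 1L):nrow(base$atoms)
  n2_row <- lig_rows[base$atoms$name[lig_rows] == "N2"]
  a0 <- NOMINAL_ACCEPTOR
  ## geometry feasibility: each mode target must stay clear of the scaffold
  sc_xyz <- base$xyz[seq_len(n_sc), , drop = FALSE]
  for (m in recipe$pose_modes) {
    q <- a0 + m$displacement
    if (sqrt(sum(q^2)) < 0.5)
      stop("impossible geometry: mode target collapses onto the donor atom")
    tgt <- recipe$had_mean * q / sqrt(sum(q^2))
    dmin <- min(sqrt(rowSums(sweep(sc_xyz, 2, tgt)^2)))
    if (dmin < 1.0)
      stop("impossible geometry: mode displacement places the ligand inside the pocket scaffold")
  }
  nf <- recipe$n_frames
  k <- length(recipe$pose_modes)
  draws <- with_private_seed(recipe$seed, {
    mode_idx <- if (k == 1L) rep(1L, nf)
                else sample.int(k, nf, replace = TRUE,
                                prob = vapply(recipe$pose_modes, `[[`, 0, "weight"))
    eps <- matrix(stats::rnorm(3L * nf), nf, 3L)
    d <- stats::rnorm(nf, recipe$had_mean, recipe$had_sd)
    list(mode_idx = mode_idx, eps = eps, d = d)
  })
  if (!is.null(recipe$escape)) {
    f0 <- recipe$escape$frame
    late <- seq_len(nf) > f0
    draws$d[late] <- draws$d[late] + recipe$escape$rate * (which(late) - f0)
  }
  coords <- array(rep(base$xyz, nf), c(nrow(base$xyz), 3L, nf))
  n2_nominal <- base$xyz[n2_row, ]
  for (f in seq_len(nf)) {
    m <- recipe$pose_modes[[draws$mode_idx[f]]]
    q <- a0 + m$displacement + m$sd * draws$eps[f, ]
    u <- q / sqrt(sum(q^2))
    shift <- draws$d[f] * u - n2_nominal
    coords[lig_rows, , f] <- sweep(base$xyz[lig_rows, , drop = FALSE], 2,
                                   shift, "+")
  }
  mol_trajectory(base, coords, times = recipe$frame_interval * seq_len(nf))
}

#' Regular planar ring structure
#'
#' A regular n-gon of one element in the xy-plane, centered at the origin,
#' with the given bond (edge) length; for n = 6 the circumradius equals the
#' bond length, giving a benzene-like carbon skeleton at 1.39 Angstrom.
#'
#' @param n number of atoms (>= 3).
#' @param bond_length edge length, Angstrom.
#' @param element element symbol.
#' @param resname residue name for the generated atoms.
#' @return A `mol_structure` with atoms named `<element>1..<element>n`.
#' @export
make_ring <- function(n = 6L, bond_length = 1.39, element = "C",
                      resname = "RNG") {
  if (n < 3L) stop("a ring needs at least 3 atoms")
  radius <- bond_length / (2 * sin(pi / n))
  ang <- 2 * pi * (0:(n - 1L)) / n
  atoms <- data.frame(element = element,
                      name = paste0(element, seq_len(n)),
                      resname = resname, resid = 1L, chain = "A",
                      stringsAsFactors = FALSE)
  mol_structure(atoms, cbind(radius * cos(ang), radius * sin(ang), 0),
                title = sprintf("%s%d ring", element, n))
}

#' Translate a structure
#'
#' @param structure a `mol_structure`.
#' @param shift 3-vector, Angstrom.
#' @export
translate_structure <- function(structure, shift) {
  mol_structure(structure$atoms, sweep(structure$xyz, 2, shift, "+"),
                title = structure$title)
}

#' Concatenate two structures
#'
#' Atom order is a's atoms followed by b's.
#'
#' @param a,b `mol_structure`s.
#' @export
combine_structures <- function(a, b) {
  mol_structure(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz),
                title = paste(a$title, "+", b$title))
}
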