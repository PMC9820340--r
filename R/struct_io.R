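## Structure, trajectory and volumetric-grid I/O.
##
## Internal representation: a `mol_structure` is a list with an `atoms`
## data.frame (element, name, resname, resid, chain), an n x 3 `xyz` matrix in
## Angstrom, and a free-text `title`. A `mol_trajectory` holds one topology
## plus an n_atoms x 3 x n_frames coordinate array and optional frame times in
## ns. A `volumetric_grid` is origin + 3 step vectors + shape + values stored
## with the third (z) index fastest, the ordering used by cube-format files.

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `element`, `name`, `resname`, `resid`,
#'   `chain`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param title free-text title.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, xyz, title = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) < 1L) stop("a structure needs at least one atom")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  el <- normalize_element(atoms$element)
  if (anyNA(el)) {
    bad <- which(is.na(el))[1L]
    stop(sprintf("unrecognized element '%s' for atom %d (name '%s')",
                 atoms$element[bad], bad, atoms$name[bad]))
  }
  atoms$element <- el
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, title = title),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure: %d atoms, %d residues%s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param topology a `mol_structure` providing atom metadata for every frame.
#' @param coords n_atoms x 3 x n_frames array (Angstrom).
#' @param times optional frame times in ns, strictly increasing.
#' @return An object of class `mol_trajectory`.
#' @export
mol_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "mol_structure"))
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[1L] != nrow(topology$atoms) || dim(coords)[2L] != 3L)
    stop("coords must be n_atoms x 3 x n_frames")
  if (!is.null(times)) {
    if (length(times) != dim(coords)[3L]) stop("times length != frame count")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = times),
            class = "mol_trajectory")
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("mol_trajectory: %d frames x %d atoms\n",
              n_frames(x), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `mol_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a `mol_trajectory`.
#' @param i frame index (1-based).
#' @export
frame_structure <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  mol_structure(traj$topology$atoms, traj$coords[, , i],
                title = sprintf("%s frame %d", traj$topology$title, i))
}

## ---- PDB ------------------------------------------------------------------

pdb_field <- function(lines, from, to) substr(lines, from, to)

## Element inference for PDB atoms: columns 77-78 when non-blank, otherwise
## the leading alphabetic characters of the atom name with digits stripped
## (two-letter symbols recognized only when they match a known element).
infer_pdb_element <- function(elem_col, name) {
  e <- trimws(elem_col)
  out <- normalize_element(e)
  blank <- !nzchar(e)
  if (any(blank)) {
    nm <- gsub("[^A-Za-z]", "", name[blank])
    full <- normalize_element(nm)          # e.g. "FE" -> Fe, "CL" -> Cl
    one <- normalize_element(substr(nm, 1, 1))  # e.g. "CA" -> C, "OH" -> O
    out[blank] <- ifelse(!is.na(full), full, one)
  }
  out
}

parse_pdb_atoms <- function(lines, lineno, path) {
  rec <- pdb_field(lines, 1, 6)
  keep <- grepl("^(ATOM|HETATM)", rec)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L)
    stop(sprintf("no ATOM/HETATM records in '%s'", path))
  xs <- suppressWarnings(as.numeric(pdb_field(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(pdb_field(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(pdb_field(lines, 47, 54)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop(sprintf("PDB parse error at line %d of '%s': unreadable coordinate field",
                 lineno[bad[1L]], path))
  resid <- suppressWarnings(as.integer(pdb_field(lines, 23, 26)))
  bad <- which(is.na(resid))
  if (length(bad))
    stop(sprintf("PDB parse error at line %d of '%s': unreadable residue number",
                 lineno[bad[1L]], path))
  name <- trimws(pdb_field(lines, 13, 16))
  elem <- infer_pdb_element(pdb_field(lines, 77, 78), name)
  if (anyNA(elem)) {
    bad <- which(is.na(elem))[1L]
    stop(sprintf("unknown element for atom '%s' at line %d of '%s'",
                 name[bad], lineno[bad], path))
  }
  atoms <- data.frame(
    element = elem,
    name = name,
    resname = trimws(pdb_field(lines, 18, 20)),
    resid = resid,
    chain = pdb_field(lines, 22, 22),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, xyz = cbind(xs, ys, zs))
}

format_pdb_atom_lines <- function(atoms, xyz) {
  n <- nrow(atoms)
  sprintf("HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(n) %% 100000L,
          ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name),
          atoms$resname, atoms$chain, atoms$resid,
          xyz[, 1], xyz[, 2], xyz[, 3],
          toupper(atoms$element))
}

## ---- XYZ ------------------------------------------------------------------

parse_xyz_block <- function(lines, start, path) {
  n <- suppressWarnings(as.integer(lines[start]))
  if (is.na(n) || n < 1L)
    stop(sprintf("XYZ parse error at line %d of '%s': expected atom count",
                 start, path))
  if (start + 1L + n > length(lines))
    stop(sprintf("XYZ file '%s' truncated: frame starting at line %d declares %d atoms",
                 path, start, n))
  title <- lines[start + 1L]
  body <- lines[start + 1L + seq_len(n)]
  toks <- strsplit(sub("^\\s+", "", body), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad))
    stop(sprintf("XYZ parse error at line %d of '%s'", start + 1L + bad[1L], path))
  el <- vapply(toks, `[`, "", 1L)
  xyz <- t(vapply(toks, function(t) suppressWarnings(as.numeric(t[2:4])),
                  numeric(3)))
  bad <- which(apply(is.na(xyz), 1, any))
  if (length(bad))
    stop(sprintf("XYZ parse error at line %d of '%s': unreadable coordinate",
                 start + 1L + bad[1L], path))
  list(n = n, title = title, element = el, xyz = xyz,
       next_start = start + 2L + n)
}

xyz_atoms_frame <- function(el, resname = "MOL") {
  data.frame(element = el,
             name = paste0(el, seq_along(el)),
             resname = resname, resid = 1L, chain = "A",
             stringsAsFactors = FALSE)
}

## ---- public readers/writers ----------------------------------------------

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, pdb = "pdb", ent = "pdb", xyz = "xyz", cube = "cube", cub = "cube",
         stop(sprintf("cannot guess format from extension '%s'", ext)))
}

#' Read a molecular structure from a PDB or XYZ file
#'
#' For PDB only ATOM/HETATM records contribute atoms; the element is taken
#' from columns 77-78 when present, otherwise inferred from the atom name.
#' Multi-model PDB files yield the first model.
#'
#' @param path file path.
#' @param format "pdb" or "xyz"; guessed from the extension when missing.
#' @return A `mol_structure`.
#' @export
read_structure <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("pdb", "xyz"))
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") {
    blk <- parse_xyz_block(lines, 1L, path)
    el <- normalize_element(blk$element)
    if (anyNA(el)) {
      bad <- which(is.na(el))[1L]
      stop(sprintf("unknown element '%s' at line %d of '%s'",
                   blk$element[bad], 2L + bad, path))
    }
    return(mol_structure(xyz_atoms_frame(el), blk$xyz, title = blk$title))
  }
  ## PDB: keep only the first model if MODEL records are present
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines2 <- lines[seq_len(endm[1L] - 1L)] else lines2 <- lines
  p <- parse_pdb_atoms(lines2, seq_along(lines2), path)
  mol_structure(p$atoms, p$xyz, title = basename(path))
}

#' Write a molecular structure to a PDB or XYZ file
#'
#' @param structure a `mol_structure`.
#' @inheritParams read_structure
#' @export
write_structure <- function(structure, path, format = guess_format(path)) {
  format <- match.arg(format, c("pdb", "xyz"))
  if (format == "xyz") {
    n <- nrow(structure$atoms)
    lines <- c(as.character(n), structure$title,
               sprintf("%-2s %14.8f %14.8f %14.8f", structure$atoms$element,
                       structure$xyz[, 1], structure$xyz[, 2], structure$xyz[, 3]))
  } else {
    lines <- c(format_pdb_atom_lines(structure$atoms, structure$xyz), "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB or multi-frame XYZ file
#'
#' Frames are delimited by MODEL/ENDMDL records (PDB) or stacked XYZ blocks;
#' a file without MODEL records yields a single-frame trajectory. All frames
#' must share the atom count and order of the first frame.
#'
#' @inheritParams read_structure
#' @param format "pdb" or "xyz".
#' @return A `mol_trajectory`.
#' @export
read_trajectory <- function(path, format = guess_format(path)) {
  format <- match.arg(format, c("pdb", "xyz"))
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms1 <- NULL
  if (format == "pdb") {
    starts <- grep("^MODEL", lines)
    if (length(starts) == 0L) {
      p <- parse_pdb_atoms(lines, seq_along(lines), path)
      return(mol_trajectory(mol_structure(p$atoms, p$xyz, basename(path)),
                            array(p$xyz, c(nrow(p$xyz), 3L, 1L))))
    }
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    for (k in seq_along(starts)) {
      idx <- (starts[k] + 1L):(ends[k] - 1L)
      p <- parse_pdb_atoms(lines[idx], idx, path)
      if (k == 1L) atoms1 <- p$atoms
      else if (nrow(p$atoms) != nrow(atoms1))
        stop(sprintf("frame %d of '%s' has %d atoms; frame 1 has %d",
                     k, path, nrow(p$atoms), nrow(atoms1)))
      frames[[k]] <- p$xyz
    }
  } else {
    start <- 1L
    k <- 0L
    while (start <= length(lines) && nzchar(sub("\\s+", "", lines[start]))) {
      blk <- parse_xyz_block(lines, start, path)
      k <- k + 1L
      if (k == 1L) {
        el <- normalize_element(blk$element)
        if (anyNA(el)) stop(sprintf("unknown element in '%s'", path))
        atoms1 <- xyz_atoms_frame(el)
      } else if (blk$n != nrow(atoms1)) {
        stop(sprintf("frame %d of '%s' has %d atoms; frame 1 has %d",
                     k, path, blk$n, nrow(atoms1)))
      }
      frames[[k]] <- blk$xyz
      start <- blk$next_start
    }
  }
  coords <- array(0, c(nrow(atoms1), 3L, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  mol_trajectory(mol_structure(atoms1, frames[[1L]], basename(path)), coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `mol_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(format_pdb_atom_lines(traj$topology$atoms, traj$coords[, , k]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- atom selection -------------------------------------------------------

#' Select atoms with a minimal expression grammar
#'
#' The grammar is a conjunction ("and") of predicates:
#' `resname <code>`, `resid <integer>`, `name <label>`, `element <symbol>`,
#' `not element <symbol>`, `chain <id>`. No ranges or wildcards. An empty
#' match returns an empty selection, not an error.
#'
#' @param structure a `mol_structure`.
#' @param expression selection text, e.g. `"resname FMN and name N5"`.
#' @return Integer vector of atom indices in structure order.
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(expression, "\\band\\b")[[1L]]
  if (length(clauses) == 0L || all(!nzchar(trimws(clauses))))
    stop(sprintf("invalid selection expression: '%s'", expression))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1L]]
    neg <- FALSE
    if (length(tok) >= 1L && tok[1L] == "not") {
      neg <- TRUE
      tok <- tok[-1L]
    }
    if (length(tok) != 2L)
      stop(sprintf("invalid selection expression: '%s' (clause '%s')",
                   expression, trimws(cl)))
    m <- switch(tok[1L],
      resname = a$resname == tok[2L],
      resid   = a$resid == suppressWarnings(as.integer(tok[2L])),
      name    = a$name == tok[2L],
      element = a$element == normalize_element(tok[2L]),
      chain   = a$chain == tok[2L],
      stop(sprintf("invalid selection expression: '%s' (unknown predicate '%s')",
                   expression, tok[1L]))
    )
    m[is.na(m)] <- FALSE
    keep <- keep & (if (neg) !m else m)
  }
  which(keep)
}

## Resolve a selection argument (expression or index vector) to indices.
resolve_selection <- function(structure, sel) {
  if (is.character(sel) && length(sel) == 1L) sel <- select_atoms(structure, sel)
  sel <- as.integer(sel)
  if (anyDuplicated(sel)) stop("selection indices must be unique")
  if (length(sel) && (min(sel) < 1L || max(sel) > nrow(structure$atoms)))
    stop("selection index out of bounds")
  sel
}

## ---- volumetric grids (cube format) --------------------------------------

#' Construct a volumetric grid
#'
#' @param origin 3-vector, Angstrom.
#' @param axes 3 x 3 matrix whose rows are the grid step vectors, Angstrom.
#' @param shape 3 positive integers (number of points along each axis).
#' @param values scalar field, length `prod(shape)`, stored with the third
#'   index fastest (cube ordering); may be NULL for a geometry-only grid.
#' @export
volumetric_grid <- function(origin, axes, shape, values = NULL) {
  axes <- as.matrix(axes)
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("grid shape must be positive")
  if (abs(det(axes)) < 1e-12) stop("grid axes must be linearly independent")
  if (!is.null(values) && length(values) != prod(shape))
    stop(sprintf("values length %d != prod(shape) = %d",
                 length(values), prod(shape)))
  structure(list(origin = as.numeric(origin), axes = axes,
                 shape = shape, values = values),
            class = "volumetric_grid")
}

#' Cartesian coordinates of every grid point
#'
#' Points are returned in storage order (third index fastest).
#'
#' @param grid a `volumetric_grid`.
#' @return `prod(shape)` x 3 matrix, Angstrom.
#' @export
grid_points <- function(grid) {
  n <- grid$shape
  i <- rep(0:(n[1L] - 1L), each = n[2L] * n[3L])
  j <- rep(rep(0:(n[2L] - 1L), each = n[3L]), times = n[1L])
  k <- rep(0:(n[3L] - 1L), times = n[1L] * n[2L])
  cbind(grid$origin[1L] + i * grid$axes[1, 1] + j * grid$axes[2, 1] + k * grid$axes[3, 1],
        grid$origin[2L] + i * grid$axes[1, 2] + j * grid$axes[2, 2] + k * grid$axes[3, 2],
        grid$origin[3L] + i * grid$axes[1, 3] + j * grid$axes[2, 3] + k * grid$axes[3, 3])
}

#' Build an axis-aligned grid covering a box
#'
#' @param lower,upper box corners, Angstrom.
#' @param spacing grid step, Angstrom.
#' @return A geometry-only `volumetric_grid` with at least 2 points per axis.
#' @export
grid_from_box <- function(lower, upper, spacing = 0.15) {
  if (spacing <= 0) stop("spacing must be positive")
  ext <- pmax(upper - lower, 0)
  shape <- pmax(2L, as.integer(ceiling(ext / spacing)) + 1L)
  volumetric_grid(lower, diag(rep(spacing, 3)), shape)
}

#' Write a volumetric grid as a cube-format file
#'
#' Coordinates are converted to Bohr (the format's convention); values are
#' written six per line with the z index fastest.
#'
#' @param grid a `volumetric_grid` with values.
#' @param structure a `mol_structure` providing the atom records.
#' @param path output path.
#' @export
write_grid <- function(grid, structure, path) {
  if (is.null(grid$values)) stop("grid has no values")
  if (length(grid$values) != prod(grid$shape))
    stop("grid values length does not match shape")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("flavoreact volumetric field", "cube format, z-fastest"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(structure$atoms),
                     grid$origin[1] / BOHR_A, grid$origin[2] / BOHR_A,
                     grid$origin[3] / BOHR_A), con)
  for (r in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", grid$shape[r],
                       grid$axes[r, 1] / BOHR_A, grid$axes[r, 2] / BOHR_A,
                       grid$axes[r, 3] / BOHR_A), con)
  z <- ELEMENT_NUMBERS[structure$atoms$element]
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", z, as.numeric(z),
                     structure$xyz[, 1] / BOHR_A, structure$xyz[, 2] / BOHR_A,
                     structure$xyz[, 3] / BOHR_A), con)
  v <- grid$values
  pad <- (-length(v)) %% 6L
  vm <- matrix(c(sprintf("%13.5E", v), rep("", pad)), ncol = 6L, byrow = TRUE)
  body <- apply(vm, 1L, paste, collapse = " ")
  writeLines(body, con)
  invisible(path)
}

#' Read a cube-format volumetric file
#'
#' @param path file path.
#' @return list with `grid` (a `volumetric_grid`, Angstrom) and `structure`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  num <- function(i) as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]])
  h <- num(3L)
  natoms <- as.integer(h[1L])
  origin <- h[2:4] * BOHR_A
  axes <- matrix(0, 3, 3)
  shape <- integer(3)
  for (r in 1:3) {
    a <- num(3L + r)
    shape[r] <- as.integer(a[1L])
    axes[r, ] <- a[2:4] * BOHR_A
  }
  el_z <- integer(natoms)
  xyz <- matrix(0, natoms, 3)
  for (k in seq_len(natoms)) {
    a <- num(6L + k)
    el_z[k] <- as.integer(a[1L])
    xyz[k, ] <- a[3:5] * BOHR_A
  }
  el <- names(ELEMENT_NUMBERS)[match(el_z, ELEMENT_NUMBERS)]
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6L + natoms))]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop(sprintf("cube file '%s' has %d values; shape implies %d",
                 path, length(vals), prod(shape)))
  st <- mol_structure(xyz_atoms_frame(el), xyz, title = basename(path))
  list(grid = volumetric_grid(origin, axes, shape, vals), structure = st)
}

## ---- delimited tables -----------------------------------------------------

read_delim_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE)
}

#' Read a frontier-orbital energy table
#'
#' Expects delimited text (comma or tab, header row) with columns for the
#' compound identifier, the HOMO energy and the LUMO energy, in eV. Rows in
#' which the LUMO lies below the HOMO are rejected: an occupied level above
#' the unoccupied one is unphysical in this ground-state picture.
#'
#' @param path file path.
#' @return data.frame of class `orbital_energies` with columns `compound`,
#'   `eps_homo`, `eps_lumo`.
#' @export
read_orbital_table <- function(path) {
  df <- read_delim_table(path)
  names(df) <- tolower(names(df))
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0L)
      stop(sprintf("orbital table '%s' lacks a column named one of: %s",
                   path, paste(cands, collapse = ", ")))
    df[[hit[1L]]]
  }
  out <- data.frame(
    compound = as.character(pick(c("compound", "id", "molecule"))),
    eps_homo = as.numeric(pick(c("eps_homo", "homo", "e_homo"))),
    eps_lumo = as.numeric(pick(c("eps_lumo", "lumo", "e_lumo"))),
    stringsAsFactors = FALSE
  )
  bad <- which(out$eps_lumo < out$eps_homo)
  if (length(bad))
    stop(sprintf(paste0("row %d ('%s'): eps_lumo (%g) < eps_homo (%g); an ",
                        "occupied orbital above the unoccupied one is unphysical"),
                 bad[1L], out$compound[bad[1L]],
                 out$eps_lumo[bad[1L]], out$eps_homo[bad[1L]]))
  class(out) <- c("orbital_energies", "data.frame")
  out
}
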