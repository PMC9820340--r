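## Point-charge electrostatic potential maps and ring-current-strength
## aromaticity bookkeeping.

#' Read a per-atom partial charge table
#'
#' Delimited text (comma or tab, header row) with a `charge` column and an
#' optional `atom` index column used to order the charges. The total charge
#' must be within 1e-6 of an integer (partial charges fitted to a molecular
#' ESP always sum to the formal charge).
#'
#' @param path file path.
#' @param n_atoms expected atom count, checked when given.
#' @return Numeric vector of charges, elementary charge units.
#' @export
read_charges <- function(path, n_atoms = NULL) {
  df <- read_delim_table(path)
  names(df) <- tolower(names(df))
  if (!("charge" %in% names(df)))
    stop(sprintf("charge table '%s' lacks a 'charge' column", path))
  q <- as.numeric(df$charge)
  if ("atom" %in% names(df)) q <- q[order(as.integer(df$atom))]
  if (!is.null(n_atoms) && length(q) != n_atoms)
    stop(sprintf("charge table has %d rows; structure has %d atoms",
                 length(q), n_atoms))
  tot <- sum(q)
  if (abs(tot - round(tot)) > 1e-6)
    stop(sprintf("total charge %.8f is not within 1e-6 of an integer", tot))
  q
}

#' Point-charge electrostatic potential on a grid
#'
#' `V(r) = sum_a q_a / |r - R_a|` in atomic units (Hartree per elementary
#' charge). This is the monopole-level approximation of a molecular
#' electrostatic potential map; it reproduces the qualitative picture
#' (negative potential concentrated at nitro oxygens, positive over
#' electron-poor rings) without any electronic-structure input.
#'
#' @param structure a `mol_structure`.
#' @param charges numeric vector aligned to the structure's atom order.
#' @param grid a `volumetric_grid` giving the evaluation points (Angstrom).
#'   Grid points may not coincide with a nucleus.
#' @return A `volumetric_grid` carrying the potential values (a.u.).
#' @export
point_charge_esp <- function(structure, charges, grid) {
  if (length(charges) != nrow(structure$atoms))
    stop(sprintf("charge vector length %d does not match %d atoms",
                 length(charges), nrow(structure$atoms)))
  pts <- grid_points(grid) / BOHR_A
  R <- structure$xyz / BOHR_A
  V <- numeric(nrow(pts))
  for (a in seq_len(nrow(R))) {
    r <- sqrt((pts[, 1] - R[a, 1])^2 + (pts[, 2] - R[a, 2])^2 +
                (pts[, 3] - R[a, 3])^2)
    if (any(r < 1e-9))
      stop("grid point coincides with a nucleus; offset the grid origin")
    V <- V + charges[a] / r
  }
  volumetric_grid(grid$origin, grid$axes, grid$shape, V)
}

#' Potential extrema on a van der Waals distance shell
#'
#' Restricts the potential grid to nodes whose scaled distance to the
#' molecule, `min_a |r - R_a| / r_vdw(a)`, lies within `[scale_low,
#' scale_high]` (a band outside the atoms, Bondi-style radii), and reports
#' the most negative and most positive potential in the band together with
#' the nearest atom to each extremum. Negative-potential regions mark sites
#' open to protonation and electrophilic attack.
#'
#' @param potential a value-carrying `volumetric_grid` from
#'   [point_charge_esp()].
#' @param structure the `mol_structure` the potential belongs to.
#' @param scale_low,scale_high shell band in units of the vdW radius
#'   (must exceed 1 so the band lies outside the atoms).
#' @return list of class `esp_extrema`: `min` and `max`, each with `value`
#'   (a.u.), `location` (Angstrom) and `nearest_atom` (index).
#' @export
esp_extrema <- function(potential, structure, scale_low = 1.2,
                        scale_high = 2.0) {
  if (scale_low <= 1) stop("scale_low must exceed 1 (shell outside the atoms)")
  if (scale_high <= scale_low) stop("scale_high must exceed scale_low")
  pts <- grid_points(potential)
  rv <- VDW_RADII[structure$atoms$element]
  n <- nrow(pts)
  scaled <- rep(Inf, n)
  nearest <- integer(n)
  for (a in seq_len(nrow(structure$xyz))) {
    d <- sqrt((pts[, 1] - structure$xyz[a, 1])^2 +
                (pts[, 2] - structure$xyz[a, 2])^2 +
                (pts[, 3] - structure$xyz[a, 3])^2) / rv[a]
    upd <- d < scaled
    scaled[upd] <- d[upd]
    nearest[upd] <- a
  }
  band <- which(scaled >= scale_low & scaled <= scale_high)
  if (length(band) == 0L)
    stop("no grid nodes fall in the vdW shell band; use a finer or larger grid")
  v <- potential$values[band]
  i_min <- band[which.min(v)]
  i_max <- band[which.max(v)]
  mk <- function(i) list(value = potential$values[i], location = pts[i, ],
                         nearest_atom = nearest[i])
  structure(list(min = mk(i_min), max = mk(i_max),
                 scale_low = scale_low, scale_high = scale_high),
            class = "esp_extrema")
}

#' Net ring current strength and aromaticity classification
#'
#' The net ring current strength (RCS) is the sum of the diatropic
#' (positive, clockwise under the convention of a field perpendicular to the
#' ring) and paratropic (negative) integrated current components, in nA/T.
#' Positive net values characterize aromatic rings, negative values
#' antiaromatic ones, and values close to zero non-aromatic character; the
#' classification threshold `z` (default 1 nA/T) makes "close to zero"
#' explicit. For display the net value is rounded half-up to one decimal
#' (`17.60 + (-4.95) -> 12.7`).
#'
#' @param diatropic diatropic component, nA/T, >= 0.
#' @param paratropic paratropic component, nA/T, <= 0.
#' @param label free-text ring label.
#' @param threshold classification band half-width z, nA/T.
#' @return list of class `ring_current_record`: `label`, `diatropic`,
#'   `paratropic`, `net`, `net_display` (half-up, one decimal),
#'   `classification` in {aromatic, antiaromatic, non-aromatic}.
#' @examples
#' net_ring_current(17.60, -4.95, label = "benzene")
#' @export
net_ring_current <- function(diatropic, paratropic, label = "",
                             threshold = 1.0) {
  if (diatropic < 0)
    stop("diatropic component must be >= 0 (sign convention)")
  if (paratropic > 0)
    stop("paratropic component must be <= 0 (sign convention)")
  if (threshold <= 0) stop("threshold must be positive")
  net <- diatropic + paratropic
  cls <- if (net > threshold) "aromatic"
         else if (net < -threshold) "antiaromatic"
         else "non-aromatic"
  structure(list(label = label, diatropic = diatropic,
                 paratropic = paratropic, net = net,
                 net_display = round_half_up(net, 1L),
                 classification = cls, threshold = threshold),
            class = "ring_current_record")
}

#' @export
print.ring_current_record <- function(x, ...) {
  cat(sprintf("%snet RCS %.1f nA/T (diatropic %+.2f, paratropic %+.2f): %s\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$net_display, x$diatropic, x$paratropic, x$classification))
  invisible(x)
}

#' Ring-current table from per-ring components
#'
#' Vectorized convenience over [net_ring_current()].
#'
#' @param df data.frame with columns `label`, `diatropic`, `paratropic`.
#' @param threshold classification band half-width, nA/T.
#' @return data.frame with `net`, `net_display` and `classification` added.
#' @export
ring_current_table <- function(df, threshold = 1.0) {
  recs <- lapply(seq_len(nrow(df)), function(i)
    net_ring_current(df$diatropic[i], df$paratropic[i],
                     label = as.character(df$label[i]), threshold = threshold))
  data.frame(label = df$label, diatropic = df$diatropic,
             paratropic = df$paratropic,
             net = vapply(recs, `[[`, 0, "net"),
             net_display = vapply(recs, `[[`, 0, "net_display"),
             classification = vapply(recs, `[[`, "", "classification"),
             stringsAsFactors = FALSE)
}
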