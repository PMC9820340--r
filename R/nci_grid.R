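## Promolecular non-covalent-interaction (NCI) analysis.
##
## The molecular electron density is approximated as a promolecular sum of
## spherical free-atom densities, each a sum of exponential shells
## rho_atom(r) = sum_i c_i exp(-r / zeta_i) in atomic units. The reduced
## density gradient
##   s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))
## is small where weak interactions live; the sign of lambda2 (the middle
## eigenvalue of the density Hessian) times rho distinguishes attractive,
## van der Waals, and repulsive contacts. Gradient and Hessian are
## accumulated analytically from the same exponential terms - no finite
## differences in the production path.

#' Default proatom density model
#'
#' Exponential-shell free-atom densities for H, C, N, O, P and S. Each shell
#' carries `c * exp(-r / zeta)` (atomic units) with the coefficient fixed by
#' normalizing the shell to its electron count (`c = n / (8 pi zeta^3)`).
#' Core-shell decay lengths come from screened (Slater-rule) nuclear charges;
#' the valence-shell decay follows the exact asymptotic law of an atomic
#' density, `rho ~ exp(-2 sqrt(2 Ip) r)` with `Ip` the first ionization
#' energy, so the long-range tails that dominate intermolecular
#' low-gradient regions are physically scaled. Hydrogen is the exact
#' ground-state density `exp(-2 r) / pi`. The set is deliberately simple,
#' monotonically decreasing, and swappable: pass any list of data.frames
#' with columns `c` and `zeta` named by element.
#'
#' @return Named list of data.frames (`c`, `zeta`), class `proatom_model`.
#' @export
default_proatom_model <- function() {
  core <- function(n_elec, alpha) {        # Slater screened exponent
    zeta <- 1 / (2 * alpha)
    data.frame(c = n_elec / (8 * pi * zeta^3), zeta = zeta)
  }
  valence <- function(n_elec, ip) {        # ionization-derived tail, Ip in au
    zeta <- 1 / (2 * sqrt(2 * ip))
    data.frame(c = n_elec / (8 * pi * zeta^3), zeta = zeta)
  }
  model <- list(
    H = valence(1, 0.5),
    C = rbind(core(2, 5.70), valence(4, 0.4138)),
    N = rbind(core(2, 6.70), valence(5, 0.5341)),
    O = rbind(core(2, 7.70), valence(6, 0.5005)),
    P = rbind(core(2, 14.70), core(8, 5.425), valence(5, 0.3855)),
    S = rbind(core(2, 15.70), core(8, 5.925), valence(6, 0.3807))
  )
  structure(model, class = "proatom_model")
}

#' Evaluate a single proatom density at given radii
#'
#' @param model a `proatom_model`.
#' @param element element symbol.
#' @param r radii in Bohr.
#' @return Density values, atomic units.
#' @export
proatom_density <- function(model, element, r) {
  p <- model[[element]]
  if (is.null(p)) stop(sprintf("element '%s' missing from proatom model", element))
  out <- numeric(length(r))
  for (i in seq_len(nrow(p))) out <- out + p$c[i] * exp(-r / p$zeta[i])
  out
}

## Middle eigenvalue of many symmetric 3x3 matrices, vectorized.
## h is an n x 6 matrix with columns xx, yy, zz, xy, xz, yz.
sym3_middle_eigenvalue <- function(h) {
  a <- h[, 1L]; b <- h[, 2L]; cc <- h[, 3L]
  d <- h[, 4L]; e <- h[, 5L]; f <- h[, 6L]
  q <- (a + b + cc) / 3
  a1 <- a - q; b1 <- b - q; c1 <- cc - q
  p2 <- (a1^2 + b1^2 + c1^2) / 6 + (d^2 + e^2 + f^2) / 3
  p <- sqrt(pmax(p2, 0))
  ## det of (H - q I) / p, guarded for the isotropic case p ~ 0
  safe_p <- ifelse(p > 0, p, 1)
  detB <- (a1 * (b1 * c1 - f^2) - d * (d * c1 - f * e) + e * (d * f - b1 * e)) /
    safe_p^3
  rr <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(rr) / 3
  ## with phi in [0, pi/3]: e1 is the largest, e3 the smallest eigenvalue
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  mid <- 3 * q - e1 - e3
  ifelse(p > 0, mid, q)
}

#' Promolecular density, gradient, Hessian and NCI fields on a grid
#'
#' Sums proatom densities over all atoms at every grid point and accumulates
#' the analytic gradient and Hessian of the same exponential terms. From
#' these it fills the reduced density gradient `s` and the signed density
#' `sign(lambda2) * rho`, where lambda2 is the middle eigenvalue of the 3x3
#' density Hessian.
#'
#' @param structure a `mol_structure` (coordinates in Angstrom).
#' @param grid a `volumetric_grid` giving the evaluation geometry (Angstrom);
#'   spacing of 0.25 Angstrom or finer is recommended.
#' @param model a `proatom_model`; every element of the structure must be
#'   present in it.
#' @return list of class `nci_grid`: `geometry` (the input grid), `rho`,
#'   `grad` (n x 3), `hessian` (n x 6: xx, yy, zz, xy, xz, yz), `s`,
#'   `lambda2`, `signed_rho` - all in atomic units, co-registered in grid
#'   storage order.
#' @export
promolecular_fields <- function(structure, grid,
                                model = default_proatom_model()) {
  els <- unique(structure$atoms$element)
  missing <- setdiff(els, names(model))
  if (length(missing))
    stop(sprintf("element(s) missing from proatom model: %s",
                 paste(missing, collapse = ", ")))
  if (!("H" %in% els))
    message("promolecular fields: structure has no hydrogens (heavy-atom promolecule)")
  pts <- grid_points(grid) / BOHR_A          # Bohr
  R <- structure$xyz / BOHR_A
  n <- nrow(pts)
  rho <- numeric(n)
  grad <- matrix(0, n, 3L)
  hess <- matrix(0, n, 6L)
  for (a in seq_len(nrow(R))) {
    dx <- pts[, 1L] - R[a, 1L]
    dy <- pts[, 2L] - R[a, 2L]
    dz <- pts[, 3L] - R[a, 3L]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    r <- pmax(r, 1e-8)                       # guard nuclear positions
    p <- model[[structure$atoms$element[a]]]
    for (i in seq_len(nrow(p))) {
      e <- p$c[i] * exp(-r / p$zeta[i])
      fp <- -e / p$zeta[i]                   # f'(r)
      fpp <- e / p$zeta[i]^2                 # f''(r)
      rho <- rho + e
      gfac <- fp / r
      grad[, 1L] <- grad[, 1L] + gfac * dx
      grad[, 2L] <- grad[, 2L] + gfac * dy
      grad[, 3L] <- grad[, 3L] + gfac * dz
      t1 <- (fpp - gfac) / (r * r)           # coefficient of d_a d_b
      hess[, 1L] <- hess[, 1L] + t1 * dx * dx + gfac
      hess[, 2L] <- hess[, 2L] + t1 * dy * dy + gfac
      hess[, 3L] <- hess[, 3L] + t1 * dz * dz + gfac
      hess[, 4L] <- hess[, 4L] + t1 * dx * dy
      hess[, 5L] <- hess[, 5L] + t1 * dx * dz
      hess[, 6L] <- hess[, 6L] + t1 * dy * dz
    }
  }
  s <- reduced_gradient(rho, grad)
  lam2 <- sym3_middle_eigenvalue(hess)
  structure(list(geometry = grid, rho = rho, grad = grad, hessian = hess,
                 s = s, lambda2 = lam2, signed_rho = sign(lam2) * rho),
            class = "nci_grid")
}

#' Reduced density gradient
#'
#' `s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, pointwise, atomic units
#' in, dimensionless out.
#'
#' @param rho density values (> 0), atomic units.
#' @param grad n x 3 gradient matrix, atomic units.
#' @export
reduced_gradient <- function(rho, grad) {
  if (any(rho <= 0)) stop("reduced gradient requires strictly positive density")
  gnorm <- sqrt(rowSums(as.matrix(grad)^2))
  gnorm / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

#' Classify NCI grid points by interaction type
#'
#' Retains points with `s < s_max` and partitions them by `sign(lambda2) *
#' rho` against a threshold `t`: attractive (< -t), van der Waals (within
#' +/- t), repulsive (> t). The defaults (s_max 0.5, t 0.01 a.u.) follow
#' common promolecular-NCI practice.
#'
#' @param grid an `nci_grid`.
#' @param s_max reduced-gradient retention threshold (dimensionless).
#' @param t signed-density category threshold, atomic units.
#' @return list of class `nci_classification`: per-category `counts`,
#'   `indices` (grid storage order), `centroids` (Angstrom, NA when empty),
#'   plus `n_retained`, `s_max`, `t`.
#' @export
classify_nci <- function(grid, s_max = 0.5, t = 0.01) {
  if (s_max <= 0 || t <= 0) stop("thresholds must be positive")
  keep <- which(grid$s < s_max)
  if (length(keep) == 0L)
    warning("no grid points retained below s_max; empty classification")
  sr <- grid$signed_rho[keep]
  idx <- list(attractive = keep[sr < -t],
              vdw = keep[abs(sr) <= t],
              repulsive = keep[sr > t])
  pts <- grid_points(grid$geometry)
  centroids <- lapply(idx, function(i)
    if (length(i)) colMeans(pts[i, , drop = FALSE]) else rep(NA_real_, 3))
  structure(list(counts = vapply(idx, length, 1L), indices = idx,
                 centroids = centroids, n_retained = length(keep),
                 s_max = s_max, t = t),
            class = "nci_classification")
}

#' @export
print.nci_classification <- function(x, ...) {
  cat(sprintf("NCI classification (s < %.2f, t = %.3g a.u.): %d points retained\n",
              x$s_max, x$t, x$n_retained))
  cat(sprintf("  attractive %d | van der Waals %d | repulsive %d\n",
              x$counts[["attractive"]], x$counts[["vdw"]],
              x$counts[["repulsive"]]))
  invisible(x)
}

#' Interfacial NCI analysis around a ligand
#'
#' Builds a grid over the ligand bounding box padded by `margin` (default 3
#' Angstrom, the conventional contact shell), evaluates promolecular fields
#' for the whole complex on it, and classifies the retained low-gradient
#' points. Use [write_grid()] on the `signed_rho` and `s` fields to export
#' the conventional cube-file pair for isosurface coloring.
#'
#' @param complex a `mol_structure` containing pocket and ligand.
#' @param ligand ligand atom selection.
#' @param margin box padding, Angstrom.
#' @param spacing grid step, Angstrom.
#' @param model a `proatom_model`.
#' @param s_max,t classification thresholds (see [classify_nci()]).
#' @return list with `grid` (an `nci_grid`) and `classification`.
#' @export
interfacial_nci <- function(complex, ligand, margin = 3.0, spacing = 0.15,
                            model = default_proatom_model(),
                            s_max = 0.5, t = 0.01) {
  lig <- resolve_selection(complex, ligand)
  if (length(lig) == 0L) stop("empty ligand selection")
  lx <- complex$xyz[lig, , drop = FALSE]
  g <- grid_from_box(apply(lx, 2, min) - margin, apply(lx, 2, max) + margin,
                     spacing)
  ng <- promolecular_fields(complex, g, model)
  list(grid = ng, classification = classify_nci(ng, s_max = s_max, t = t))
}

#' Extract one NCI field as a value-carrying volumetric grid
#'
#' @param grid an `nci_grid`.
#' @param field one of "rho", "s", "signed_rho", "lambda2".
#' @return A `volumetric_grid` suitable for [write_grid()].
#' @export
nci_field_grid <- function(grid, field = c("signed_rho", "s", "rho", "lambda2")) {
  field <- match.arg(field)
  g <- grid$geometry
  volumetric_grid(g$origin, g$axes, g$shape, grid[[field]])
}
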