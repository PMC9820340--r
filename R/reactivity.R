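## Conceptual-DFT global reactivity descriptors.
##
## All descriptors derive from the frontier orbital energies through Koopmans'
## theorem: ionization potential I = -eps_HOMO, electron affinity
## A = -eps_LUMO. The electrodonating and electroaccepting powers follow the
## standard quadratic-interpolation definitions,
##   omega^- = (3I + A)^2 / (16 (I - A)),
##   omega^+ = (I + 3A)^2 / (16 (I - A)),
## so that omega^- - omega^+ = chi holds exactly. Everything is in eV.

DESCRIPTOR_KEYS <- c("gap", "chi", "eta", "omega",
                     "omega_minus", "omega_plus", "net_electrophilicity")

#' Global reactivity descriptors from frontier orbital energies
#'
#' Computes, per compound: the HOMO-LUMO gap, electronegativity (chi), global
#' hardness (eta), electrophilicity (omega = chi^2 / 2 eta), electrodonating
#' power (omega^-), electroaccepting power (omega^+) and net electrophilicity
#' (their sum). A degenerate gap (eps_lumo == eps_homo) is rejected because
#' omega and the charge-transfer powers divide by the hardness; eps_lumo <
#' eps_homo is a domain error.
#'
#' @param orb an `orbital_energies` data.frame (see [read_orbital_table()]),
#'   or any data.frame with columns `compound`, `eps_homo`, `eps_lumo` (eV).
#' @return data.frame of class `reactivity_profile`: the inputs plus the
#'   seven descriptor columns, all in eV at full floating precision.
#' @examples
#' reactivity_profile(data.frame(compound = "TNT",
#'                               eps_homo = -9.0, eps_lumo = -3.5))
#' @export
reactivity_profile <- function(orb) {
  eh <- orb$eps_homo
  el <- orb$eps_lumo
  if (any(el < eh)) {
    bad <- which(el < eh)[1L]
    stop(sprintf("'%s': eps_lumo < eps_homo is outside the descriptor domain",
                 orb$compound[bad]))
  }
  if (any(el == eh)) {
    bad <- which(el == eh)[1L]
    stop(sprintf("'%s': degenerate gap (eps_lumo == eps_homo); hardness is zero",
                 orb$compound[bad]))
  }
  I <- -eh
  A <- -el
  gap <- el - eh
  chi <- (I + A) / 2
  eta <- (I - A) / 2
  omega <- chi^2 / (2 * eta)
  omega_minus <- (3 * I + A)^2 / (16 * (I - A))
  omega_plus <- (I + 3 * A)^2 / (16 * (I - A))
  out <- data.frame(
    compound = orb$compound, eps_homo = eh, eps_lumo = el,
    gap = gap, chi = chi, eta = eta, omega = omega,
    omega_minus = omega_minus, omega_plus = omega_plus,
    net_electrophilicity = omega_minus + omega_plus,
    stringsAsFactors = FALSE
  )
  class(out) <- c("reactivity_profile", "data.frame")
  out
}

## Decimal truncation toward zero with a 1e-9 guard so that values sitting a
## few ulp below an exact decimal (e.g. 9.6 - 3.7 = 5.8999999999999995) are
## treated as exact.
truncate_decimal <- function(x, decimals) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 1e-9) / f
}

## Half-up decimal rounding with the same guard (12.649999999999999 -> 12.7).
round_half_up <- function(x, decimals) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Format a reactivity profile for display
#'
#' Renders every numeric column at a fixed number of decimals, either
#' truncated toward zero or rounded (round-half-even, the IEEE default). The
#' underlying profile is untouched. Truncation is the default because it is
#' the convention under which published one-decimal descriptor tables in this
#' area reproduce cell-for-cell from the stated orbital energies.
#'
#' @param profile a `reactivity_profile`.
#' @param decimals non-negative integer.
#' @param mode "truncate" or "round_half_even".
#' @return data.frame of character strings, same shape as the numeric part of
#'   `profile`, with the compound column first.
#' @export
format_profile <- function(profile, decimals = 1L,
                           mode = c("truncate", "round_half_even")) {
  mode <- match.arg(mode)
  if (decimals < 0L) stop("decimals must be >= 0")
  num_cols <- setdiff(names(profile), "compound")
  out <- data.frame(compound = profile$compound, stringsAsFactors = FALSE)
  for (cn in num_cols) {
    x <- profile[[cn]]
    y <- if (mode == "truncate") truncate_decimal(x, decimals)
         else round(x, decimals)
    out[[cn]] <- sprintf(paste0("%.", decimals, "f"), y)
  }
  out
}

#' Rank compounds by a descriptor, grouping ties
#'
#' Orders compounds by decreasing descriptor value and merges compounds whose
#' values differ from the leading member of a group by at most
#' `tie_tolerance` into one tie group.
#'
#' @param x a `reactivity_profile`, or a named numeric vector of values.
#' @param key one of the descriptor names (ignored when `x` is a named
#'   vector): gap, chi, eta, omega, omega_minus, omega_plus,
#'   net_electrophilicity.
#' @param tie_tolerance maximum within-group spread, eV.
#' @return list of character vectors (tie groups), in descending order of the
#'   group representative value; the `values` attribute carries the sorted
#'   values.
#' @export
rank_compounds <- function(x, key = "gap", tie_tolerance = 0) {
  if (is.data.frame(x)) {
    if (!(key %in% DESCRIPTOR_KEYS))
      stop(sprintf("unknown descriptor key '%s'; valid keys: %s",
                   key, paste(DESCRIPTOR_KEYS, collapse = ", ")))
    vals <- stats::setNames(x[[key]], x$compound)
  } else {
    vals <- x
    if (is.null(names(vals))) stop("values must be named by compound")
  }
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  groups <- list()
  rep_val <- NULL
  for (i in seq_along(vals)) {
    if (is.null(rep_val) || rep_val - vals[i] > tie_tolerance) {
      groups[[length(groups) + 1L]] <- names(vals)[i]
      rep_val <- vals[i]
    } else {
      groups[[length(groups)]] <- c(groups[[length(groups)]], names(vals)[i])
    }
  }
  attr(groups, "values") <- vals
  groups
}

#' Packaged frontier-orbital energies for the seven nitroaromatic substrates
#'
#' Returns the (eps_HOMO, eps_LUMO) pairs (eV, PBE0-D3/Def2-TZVP level) for
#' TNT, DN6, DN4, 4AD, 2AD, TNB and NBZ, shipped as a delimited fixture in
#' `extdata/frontier_orbitals.csv`.
#'
#' @return An `orbital_energies` data.frame with seven rows.
#' @export
nitroaromatic_orbitals <- function() {
  read_orbital_table(system.file("extdata", "frontier_orbitals.csv",
                                 package = "flavoreact", mustWork = TRUE))
}
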