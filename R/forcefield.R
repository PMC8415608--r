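#' Short-range hydrophobicity-scaled pair energy
#'
#' The Ashbaugh-Hatch form used by the residue-level model: inside the
#' Lennard-Jones minimum (at distance 2^(1/6) sigma_ij) the full 12-6 potential
#' shifted up by `(1 - lambda_ij) epsilon`, outside it the 12-6 potential
#' scaled by `lambda_ij`. For the HPS pair model `lambda_ij` and `sigma_ij`
#' are arithmetic means of the per-residue values and the well depth is the
#' global `epsilon`; for the KH pair model the pair-energy matrix sets a
#' pair-specific well depth and a binary attractive/repulsive `lambda`.
#' With `shifted = TRUE` (the engine's convention) the outer-branch value at
#' the cutoff is subtracted so the energy goes continuously to zero there,
#' and the function returns 0 beyond the cutoff.
#'
#' @param r Distance(s) in Angstrom; must be positive.
#' @param i,j One-letter residue codes.
#' @param table A [param_table()].
#' @param shifted Apply the cutoff shift (default `TRUE`).
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
pair_energy_short <- function(r, i, j, table = default_param_table(),
                              shifted = TRUE) {
  stopifnot(all(r > 0))
  pc <- pair_coefficients(table)
  if (!i %in% pc$codes || !j %in% pc$codes)
    stop("unknown residue code(s): ", paste(setdiff(c(i, j), pc$codes),
                                            collapse = ", "))
  eps <- pc$eps[i, j]; lam <- pc$lam[i, j]; sig <- pc$sig[i, j]
  rc <- table$globals$lj_cutoff
  lj <- function(x) 4 * eps * ((sig / x)^12 - (sig / x)^6)
  rmin <- 2^(1 / 6) * sig
  u <- ifelse(r <= rmin, lj(r) + (1 - lam) * eps, lam * lj(r))
  if (shifted) {
    u <- u - lam * lj(rc)
    u[r >= rc] <- 0
  }
  u
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' Yukawa-screened Coulomb interaction
#' `U(r) = kc * q_i q_j exp(-r / kappa) / r`, with `kc = 332.06371 /
#' dielectric` kcal A/mol and `kappa` the Debye screening length from the
#' parameter table's globals. Zero whenever either charge is zero.
#'
#' @param r Distance(s) in Angstrom; positive.
#' @param q_i,q_j Formal charges in units of e.
#' @param table A [param_table()].
#' @param shifted Subtract the value at the Coulomb cutoff and truncate
#'   beyond it (the engine's convention); default `FALSE` gives the bare
#'   closed form.
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
pair_energy_dh <- function(r, q_i, q_j, table = default_param_table(),
                           shifted = FALSE) {
  stopifnot(all(r > 0))
  g <- table$globals
  kc <- .coulomb_k / g$dielectric
  u <- kc * q_i * q_j * exp(-r / g$debye_length) / r
  if (shifted) {
    rc <- g$coul_cutoff
    u <- u - kc * q_i * q_j * exp(-rc / g$debye_length) / rc
    u[r >= rc] <- 0
  }
  u
}

#' Total energies and forces of a configuration
#'
#' Evaluates the full force field (short-range pair term, screened
#' electrostatics, harmonic bonds) for a periodic configuration under the
#' minimum-image convention. Directly bonded `(i, i+1)` pairs are excluded
#' from the nonbonded sums.
#'
#' @param config A configuration from [build_slab()] or relatives.
#' @param table A [param_table()].
#' @return A list with `breakdown`, a one-row tibble of per-bead energies
#'   (`e_lj`, `e_coul`, `e_bond`, kcal/mol per bead, plus system totals),
#'   and `forces`, an `n x 3` matrix in kcal/mol/A.
#' @export
system_energy_forces <- function(config, table = default_param_table()) {
  pc <- pair_coefficients(table)
  check_box(config$box, table, has_charges = any(pc$q[config$type] != 0))
  type <- match(config$type, pc$codes) - 1L
  if (anyNA(type)) stop("configuration contains bead types absent from table")
  out <- cpp_energy_forces(config$positions, config$box, type,
                           config$bonds - 1L, pc$eps, pc$lam, pc$sig,
                           unname(pc$q), engine_globals(table))
  n <- nrow(config$positions)
  breakdown <- tibble::tibble(
    e_lj = out$e_lj / n, e_coul = out$e_coul / n, e_bond = out$e_bond / n,
    total_lj = out$e_lj, total_coul = out$e_coul, total_bond = out$e_bond,
    n_beads = n)
  list(breakdown = breakdown, forces = out$forces)
}

# the binding cutoff is the largest one that can act: electrostatics only
# matter when charged beads are present
check_box <- function(box, table, has_charges = TRUE) {
  rc <- if (has_charges)
    max(table$globals$lj_cutoff, table$globals$coul_cutoff)
  else table$globals$lj_cutoff
  if (any(box < 2 * rc))
    stop("box edge smaller than twice the nonbonded cutoff (", 2 * rc, " A)")
  invisible(box)
}
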