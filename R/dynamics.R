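#' Run Langevin dynamics
#'
#' Integrates the system with a BAOAB-splitting Langevin integrator at
#' constant volume and temperature. Velocities are drawn from the
#' Maxwell-Boltzmann distribution at the start; a single integer seed fully
#' determines the stochastic stream, so identical inputs reproduce
#' bit-identical trajectories and thermodynamic logs. With `friction = 0`
#' the O-step is skipped and the scheme reduces to velocity Verlet
#' (zero-noise limit, used for energy-conservation checks).
#'
#' The timestep must stay below the stability bound of the stiffest degree
#' of freedom; with the shipped bond constant and bead masses, 10 fs is
#' conservative. If any force component exceeds `fmax` the run aborts with
#' an instability error naming the step and bead.
#'
#' @param config A `cg_configuration`.
#' @param spec A [system_spec()] (temperature, timestep, friction, step
#'   counts, sampling interval, seed).
#' @param table A [param_table()].
#' @param skin Neighbour-list skin distance in Angstrom; the list is rebuilt
#'   whenever any bead has moved more than half the skin.
#' @param fmax Instability threshold on any force component (kcal/mol/A).
#' @return A `cg_trajectory`: unwrapped frames (`n x 3 x n_frames` array),
#'   a thermodynamic log tibble (`time_fs`, `temperature`, `kinetic`,
#'   `e_lj`, `e_coul`, `e_bond`), the box, topology and final phase-space
#'   state.
#' @export
run_langevin <- function(config, spec, table = default_param_table(),
                         skin = 3, fmax = 1e4) {
  pc <- pair_coefficients(table)
  check_box(config$box, table, has_charges = any(pc$q[config$type] != 0))
  type <- match(config$type, pc$codes) - 1L
  if (anyNA(type)) stop("configuration contains bead types absent from table")
  mass_bead <- unname(pc$mass[config$type])
  out <- cpp_run_langevin(
    config$positions, config$box, type, config$bonds - 1L, pc$eps, pc$lam,
    pc$sig, unname(pc$q), mass_bead, engine_globals(table),
    spec$timestep, spec$temperature, spec$friction, spec$n_equil,
    spec$n_prod, spec$sample_interval, spec$seed, skin, fmax)
  nf <- out$n_frames
  frames <- out$frames
  if (nf < dim(frames)[3]) frames <- frames[, , seq_len(nf), drop = FALSE]
  log <- tibble::tibble(time_fs = out$time_fs, temperature = out$temperature,
                        kinetic = out$kinetic, e_lj = out$e_lj,
                        e_coul = out$e_coul, e_bond = out$e_bond)
  structure(list(frames = frames, log = log, box = config$box,
                 topology = list(type = config$type,
                                 chain_id = config$chain_id,
                                 bonds = config$bonds,
                                 sequences = config$sequences),
                 spec = spec,
                 final = list(positions = out$positions,
                              velocities = out$velocities)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", dim(x$frames)[1], " beads, ", dim(x$frames)[3],
      " frames, T = ", x$spec$temperature, " K\n", sep = "")
  invisible(x)
}

#' Mean-squared displacement and diffusion coefficient
#'
#' `mean_squared_displacement()` averages the squared displacement over all
#' beads and sliding time origins of the (unwrapped) trajectory.
#' `diffusion_coefficient()` applies the Einstein relation, fitting
#' `MSD = 6 D t` over a lag window well away from both the ballistic regime
#' and the poorly averaged longest lags.
#'
#' @param traj A `cg_trajectory` (frames are stored unwrapped).
#' @param max_lag_frac Largest lag considered, as a fraction of the
#'   trajectory length.
#' @return A tibble with `lag_fs` and `msd` (A^2); the lag-0 entry is 0 by
#'   construction.
#' @export
mean_squared_displacement <- function(traj, max_lag_frac = 0.5) {
  nf <- dim(traj$frames)[3]
  if (nf < 4) stop("insufficient data: need at least 4 frames for an MSD")
  dt_frame <- traj$spec$timestep * traj$spec$sample_interval
  max_lag <- max(2L, floor(nf * max_lag_frac))
  lags <- 0:max_lag
  msd <- vapply(lags, function(l) {
    if (l == 0) return(0)
    orig <- seq_len(nf - l)
    d <- traj$frames[, , orig + l, drop = FALSE] -
      traj$frames[, , orig, drop = FALSE]
    mean(apply(d^2, c(1, 3), sum))
  }, 0)
  tibble::tibble(lag_fs = lags * dt_frame, msd = msd)
}

#' @rdname mean_squared_displacement
#' @param msd Tibble from `mean_squared_displacement()`.
#' @param fit_window Fractions of the largest lag bounding the linear fit.
#' @return `diffusion_coefficient()`: D in A^2/ns.
#' @export
diffusion_coefficient <- function(msd, fit_window = c(0.2, 0.8)) {
  lo <- fit_window[1] * max(msd$lag_fs)
  hi <- fit_window[2] * max(msd$lag_fs)
  sel <- msd$lag_fs >= lo & msd$lag_fs <= hi
  if (sum(sel) < 2) stop("insufficient data in the MSD fit window")
  slope <- coef(lm(msd ~ lag_fs, data = msd[sel, ]))[["lag_fs"]]
  (slope / 6) * 1e6    # A^2/fs -> A^2/ns
}
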