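#' Fitness backends
#'
#' A fitness backend maps a sequence to the coexisting densities
#' `c(rho_l, rho_v)` at the evaluation temperature. Two families are
#' provided: fast deterministic surrogates for exercising the
#' genetic-algorithm machinery, and the production molecular-dynamics
#' backend that runs a slab direct-coexistence simulation per candidate.
#'
#' `backend_surrogate_lambda()` returns the sequence's mean hydrophobicity
#' as the liquid density (vapour 0): a monotone stand-in under which
#' evolution must drive the mean `lambda` upward.
#' `backend_surrogate_table()` looks widths up in a user-supplied table
#' (errors on unknown sequences), useful for scripted toy scenarios.
#'
#' @param table A [param_table()].
#' @return A `function(sequence) -> c(rho_l, rho_v)`.
#' @export
backend_surrogate_lambda <- function(table = default_param_table()) {
  force(table)
  function(sequence) {
    lam <- mean(residue_params(table, sequence)$lambda)
    c(rho_l = lam, rho_v = 0)
  }
}

#' @rdname backend_surrogate_lambda
#' @param widths Named numeric vector mapping sequence strings to
#'   phase-diagram widths.
#' @export
backend_surrogate_table <- function(widths) {
  force(widths)
  function(sequence) {
    if (!sequence %in% names(widths))
      stop("no width tabulated for sequence ", sequence)
    c(rho_l = unname(widths[[sequence]]), rho_v = 0)
  }
}

#' @rdname backend_surrogate_lambda
#'
#' @details `backend_md_width()` builds a slab of `n_chains` copies of the
#' candidate, runs Langevin dynamics at the evaluation temperature, and
#' reads the coexisting densities off the 25-bin density profile. Each
#' evaluation derives its private RNG seed from the candidate sequence and
#' the backend seed, so results are independent of evaluation order (the
#' contract a master-slave parallel evaluation relies on). A candidate
#' whose profile shows no dense/dilute contrast returns zero width.
#'
#' @param n_chains Chains per evaluation.
#' @param temperature Evaluation temperature (K), fixed and sub-critical.
#' @param n_equil,n_prod,sample_interval,timestep,friction Passed to
#'   [system_spec()].
#' @param seed Backend seed combined with the per-sequence hash.
#' @param n_bins Bins for the density profile.
#' @export
backend_md_width <- function(table = default_param_table(), n_chains = 20,
                             temperature = 200, n_equil = 2000,
                             n_prod = 3000, sample_interval = 100,
                             timestep = 10, friction = 1, seed = 1,
                             n_bins = 25) {
  force(table)
  function(sequence) {
    run_seed <- as.integer((as.numeric(seed) + seq_hash(sequence)) %%
                             2147483591)
    spec <- system_spec(sequence, n_chains = n_chains,
                        temperature = temperature, timestep = timestep,
                        friction = friction, n_equil = n_equil,
                        n_prod = n_prod, sample_interval = sample_interval,
                        seed = run_seed, table = table)
    config <- build_slab(spec, table)
    traj <- run_langevin(config, spec, table)
    prof <- density_profile(traj, n_bins = n_bins, table = table)
    pt <- fit_coexistence(prof)
    if (!pt$converged) return(c(rho_l = 0, rho_v = 0))
    c(rho_l = pt$rho_l, rho_v = pt$rho_v)
  }
}
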