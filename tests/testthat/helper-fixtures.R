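# Shared fixtures: toy parameter tables, small configurations, a cached toy
# slab run, and an independent brute-force SCD oracle.

default_tab <- idpevolve::default_param_table()

# toy table with short cutoffs so small boxes are legal
toy_table <- function(epsilon = 0.2, lj_cutoff = 12, coul_cutoff = 12,
                      lambda_all = NULL) {
  tab <- default_tab
  tab$globals$epsilon <- epsilon
  tab$globals$lj_cutoff <- lj_cutoff
  tab$globals$coul_cutoff <- coul_cutoff
  if (!is.null(lambda_all)) tab$residues$lambda <- lambda_all
  tab
}

# ideal-gas table: no pair interactions at all
ideal_table <- function(...) {
  tab <- toy_table(epsilon = 0, ...)
  tab$residues$charge <- rep(0L, nrow(tab$residues))
  tab
}

# hand-made configuration (bypasses packing) for force/energy checks
manual_config <- function(positions, box, type, chain_id = NULL,
                          bonds = NULL, sequences = NULL) {
  n <- nrow(positions)
  structure(list(
    positions = positions, box = box, type = type,
    chain_id = chain_id %||% rep(1L, n),
    bonds = bonds %||% matrix(integer(), 0, 2),
    sequences = sequences %||% paste(type, collapse = "")),
    class = "cg_configuration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic trajectory wrapper around a list of frames (for analysis tests)
manual_traj <- function(frames, box, type, bonds = NULL, chain_id = NULL,
                        temperature = 300, timestep = 10,
                        sample_interval = 100) {
  n <- nrow(frames[[1]])
  arr <- array(unlist(frames), dim = c(n, 3, length(frames)))
  structure(list(
    frames = arr,
    log = tibble::tibble(time_fs = seq_along(frames) * timestep *
                           sample_interval),
    box = box,
    topology = list(type = type, chain_id = chain_id %||% seq_len(n),
                    bonds = bonds %||% matrix(integer(), 0, 2),
                    sequences = type),
    spec = list(temperature = temperature, timestep = timestep,
                sample_interval = sample_interval)),
    class = "cg_trajectory")
}

# independent SCD oracle: literal row-by-row double sum
scd_brute <- function(sequence, table = default_tab) {
  q <- idpevolve::residue_params(table, sequence)$charge
  n <- length(q)
  if (n < 2) return(0)
  total <- 0
  for (m in 2:n) {
    nn <- 1:(m - 1)
    total <- total + sum(q[m] * q[nn] * sqrt(m - nn))
  }
  total / n
}

# one short toy homopolymer slab run, cached across tests in this session
.toy_cache <- new.env(parent = emptyenv())
toy_slab_traj <- function() {
  if (!is.null(.toy_cache$traj)) return(.toy_cache$traj)
  tab <- toy_table()
  seqA <- strrep("A", 20)
  spec <- idpevolve::system_spec(seqA, n_chains = 12, box = c(42, 42, 168),
                                 temperature = 250, n_equil = 1500,
                                 n_prod = 3000, sample_interval = 100,
                                 seed = 11, table = tab)
  cfg <- idpevolve::build_slab(spec, tab)
  .toy_cache$traj <- idpevolve::run_langevin(cfg, spec, tab)
  .toy_cache$table <- tab
  .toy_cache$traj
}
toy_slab_table <- function() { toy_slab_traj(); .toy_cache$table }
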