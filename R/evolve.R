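#' Genetic-algorithm configuration
#'
#' Defaults follow the published campaign settings for this model family:
#' population size 20, 8 parents per round chosen by tournaments of 5, and
#' a per-position mutation rate of 0.01.
#'
#' @param n_pop Population size `N`.
#' @param n_parents Parents selected per round (must be even).
#' @param n_tournament Tournament size; at most `n_pop`.
#' @param mutation_rate Per-position mutation probability in `[0, 1]`.
#'   Replacements are drawn uniformly from all 20 amino acids, so the
#'   effective change probability is `rate * 19/20`.
#' @param rounds Number of evolution rounds.
#' @param direction `"increase"` to widen the phase diagram, `"decrease"`
#'   to narrow it (fitness becomes the reciprocal of the width ratio).
#' @param seed Master seed; spawns independent substreams for initial
#'   mutations, tournaments, parent pairing, crossover points and child
#'   mutations.
#' @return A `ga_config` list.
#' @export
ga_config <- function(n_pop = 20, n_parents = 8, n_tournament = 5,
                      mutation_rate = 0.01, rounds = 20,
                      direction = c("increase", "decrease"), seed = 1) {
  direction <- match.arg(direction)
  stopifnot(n_parents %% 2 == 0, n_tournament <= n_pop,
            mutation_rate >= 0, mutation_rate <= 1, n_pop >= 2)
  structure(list(n_pop = as.integer(n_pop),
                 n_parents = as.integer(n_parents),
                 n_tournament = as.integer(n_tournament),
                 mutation_rate = mutation_rate, rounds = as.integer(rounds),
                 direction = direction, seed = as.integer(seed)),
            class = "ga_config")
}

#' Phase-diagram-width fitness
#'
#' The fitness of a candidate sequence is the width of its phase diagram at
#' the evaluation temperature, relative to the wild type:
#' `f(x) = (rho_l(x) - rho_v(x)) / (rho_l(WT) - rho_v(WT))`. For runs that
#' aim to narrow the phase diagram the reciprocal is used. Candidates whose
#' coexistence fit finds no dense phase (vanishing width) are assigned
#' fitness 0 and flagged, so evolution continues past them.
#'
#' @param sequence Candidate sequence string.
#' @param reference_width Denominator `rho_l(WT) - rho_v(WT)`.
#' @param backend A fitness backend: `function(sequence)` returning a named
#'   vector with `rho_l` and `rho_v` (see [backend_surrogate_lambda()] and
#'   [backend_md_width()]).
#' @param direction `"increase"` or `"decrease"`.
#' @param width_floor Widths at or below this value count as
#'   non-phase-separating.
#' @return One-row tibble: `fitness`, `rho_l`, `rho_v`, `width`,
#'   `reference_width`, `separated` flag.
#' @export
ga_fitness <- function(sequence, reference_width, backend,
                       direction = "increase", width_floor = 1e-12) {
  dens <- tryCatch(backend(sequence), error = function(e) {
    warning("fitness backend failed (", conditionMessage(e),
            "); assigning fitness 0")
    c(rho_l = NA_real_, rho_v = NA_real_)
  })
  width <- unname(dens[["rho_l"]] - dens[["rho_v"]])
  separated <- is.finite(width) && width > width_floor
  f <- if (!separated) 0
  else if (direction == "decrease") reference_width / width
  else width / reference_width
  tibble::tibble(fitness = f, rho_l = unname(dens[["rho_l"]]),
                 rho_v = unname(dens[["rho_v"]]), width = width,
                 reference_width = reference_width, separated = separated)
}

#' Sequence mutation
#'
#' Each position is independently resampled with probability `rate`; the
#' replacement is drawn uniformly from the 20 canonical amino acids, so a
#' resampled position keeps its residue with probability 1/20.
#'
#' @param sequence Sequence string.
#' @param rate Per-position mutation probability.
#' @return List with `sequence` (mutated string) and `attempted` (1-based
#'   positions where a mutation was attempted).
#' @export
mutate_sequence <- function(sequence, rate) {
  stopifnot(rate >= 0, rate <= 1)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit))
    chars[hit] <- sample(.aa_codes, length(hit), replace = TRUE)
  list(sequence = paste(chars, collapse = ""), attempted = hit)
}

#' Tournament selection of parents
#'
#' Runs `n_parents` tournaments, each a uniformly drawn subset of
#' `n_tournament` population members (without replacement within a
#' tournament); the fittest member of each tournament becomes a parent.
#' The same member may parent several times. Fitness ties are broken by
#' lowest member index.
#'
#' @param fitness Numeric vector of evaluated fitness values.
#' @param cfg A [ga_config()].
#' @return Integer vector of `n_parents` member indices.
#' @export
select_parents <- function(fitness, cfg) {
  if (anyNA(fitness)) stop("all fitness values must be evaluated")
  n <- length(fitness)
  vapply(seq_len(cfg$n_parents), function(i) {
    entrants <- sample.int(n, cfg$n_tournament)
    entrants[which.max(fitness[entrants])]
  }, 0L)
}

#' Single-point crossover
#'
#' Swaps the tails of two equal-length sequences after a position
#' `k in [1, n]`: positions `<= k` are kept, positions `> k` are exchanged.
#' `k = n` returns the parents unchanged.
#'
#' @param a,b Parent sequence strings of equal length.
#' @param k Crossover point; drawn uniformly from `1:n` when `NULL`.
#' @return List with `children` (character vector of length 2) and `k`.
#' @export
crossover <- function(a, b, k = NULL) {
  n <- nchar(a)
  if (nchar(b) != n) stop("crossover requires equal-length sequences")
  if (is.null(k)) k <- sample.int(n, 1)
  stopifnot(k >= 1, k <= n)
  if (k == n) return(list(children = c(a, b), k = k))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  tail_idx <- (k + 1):n
  tmp <- ca[tail_idx]
  ca[tail_idx] <- cb[tail_idx]
  cb[tail_idx] <- tmp
  list(children = c(paste(ca, collapse = ""), paste(cb, collapse = "")),
       k = k)
}

#' Weak-population replacement
#'
#' Greedy replacement: each child in turn replaces the current weakest
#' member if and only if it is strictly fitter. A previously inserted child
#' can itself become the weakest and be displaced. Population size is
#' unchanged. Ties for weakest are broken by lowest index.
#'
#' @param population Tibble with at least `sequence` and `fitness` columns.
#' @param children Tibble with `sequence` and `fitness` (evaluated).
#' @return The updated population tibble.
#' @export
weak_replace <- function(population, children) {
  pop <- population
  for (i in seq_len(nrow(children))) {
    weakest <- which.min(pop$fitness)     # which.min takes the first minimum
    if (children$fitness[i] > pop$fitness[weakest])
      pop[weakest, ] <- children[i, names(pop)]
  }
  pop
}

#' Run the genetic algorithm
#'
#' Evolves a population of sequences toward a wider (or narrower) phase
#' diagram. The initial population consists of `n_pop` mutated copies of
#' the wild type. Each round: evaluate fitness, select parents by
#' tournament, pair them at random, apply single-point crossover, mutate
#' the children at the same rate, evaluate them and insert them by
#' weak-population replacement. The reference width in the fitness
#' denominator is the wild type's, evaluated once with the same backend.
#'
#' Fitness evaluations within a round are order-independent: any randomness
#' a backend needs must be derived from the candidate sequence itself (as
#' [backend_md_width()] does), never drawn from a shared stream.
#'
#' @param wt Wild-type sequence string.
#' @param cfg A [ga_config()].
#' @param backend Fitness backend, `function(sequence) -> c(rho_l, rho_v)`.
#' @return A `ga_history` object: `rounds` (per-round, per-member listing),
#'   `summary` (mean/max fitness and diversity per round), `lineage`,
#'   `attempted` (per-position mutation-attempt counts), `config`,
#'   `reference_width`.
#' @export
run_ga <- function(wt, cfg, backend) {
  run_ga_impl(wt, cfg, backend, dummy = FALSE)
}

#' Dummy control: the genetic algorithm without selection pressure
#'
#' Identical to [run_ga()] except that the driving force is removed:
#' parents are chosen uniformly at random (ignoring fitness) and each child
#' replaces a uniformly chosen member unconditionally. All mutation and
#' crossover machinery is retained, so diversity evolves comparably; the
#' mean fitness trajectory should be statistically flat.
#'
#' @inheritParams run_ga
#' @export
run_dummy_ga <- function(wt, cfg, backend) {
  run_ga_impl(wt, cfg, backend, dummy = TRUE)
}

run_ga_impl <- function(wt, cfg, backend, dummy) {
  n <- nchar(wt)
  streams <- new_rng_streams(cfg$seed,
                             c("init", "tournament", "pairing", "crossover",
                               "child_mutation", "dummy_replace"))
  attempts <- integer(n)
  ref <- ga_fitness(wt, 1, backend, direction = "increase")
  if (!ref$separated)
    stop("wild type does not phase-separate under this backend; ",
         "no reference width")
  ref_width <- ref$width

  eval_fitness <- function(seqs) {
    purrr::map_dfr(seqs, ga_fitness, reference_width = ref_width,
                   backend = backend, direction = cfg$direction)
  }

  init <- stream_do(streams, "init", {
    purrr::map(seq_len(cfg$n_pop), function(i) mutate_sequence(wt,
                                                cfg$mutation_rate))
  })
  for (m in init) attempts[m$attempted] <- attempts[m$attempted] + 1L
  pop <- tibble::tibble(id = seq_len(cfg$n_pop),
                        sequence = purrr::map_chr(init, "sequence"))
  pop <- dplyr::bind_cols(pop, eval_fitness(pop$sequence))

  next_id <- cfg$n_pop + 1L
  lineage <- list()
  record_round <- function(t) {
    dplyr::mutate(pop, round = t, member = dplyr::row_number(),
                  .before = 1)
  }
  rounds <- list(record_round(0L))

  t <- 0L
  while (t < cfg$rounds) {
    t <- t + 1L
    parent_idx <- if (dummy)
      stream_do(streams, "tournament",
                sample.int(cfg$n_pop, cfg$n_parents, replace = TRUE))
    else
      stream_do(streams, "tournament", select_parents(pop$fitness, cfg))
    pairing <- stream_do(streams, "pairing", sample(seq_along(parent_idx)))
    paired <- matrix(parent_idx[pairing], ncol = 2, byrow = TRUE)

    children <- character(0)
    child_parents <- list()
    for (p in seq_len(nrow(paired))) {
      k <- stream_do(streams, "crossover",
                     sample.int(nchar(wt), 1))
      cr <- crossover(pop$sequence[paired[p, 1]],
                      pop$sequence[paired[p, 2]], k = k)
      children <- c(children, cr$children)
      child_parents <- c(child_parents,
                         list(c(paired[p, ], k), c(paired[p, 2:1], k)))
    }
    mutated <- stream_do(streams, "child_mutation",
                         purrr::map(children, mutate_sequence,
                                    rate = cfg$mutation_rate))
    for (m in mutated) attempts[m$attempted] <- attempts[m$attempted] + 1L
    child_seqs <- purrr::map_chr(mutated, "sequence")
    child_tbl <- tibble::tibble(id = next_id + seq_along(child_seqs) - 1L,
                                sequence = child_seqs)
    next_id <- next_id + length(child_seqs)
    child_tbl <- dplyr::bind_cols(child_tbl, eval_fitness(child_tbl$sequence))
    lineage[[t]] <- tibble::tibble(
      round = t, child_id = child_tbl$id,
      parent_a = pop$id[vapply(child_parents, `[`, 0, 1)],
      parent_b = pop$id[vapply(child_parents, `[`, 0, 2)],
      crossover_k = vapply(child_parents, `[`, 0, 3))

    if (dummy) {
      targets <- stream_do(streams, "dummy_replace",
                           sample.int(cfg$n_pop, nrow(child_tbl),
                                      replace = TRUE))
      for (i in seq_len(nrow(child_tbl)))
        pop[targets[i], ] <- child_tbl[i, names(pop)]
    } else {
      pop <- weak_replace(pop, child_tbl)
    }
    rounds[[t + 1L]] <- record_round(t)
  }

  rounds_tbl <- dplyr::bind_rows(rounds)
  summary_tbl <- rounds_tbl |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(mean_fitness = mean(.data$fitness),
                     max_fitness = max(.data$fitness),
                     diversity = dplyr::n_distinct(.data$sequence),
                     .groups = "drop")
  structure(list(rounds = rounds_tbl, summary = summary_tbl,
                 lineage = dplyr::bind_rows(lineage),
                 attempted = tibble::tibble(position = seq_len(n),
                                            attempts = attempts),
                 config = cfg, wild_type = wt, reference_width = ref_width,
                 dummy = dummy),
            class = "ga_history")
}

#' @export
print.ga_history <- function(x, ...) {
  last <- dplyr::filter(x$summary, .data$round == max(.data$round))
  cat("<ga_history> ", max(x$summary$round), " rounds, N = ",
      x$config$n_pop, if (x$dummy) " (dummy control)", "\n", sep = "")
  cat("  final mean fitness ", signif(last$mean_fitness, 4), ", max ",
      signif(last$max_fitness, 4), ", diversity ", last$diversity, "/",
      x$config$n_pop, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ga_history <- function(x, ...) x$rounds

#' @export
glance.ga_history <- function(x, ...) {
  first <- dplyr::filter(x$summary, .data$round == 0)
  last <- dplyr::filter(x$summary, .data$round == max(.data$round))
  tibble::tibble(
    rounds = max(x$summary$round),
    n_pop = x$config$n_pop,
    initial_mean_fitness = first$mean_fitness,
    final_mean_fitness = last$mean_fitness,
    final_max_fitness = last$max_fitness,
    final_diversity = last$diversity,
    coverage = mean(x$attempted$attempts > 0))
}
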