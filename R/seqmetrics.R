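#' Sequence charge decoration (SCD)
#'
#' The distance-weighted charge-pair statistic
#' `Q_SCD = (1/N) * sum_{m=2}^{N} sum_{n=1}^{m-1} q_m q_n sqrt(m - n)`,
#' where `q_i` is the formal charge of residue `i` and `N` the sequence
#' length. More negative values indicate alternating/well-mixed charge
#' patterns; SCD anti-correlates with the critical solution temperature of
#' charge-rich IDRs. Sequences with fewer than two charged residues score
#' exactly 0.
#'
#' @param sequence Sequence string.
#' @param table A [param_table()] supplying formal charges (histidine is
#'   neutral in the shipped table).
#' @return A one-row tibble: `q_scd`, `n`, `n_charged`.
#' @export
scd <- function(sequence, table = default_param_table()) {
  q <- residue_params(table, sequence)$charge
  n <- length(q)
  idx <- which(q != 0)
  if (length(idx) < 2)
    return(tibble::tibble(q_scd = 0, n = n, n_charged = length(idx)))
  qm <- q[idx]
  dmat <- outer(idx, idx, function(a, b) sqrt(abs(a - b)))
  qq <- outer(qm, qm)
  val <- sum(qq[upper.tri(qq)] * dmat[upper.tri(dmat)]) / n
  tibble::tibble(q_scd = val, n = n, n_charged = length(idx))
}

#' Charge composition of a sequence
#'
#' @param sequence Sequence string.
#' @param table A [param_table()]; D/E carry -1, K/R +1, histidine neutral.
#' @return One-row tibble: `net_charge` (e), `n_charged`, `frac_charged`.
#' @export
charge_stats <- function(sequence, table = default_param_table()) {
  q <- residue_params(table, sequence)$charge
  tibble::tibble(net_charge = sum(q), n_charged = sum(q != 0),
                 frac_charged = mean(q != 0),
                 n_positive = sum(q > 0), n_negative = sum(q < 0))
}

#' Hydrophobicity and size statistics
#'
#' Mean hydrophobicity `lambda`, mean bead size `sigma` and the
#' position-resolved maps for one sequence.
#'
#' @param sequence Sequence string.
#' @param table A [param_table()].
#' @return List with `mean_lambda`, `mean_sigma` and `per_residue` (tibble
#'   `position`, `code`, `lambda`, `sigma`, `charge`).
#' @export
hydropathy_stats <- function(sequence, table = default_param_table()) {
  rp <- residue_params(table, sequence)
  list(mean_lambda = mean(rp$lambda), mean_sigma = mean(rp$sigma),
       per_residue = tibble::tibble(position = seq_len(nrow(rp)),
                                    code = rp$code, lambda = rp$lambda,
                                    sigma = rp$sigma, charge = rp$charge))
}

#' Population-averaged per-residue maps
#'
#' Aligns equal-length sequences positionally and averages `lambda`,
#' `sigma` and charge per position; `population_change_map()` subtracts the
#' wild type, giving the per-residue change map of an evolved population.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param table A [param_table()].
#' @return Tibble `position`, `lambda`, `sigma`, `charge` (population
#'   means); for the change map, `d_lambda`, `d_sigma`, `d_charge`.
#' @export
population_map <- function(sequences, table = default_param_table()) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("population averaging requires equal-length sequences")
  maps <- purrr::map(sequences, function(s)
    hydropathy_stats(s, table)$per_residue)
  tibble::tibble(
    position = seq_len(lens[1]),
    lambda = rowMeans(sapply(maps, `[[`, "lambda")),
    sigma = rowMeans(sapply(maps, `[[`, "sigma")),
    charge = rowMeans(sapply(maps, `[[`, "charge")))
}

#' @rdname population_map
#' @param wt Wild-type sequence (same length).
#' @export
population_change_map <- function(wt, sequences,
                                  table = default_param_table()) {
  ref <- population_map(wt, table)
  pop <- population_map(sequences, table)
  tibble::tibble(position = ref$position,
                 d_lambda = pop$lambda - ref$lambda,
                 d_sigma = pop$sigma - ref$sigma,
                 d_charge = pop$charge - ref$charge)
}

# circular chunk windows: positions of a length-l window starting at p (1-based)
circ_window <- function(p, l, n) ((p - 1 + seq_len(l) - 1) %% n) + 1

# do circular windows starting at p1, p2 overlap?
windows_overlap <- function(p1, p2, l, n) {
  d <- min((p2 - p1) %% n, (p1 - p2) %% n)
  d < l
}

#' Chunk shuffling
#'
#' Repeatedly exchanges two length-`l` chunks of the sequence, treating the
#' ends periodically so there is no positional bias against them. The
#' swapped chunks may contain identical residues; overall composition is
#' invariant. The number of amino-acid pairs changed is `steps * l`. With
#' `bias_fraction` set, both windows are drawn only from the top fraction
#' of all `n` contiguous (periodic) windows ranked by mean hydrophobicity,
#' re-ranked after each accepted swap. Overlapping window pairs are
#' redrawn (bounded retries) since an exchange between overlapping windows
#' is ill-defined.
#'
#' @param sequence Sequence string.
#' @param l Chunk length, `1 <= l <= n`.
#' @param steps Number of exchange steps.
#' @param bias_fraction Optional fraction (e.g. 0.3) restricting draws to
#'   the most hydrophobic windows.
#' @param backend Optional fitness backend; when supplied, the relative
#'   width is recorded after every step.
#' @param reference_width Denominator for the fitness trace (defaults to
#'   the starting sequence's own width under `backend`).
#' @param table A [param_table()] (window hydrophobicities).
#' @param max_redraw Bounded retries for overlapping/ineligible draws.
#' @return List of class `shuffle_record`: `trace` (tibble `step`,
#'   `pairs_changed`, `sequence`, `fitness`), `swaps` (tibble `step`, `p1`,
#'   `p2`), `l`, `bias_fraction`, `final`.
#' @export
chunk_shuffle <- function(sequence, l, steps, bias_fraction = NULL,
                          backend = NULL, reference_width = NULL,
                          table = default_param_table(), max_redraw = 100) {
  n <- nchar(sequence)
  stopifnot(l >= 1, l <= n)
  chars <- strsplit(sequence, "")[[1]]
  lam <- setNames(table$residues$lambda, table$residues$code)

  eval_width <- NULL
  if (!is.null(backend)) {
    if (is.null(reference_width)) {
      d0 <- backend(sequence)
      reference_width <- unname(d0[["rho_l"]] - d0[["rho_v"]])
    }
    eval_width <- function(s) {
      d <- backend(s)
      unname(d[["rho_l"]] - d[["rho_v"]]) / reference_width
    }
  }

  eligible_starts <- function(ch) {
    if (is.null(bias_fraction)) return(seq_len(n))
    lam_seq <- lam[ch]
    win_mean <- vapply(seq_len(n), function(p)
      mean(lam_seq[circ_window(p, l, n)]), 0)
    k <- max(2L, ceiling(bias_fraction * n))
    order(win_mean, decreasing = TRUE)[seq_len(k)]
  }

  swaps <- matrix(0L, steps, 2)
  trace_seq <- character(steps + 1)
  trace_fit <- rep(NA_real_, steps + 1)
  trace_seq[1] <- sequence
  if (!is.null(eval_width)) trace_fit[1] <- eval_width(sequence)

  for (s in seq_len(steps)) {
    starts <- eligible_starts(chars)
    ok <- FALSE
    for (try in seq_len(max_redraw)) {
      pq <- sample(starts, 2)
      # full-length windows always overlap as sets; their exchange is a
      # well-defined cyclic rotation, so only l < n pairs are redrawn
      if (l == n || !windows_overlap(pq[1], pq[2], l, n)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not draw non-overlapping windows after ", max_redraw,
           " tries (chunk length too large for the eligible set)")
    w1 <- circ_window(pq[1], l, n); w2 <- circ_window(pq[2], l, n)
    tmp <- chars[w1]; chars[w1] <- chars[w2]; chars[w2] <- tmp
    swaps[s, ] <- pq
    trace_seq[s + 1] <- paste(chars, collapse = "")
    if (!is.null(eval_width)) trace_fit[s + 1] <- eval_width(trace_seq[s + 1])
  }

  structure(list(
    trace = tibble::tibble(step = 0:steps, pairs_changed = (0:steps) * l,
                           sequence = trace_seq, fitness = trace_fit),
    swaps = tibble::tibble(step = seq_len(steps), p1 = swaps[, 1],
                           p2 = swaps[, 2]),
    l = l, bias_fraction = bias_fraction,
    final = trace_seq[steps + 1]), class = "shuffle_record")
}

#' Replay a logged swap list
#'
#' Applies the swaps recorded by [chunk_shuffle()] to a sequence,
#' reproducing its deterministic permutation composition.
#'
#' @param sequence Starting sequence.
#' @param swaps Tibble with `p1`, `p2` columns.
#' @param l Chunk length.
#' @return The final sequence string.
#' @export
apply_swaps <- function(sequence, swaps, l) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  for (s in seq_len(nrow(swaps))) {
    w1 <- circ_window(swaps$p1[s], l, n)
    w2 <- circ_window(swaps$p2[s], l, n)
    tmp <- chars[w1]; chars[w1] <- chars[w2]; chars[w2] <- tmp
  }
  paste(chars, collapse = "")
}

#' Glycine scanning
#'
#' Replaces successive non-overlapping chunks (default 6 residues; a final
#' shorter chunk is scanned as-is) with glycine, one variant per chunk, and
#' reports each chunk's hydrophobicity excess over glycine,
#' `delta_lambda = <lambda>_chunk - lambda(G)`. When a fitness backend is
#' supplied, each variant's relative phase-diagram width is evaluated.
#'
#' @param sequence Sequence string.
#' @param chunk_len Chunk length (default 6).
#' @param table A [param_table()].
#' @param backend Optional fitness backend.
#' @param reference_width Optional denominator for relative fitness
#'   (defaults to the unmutated sequence's width under `backend`).
#' @return A `ScanResult` tibble: `chunk`, `start`, `end`, `delta_lambda`,
#'   `variant` and (with a backend) `fitness`.
#' @export
glycine_scan <- function(sequence, chunk_len = 6,
                         table = default_param_table(), backend = NULL,
                         reference_width = NULL) {
  stopifnot(chunk_len >= 1)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  lam <- setNames(table$residues$lambda, table$residues$code)
  lam_g <- lam[["G"]]
  starts <- seq(1, n, by = chunk_len)
  out <- purrr::map_dfr(seq_along(starts), function(i) {
    s0 <- starts[i]; s1 <- min(s0 + chunk_len - 1, n)
    var <- chars; var[s0:s1] <- "G"
    tibble::tibble(chunk = i, start = s0, end = s1,
                   delta_lambda = mean(lam[chars[s0:s1]]) - lam_g,
                   variant = paste(var, collapse = ""))
  })
  if (!is.null(backend)) {
    if (is.null(reference_width)) {
      d0 <- backend(sequence)
      reference_width <- unname(d0[["rho_l"]] - d0[["rho_v"]])
    }
    out$fitness <- purrr::map_dbl(out$variant, function(v) {
      d <- backend(v)
      unname(d[["rho_l"]] - d[["rho_v"]]) / reference_width
    })
  }
  out
}

#' Pair correlation function g(r)
#'
#' For each bead, counts all non-harmonically-bonded other beads in shells
#' of width `dr`, averaged over beads and frames and normalised by the
#' shell volume and the common number density `N/V`. Intended for
#' homogeneous (single-phase) trajectories at a stated number density.
#'
#' @param traj A `cg_trajectory`.
#' @param dr Shell width in Angstrom (default 0.5).
#' @param rmax Maximum distance; capped (with a warning) at half the
#'   smallest box edge.
#' @return An `rdf` tibble: `r` (shell centres), `g`.
#' @export
radial_distribution <- function(traj, dr = 0.5, rmax = NULL) {
  box <- traj$box
  cap <- min(box) / 2
  if (is.null(rmax)) rmax <- cap
  if (rmax > cap) {
    warning("rmax truncated to half the minimum box edge (", signif(cap, 4),
            " A)")
    rmax <- cap
  }
  n <- dim(traj$frames)[1]
  nf <- dim(traj$frames)[3]
  hist <- cpp_rdf_hist(as.numeric(traj$frames), box,
                       traj$topology$bonds - 1L, n, nf, dr, rmax)
  nbin <- length(hist)
  r_lo <- (seq_len(nbin) - 1) * dr
  shell <- 4 / 3 * pi * ((r_lo + dr)^3 - r_lo^3)
  rho_n <- n / prod(box)
  g <- hist / (nf * n) / (shell * rho_n)
  structure(tibble::tibble(r = r_lo + dr / 2, g = g),
            class = c("rdf", "tbl_df", "tbl", "data.frame"),
            number_density = rho_n, dr = dr)
}

#' Pairwise energy decomposition of a trajectory
#'
#' Recomputes the Coulomb and short-range ("hydrophobic") pairwise energy
#' per bead frame by frame and reports time averages with standard
#' deviations, the quantities whose WT-vs-evolved differences localise the
#' driving force of an evolution run.
#'
#' @param traj A `cg_trajectory`.
#' @param table A [param_table()].
#' @return One-row tibble: `e_coul`, `e_lj`, `e_bond` (kcal/mol per bead)
#'   with `sd_coul`, `sd_lj`, `sd_bond` over frames.
#' @export
energy_decomposition <- function(traj, table = default_param_table()) {
  nf <- dim(traj$frames)[3]
  n <- dim(traj$frames)[1]
  config <- list(box = traj$box, type = traj$topology$type,
                 bonds = traj$topology$bonds)
  per_frame <- purrr::map_dfr(seq_len(nf), function(f) {
    config$positions <- traj$frames[, , f]
    system_energy_forces(config, table)$breakdown
  })
  tibble::tibble(
    e_coul = mean(per_frame$e_coul), e_lj = mean(per_frame$e_lj),
    e_bond = mean(per_frame$e_bond),
    sd_coul = sd(per_frame$e_coul), sd_lj = sd(per_frame$e_lj),
    sd_bond = sd(per_frame$e_bond), n_frames = nf, n_beads = n)
}
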