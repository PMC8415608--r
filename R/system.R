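#' Specify a periodic multi-chain system
#'
#' Collects everything a slab direct-coexistence run needs: the species
#' (sequences and chain counts), the periodic box, thermodynamic state and
#' integration settings. For slab runs the box is elongated along z
#' (`L_z >= L_x = L_y`); when `box` is omitted it is sized so the chains,
#' packed as a dense central slab at `target_density`, occupy roughly
#' `1/aspect` of the box height.
#'
#' @param species A data frame with columns `sequence` and `count`, or a
#'   single sequence string (with `n_chains`).
#' @param n_chains Chain count when `species` is a single sequence.
#' @param box Numeric length-3 `(L_x, L_y, L_z)` in Angstrom, or `NULL`.
#' @param temperature Temperature in K.
#' @param timestep Integration timestep in fs.
#' @param friction Langevin friction in ps^-1 (`0` gives the zero-noise
#'   velocity-Verlet limit).
#' @param n_equil,n_prod Equilibration and production step counts.
#' @param sample_interval Steps between saved frames.
#' @param seed Integer seed; fully determines the stochastic stream.
#' @param target_density Initial dense-slab mass density in g/cm^3 used when
#'   auto-sizing the box.
#' @param aspect Box elongation `L_z / L_x` used when auto-sizing.
#' @param table Parameter table used for masses when auto-sizing the box.
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(species, n_chains = NULL, box = NULL,
                        temperature = 300, timestep = 10, friction = 1,
                        n_equil = 1000, n_prod = 5000, sample_interval = 100,
                        seed = 1, target_density = 0.5, aspect = 4,
                        table = default_param_table()) {
  if (is.character(species)) {
    stopifnot(!is.null(n_chains))
    species <- tibble::tibble(sequence = species, count = as.integer(n_chains))
  }
  species <- tibble::as_tibble(species)
  stopifnot(all(species$count >= 1))
  if (is.null(box)) {
    mass <- sum(purrr::map2_dbl(species$sequence, species$count, function(s, k)
      k * sum(residue_params(table, s)$mass)))
    v_slab <- mass * 1.66054 / target_density
    lx <- v_slab^(1 / 3)
    box <- c(lx, lx, aspect * lx)
  }
  if (!(box[3] >= box[1] && abs(box[1] - box[2]) < 1e-9))
    stop("slab geometry requires L_z >= L_x = L_y")
  structure(list(species = species, box = box, temperature = temperature,
                 timestep = timestep, friction = friction, n_equil = n_equil,
                 n_prod = n_prod, sample_interval = sample_interval,
                 seed = as.integer(seed), target_density = target_density),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("<system_spec> ", sum(x$species$count), " chains, box ",
      paste(signif(x$box, 4), collapse = " x "), " A, T = ", x$temperature,
      " K, dt = ", x$timestep, " fs\n", sep = "")
  invisible(x)
}

# serpentine coil for one chain: bond length r0 along x, rows/layers on a
# grid with spacing `a`; returns an n x 3 matrix centred on the origin
serpentine_chain <- function(n, r0, a) {
  per_row <- max(2L, ceiling(n^(1 / 3)))
  per_layer <- per_row^2
  idx <- seq_len(n) - 1L
  layer <- idx %/% per_layer
  rowi <- (idx %% per_layer) %/% per_row
  coli <- idx %% per_row
  # alternate direction each row and each layer so consecutive beads stay
  # r0 or `a` apart
  coli <- ifelse(rowi %% 2 == 0, coli, per_row - 1 - coli)
  rowi <- ifelse(layer %% 2 == 0, rowi, per_row - 1 - rowi)
  xyz <- cbind(coli * r0, rowi * a, layer * a)
  sweep(xyz, 2, colMeans(xyz))
}

#' Build an initial slab configuration
#'
#' Chains are laid down as compact serpentine coils on a jittered grid that
#' fills the x-y cross-section of a central slab, leaving vapour space above
#' and below along z. No two beads start closer than `0.8 * sigma_min`.
#'
#' @param spec A [system_spec()].
#' @param table A [param_table()].
#' @return An object of class `cg_configuration`: positions (wrapped into
#'   the primary cell), box, per-bead type and chain id, bond list and the
#'   chain sequences.
#' @export
build_slab <- function(spec, table = default_param_table()) {
  sequences <- rep(spec$species$sequence, spec$species$count)
  build_packed(sequences, spec, table)
}

build_packed <- function(sequences, spec, table, slab = TRUE) {
  box <- spec$box
  r0 <- table$globals$bond_r0
  lens <- nchar(sequences)
  for (s in sequences) residue_params(table, s)   # validates codes
  sig_min <- min(residue_params(table, paste(unique(
    unlist(strsplit(sequences, ""))), collapse = ""))$sigma)
  min_sep <- 0.8 * sig_min
  sig_max <- max(residue_params(table, paste(unique(
    unlist(strsplit(sequences, ""))), collapse = ""))$sigma)
  a <- max(0.9 * sig_max, min_sep + 0.4)

  coils <- lapply(lens, serpentine_chain, r0 = r0, a = a)
  half_extent <- vapply(coils, function(m) apply(abs(m), 2, max), numeric(3))
  cell <- 2 * apply(half_extent, 1, max) + (min_sep + 0.6)
  # inflate chain spacing so the starting slab sits near the target density
  mass_chain <- mean(vapply(sequences, function(s)
    sum(residue_params(table, s)$mass), 0))
  rho_cell <- mass_chain * 1.66054 / prod(cell)
  target <- spec$target_density %||% 0.5
  cell <- cell * max((rho_cell / target)^(1 / 3), 1)

  n_chains <- length(sequences)
  nx <- max(1L, floor(box[1] / cell[1]))
  ny <- max(1L, floor(box[2] / cell[2]))
  if (slab) {
    nz_needed <- ceiling(n_chains / (nx * ny))
    if (nz_needed * cell[3] > box[3])
      stop("density too high: cannot pack ", n_chains,
           " chains into the requested box")
    centres <- expand.grid(
      x = (seq_len(nx) - 0.5) * cell[1],
      y = (seq_len(ny) - 0.5) * cell[2],
      z = (seq_len(nz_needed) - 0.5) * cell[3])[seq_len(n_chains), ]
    # centre the occupied block in the box; slab sits mid-z
    centres$x <- centres$x - nx * cell[1] / 2 + box[1] / 2
    centres$y <- centres$y - ny * cell[2] / 2 + box[2] / 2
    centres$z <- centres$z - nz_needed * cell[3] / 2 + box[3] / 2
  } else {
    nz <- max(1L, floor(box[3] / cell[3]))
    if (nx * ny * nz < n_chains)
      stop("density too high: cannot pack ", n_chains,
           " chains into the requested box")
    # spread cells over the whole box; pick an evenly strided subset
    grid <- expand.grid(x = (seq_len(nx) - 0.5) * box[1] / nx,
                        y = (seq_len(ny) - 0.5) * box[2] / ny,
                        z = (seq_len(nz) - 0.5) * box[3] / nz)
    pick <- round(seq(1, nrow(grid), length.out = n_chains))
    centres <- grid[pick, ]
  }

  jitter_amp <- 0.25
  pos <- with_preserved_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(n_chains), function(i) {
      jit <- runif(3, -jitter_amp, jitter_amp)
      sweep(coils[[i]], 2, as.numeric(centres[i, ]) + jit, `+`)
    }))
  })
  pos <- wrap_positions(pos, box)

  chain_id <- rep(seq_len(n_chains), lens)
  type <- unlist(strsplit(sequences, ""))
  offsets <- cumsum(c(0, lens[-n_chains]))
  bonds <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
    if (lens[i] < 2) return(NULL)
    cbind(offsets[i] + seq_len(lens[i] - 1), offsets[i] + 2:lens[i])
  }))
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  config <- structure(list(positions = pos, box = box, type = type,
                           chain_id = chain_id, bonds = bonds,
                           sequences = sequences),
                      class = "cg_configuration")
  md <- cpp_min_dist(pos, box, bonds - 1L)
  if (md < min_sep)
    stop("packing failure: minimum bead separation ", signif(md, 3),
         " A below 0.8 * sigma_min = ", signif(min_sep, 3), " A")
  config
}

#' @export
print.cg_configuration <- function(x, ...) {
  cat("<cg_configuration> ", nrow(x$positions), " beads in ",
      length(x$sequences), " chains, box ",
      paste(signif(x$box, 4), collapse = " x "), " A\n", sep = "")
  invisible(x)
}

#' Build a homogeneous bulk configuration
#'
#' Distributes the chains' serpentine coils uniformly over the whole box
#' instead of a central slab: the starting point for single-phase
#' (canonical-ensemble) runs such as liquid-phase diffusion or pair
#' correlation analyses at a stated number density.
#'
#' @param spec A [system_spec()]; the box is used as given (cubic boxes are
#'   fine here).
#' @param table A [param_table()].
#' @return A `cg_configuration`.
#' @export
build_bulk <- function(spec, table = default_param_table()) {
  sequences <- rep(spec$species$sequence, spec$species$count)
  build_packed(sequences, spec, table, slab = FALSE)
}

#' Build a protein/poly-U mixed system
#'
#' Replaces the stated fraction of protein chains by poly-U homopolymers of
#' the same length as the protein they replace, mirroring condensate media
#' that contain RNA. RNA bead parameters (code `"U"`) must be present in the
#' table; the bond topology of RNA chains is the same harmonic chain used
#' for proteins.
#'
#' @param spec A [system_spec()] (protein species only).
#' @param rna_fraction Fraction of chains to replace; `rna_fraction * total`
#'   must be a whole number.
#' @param table A [param_table()] containing a `"U"` bead type.
#' @return A `cg_configuration`.
#' @export
build_mixed_system <- function(spec, rna_fraction,
                               table = default_param_table()) {
  sequences <- rep(spec$species$sequence, spec$species$count)
  n <- length(sequences)
  n_rna <- rna_fraction * n
  if (abs(n_rna - round(n_rna)) > 1e-9)
    stop("rna_fraction * chain count must be an integer")
  n_rna <- as.integer(round(n_rna))
  if (n_rna > 0 && !"U" %in% table$residues$code)
    stop("table has no poly-U RNA bead parameters; supply a table with a ",
         "'U' row (e.g. via read_param_table()) to build RNA mixtures")
  if (n_rna > 0) {
    replaced <- unique(round(seq(1, n, length.out = n_rna)))
    sequences[replaced] <- vapply(nchar(sequences[replaced]), function(k)
      paste(rep("U", k), collapse = ""), "")
  }
  build_packed(sequences, spec, table)
}

#' Wrap positions into the primary periodic cell
#'
#' @param pos `n x 3` matrix of coordinates.
#' @param box Length-3 box vector.
#' @return Matrix with all coordinates in `[0, L)`.
#' @export
wrap_positions <- function(pos, box) {
  for (k in 1:3) pos[, k] <- pos[, k] %% box[k]
  pos
}
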