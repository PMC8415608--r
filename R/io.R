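#' Read amino-acid sequences from FASTA or plain text
#'
#' FASTA files are parsed with Biostrings; plain-text files are read one
#' sequence per line. Every residue must be one of the 20 canonical one-letter
#' codes (or a code present in `extra_codes`, e.g. `"U"` for an RNA bead).
#'
#' @param path File path.
#' @param format `"auto"` (FASTA when the first non-blank character is `>`),
#'   `"fasta"` or `"text"`.
#' @param extra_codes Additional accepted bead codes beyond the 20 canonical
#'   amino acids.
#' @return A tibble with columns `name`, `sequence`, `length`. An empty file
#'   yields an empty tibble with a warning.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "text"),
                           extra_codes = character()) {
  format <- match.arg(format)
  raw <- readLines(path, warn = FALSE)
  nonblank <- raw[nzchar(trimws(raw))]
  if (!length(nonblank)) {
    warning("no sequences found in ", path)
    return(tibble::tibble(name = character(), sequence = character(),
                          length = integer()))
  }
  if (format == "auto")
    format <- if (startsWith(trimws(nonblank[1]), ">")) "fasta" else "text"
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  } else {
    seqs <- toupper(trimws(nonblank))
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  ok <- c(.aa_codes, extra_codes)
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad))
      stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1],
           " of sequence ", names(seqs)[i])
  }
  tibble::tibble(name = names(seqs), sequence = unname(seqs),
                 length = nchar(unname(seqs)))
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector, or a tibble with `name` and
#'   `sequence` columns.
#' @param path Output file path.
#' @export
write_sequences <- function(sequences, path) {
  if (is.data.frame(sequences))
    sequences <- setNames(sequences$sequence, sequences$name)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Wild-type sequences packaged with the model
#'
#' Returns the three reference intrinsically disordered regions studied with
#' this model: the FUS prion-like domain (residues 1-163), the hnRNPA1 IDR
#' (its first 135 residues) and the LAF-1 RGG domain (residues 1-168).
#'
#' @param which Optional name (`"fus_pld"`, `"hnrnpa1_idr"`, `"laf1_idr"`);
#'   when given, the sequence string itself is returned.
#' @return A tibble of all three fixtures, or a single sequence string.
#' @export
#' @examples
#' nchar(wt_sequence("fus_pld"))
wt_sequences <- function() {
  files <- c(fus_pld = "fus_pld.fasta", hnrnpa1_idr = "hnrnpa1_idr.fasta",
             laf1_idr = "laf1_idr.fasta")
  out <- purrr::map_dfr(files, function(f)
    read_sequences(system.file("extdata", f, package = "idpevolve")))
  out$name <- names(files)
  out
}

#' @rdname wt_sequences
#' @export
wt_sequence <- function(which = c("fus_pld", "hnrnpa1_idr", "laf1_idr")) {
  which <- match.arg(which)
  tab <- wt_sequences()
  tab$sequence[tab$name == which]
}

#' Random and patterned synthetic sequences
#'
#' `make_random_sequence()` draws residues independently from a composition
#' weight vector; `make_charge_pattern()` builds alternating glutamate/lysine
#' blocks, a standard family of charge-patterned test sequences whose
#' sequence charge decoration grows in magnitude with block size.
#'
#' @param length Sequence length.
#' @param weights Named numeric vector of composition weights over residue
#'   codes; `NULL` means uniform over the 20 canonical amino acids.
#' @param seed Optional integer seed; the same (spec, seed) always yields the
#'   same sequence.
#' @return A sequence string.
#' @export
make_random_sequence <- function(length, weights = NULL, seed = NULL) {
  if (is.null(weights))
    weights <- setNames(rep(1, 20), .aa_codes)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum")
  codes <- names(weights)
  if (is.null(codes)) stop("weights must be named by residue code")
  draw <- function() paste(sample(codes, length, replace = TRUE,
                                  prob = weights), collapse = "")
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

#' @rdname make_random_sequence
#' @param block Block size; must divide `length`. Blocks alternate E then K.
#' @export
make_charge_pattern <- function(length, block) {
  if (length %% block != 0) stop("block size must divide the length")
  n_blocks <- length / block
  paste(rep(rep(c("E", "K"), length.out = n_blocks), each = block),
        collapse = "")
}

#' Synthetic ground-truth fixtures for the phase machinery
#'
#' `make_synthetic_profile()` builds a slab density profile with two
#' symmetric tanh interfaces and known plateau densities;
#' `make_synthetic_binodal()` builds coexistence points exactly on the
#' scaling-law + rectilinear-diameter curves with known critical point.
#' Both serve as exact oracles for [fit_coexistence()] and [build_binodal()].
#'
#' @param rho_l,rho_v Liquid and vapour plateau densities (`rho_l > rho_v`).
#' @param interface_width Interface width parameter (Angstrom).
#' @param noise Gaussian noise s.d. added to each bin (profile) or density
#'   (binodal points).
#' @param seed Integer seed for the noise.
#' @param n_bins Number of z bins.
#' @param lz Box length along z (Angstrom).
#' @param slab_frac Fraction of the box occupied by the dense slab.
#' @return For profiles, a `density_profile` tibble; for binodals, a tibble
#'   of coexistence points.
#' @export
make_synthetic_profile <- function(rho_l, rho_v, interface_width = 5,
                                   noise = 0, seed = 1, n_bins = 25,
                                   lz = 250, slab_frac = 0.3) {
  stopifnot(rho_l > rho_v, rho_v >= 0)
  z <- (seq_len(n_bins) - 0.5) * lz / n_bins
  zc <- lz / 2
  half <- slab_frac * lz / 2
  rho <- rho_v + (rho_l - rho_v) / 2 *
    (tanh((z - (zc - half)) / interface_width) -
     tanh((z - (zc + half)) / interface_width))
  if (noise > 0)
    rho <- rho + with_preserved_seed(seed, rnorm(n_bins, 0, noise))
  new_density_profile(z, rho, se = rep(noise, n_bins), box = c(lz, lz, lz),
                      n_frames = 1L)
}

#' @rdname make_synthetic_profile
#' @param tc,rho_c Critical temperature (K) and density.
#' @param amplitude Order-parameter amplitude `A` in
#'   `rho_l - rho_v = A (1 - T/Tc)^beta`.
#' @param diam_slope Rectilinear-diameter slope `B` in
#'   `(rho_l + rho_v)/2 = rho_c + B (Tc - T)`.
#' @param n_points Number of sub-critical temperatures.
#' @param t_range Temperatures span `t_range * tc` up to `0.99 tc`.
#' @param beta Critical exponent used to generate the points.
#' @export
make_synthetic_binodal <- function(tc, rho_c, amplitude, diam_slope = 0,
                                   n_points = 6, noise = 0, seed = 1,
                                   t_range = c(0.6, 0.95), beta = 0.325) {
  temps <- seq(t_range[1] * tc, t_range[2] * tc, length.out = n_points)
  width <- amplitude * (1 - temps / tc)^beta
  diam <- rho_c + diam_slope * (tc - temps)
  rho_l <- diam + width / 2
  rho_v <- pmax(diam - width / 2, 0)
  if (noise > 0) {
    eps <- with_preserved_seed(seed, rnorm(2 * n_points, 0, noise))
    rho_l <- rho_l + eps[seq_len(n_points)]
    rho_v <- pmax(rho_v + eps[n_points + seq_len(n_points)], 0)
  }
  tibble::tibble(temperature = temps, rho_v = rho_v, rho_l = rho_l,
                 se_v = noise, se_l = noise, converged = TRUE)
}

#' Run-configuration files
#'
#' A run configuration is a YAML document mirroring the simulation,
#' genetic-algorithm and analysis settings. The schema is versioned and
#' closed: unknown keys are rejected so that typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema_version", "system", "ga", "analysis", "seed", "notes")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$schema_version))
    stop("configuration must declare schema_version")
  sys_known <- c("species", "box", "temperature", "timestep", "friction",
                 "n_equil", "n_prod", "sample_interval", "seed")
  unknown <- setdiff(names(cfg$system), sys_known)
  if (length(unknown))
    stop("unknown system key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' @rdname read_run_config
#' @param config Named list as returned by [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seeds and package version needed to replay a
#' run.
#'
#' @param path Output JSON path.
#' @param config Configuration list.
#' @param seeds Named list/vector of seeds used.
#' @export
write_manifest <- function(path, config, seeds) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing manifests requires the jsonlite package")
  manifest <- list(
    package = "idpevolve",
    version = as.character(utils::packageVersion("idpevolve")),
    config_hash = seq_hash(paste(deparse(config), collapse = "")),
    seeds = as.list(seeds),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic 31-adic string hash on [0, 2^31 - 58)
seq_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483591
  as.integer(h)
}
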