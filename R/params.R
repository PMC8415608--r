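#' Residue parameter tables for the coarse-grained model
#'
#' A parameter table bundles the per-residue bead parameters (hydrophobicity
#' scale `lambda`, bead size `sigma` in Angstrom, formal charge in units of e,
#' mass in amu) with the global interaction constants of the model (short-range
#' well depth `epsilon`, Debye screening length, dielectric constant, harmonic
#' bond constants, nonbonded cutoffs). Two pair models are supported: `"HPS"`,
#' where the well depth of every pair is `epsilon` scaled by the arithmetic
#' mean of the two residues' `lambda` values, and `"KH"`, where a symmetric
#' pair-energy matrix sets a pair-specific well depth.
#'
#' @param residues A data frame with columns `code`, `lambda`, `sigma`,
#'   `charge`, `mass`, one row per bead type. All 20 canonical amino acids
#'   must be present; additional non-protein bead types (e.g. `"U"` for a
#'   poly-U RNA bead) may follow.
#' @param globals Named list of global constants (see
#'   [default_param_table()] for the full set).
#' @param pair_model `"HPS"` or `"KH"`.
#' @param kh Symmetric pair-energy matrix (kcal/mol) with residue codes as
#'   dimnames; required when `pair_model = "KH"`.
#'
#' @return An object of class `param_table`: a list with elements `residues`
#'   (a tibble), `globals`, `pair_model` and `kh`.
#' @export
param_table <- function(residues, globals, pair_model = "HPS", kh = NULL) {
  residues <- tibble::as_tibble(residues)
  out <- structure(
    list(residues = residues, globals = globals,
         pair_model = match.arg(pair_model, c("HPS", "KH")), kh = kh),
    class = "param_table")
  validate_param_table(out)
}

.aa_codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.required_globals <- c("epsilon", "dielectric", "debye_length", "bond_k",
                       "bond_r0", "lj_cutoff", "coul_cutoff")

#' @rdname param_table
#' @param x A `param_table`.
#' @export
validate_param_table <- function(x) {
  res <- x$residues
  need <- c("code", "lambda", "sigma", "charge", "mass")
  if (!all(need %in% names(res)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  missing_aa <- setdiff(.aa_codes, res$code)
  if (length(missing_aa))
    stop("parameter table is missing canonical residue(s): ",
         paste(missing_aa, collapse = ", "))
  if (anyDuplicated(res$code))
    stop("duplicated residue codes in parameter table")
  if (any(res$sigma <= 0)) stop("sigma must be positive")
  if (!all(res$charge %in% c(-1L, 0L, 1L)))
    stop("formal charges must be -1, 0 or +1")
  if (any(!is.finite(res$lambda))) stop("lambda values must be finite")
  if (any(res$mass <= 0)) stop("masses must be positive")
  miss_g <- setdiff(.required_globals, names(x$globals))
  if (length(miss_g))
    stop("missing global constant(s): ", paste(miss_g, collapse = ", "))
  if (x$pair_model == "KH") {
    if (is.null(x$kh)) stop("pair_model 'KH' requires a pair-energy matrix")
    if (!isTRUE(all.equal(x$kh, t(x$kh), tolerance = 1e-12)))
      stop("KH pair-energy matrix must be symmetric")
    if (!all(res$code %in% rownames(x$kh)))
      stop("KH matrix must cover every residue code in the table")
  }
  x
}

#' @export
print.param_table <- function(x, ...) {
  cat("<param_table> ", nrow(x$residues), " bead types, pair model ",
      x$pair_model, "\n", sep = "")
  cat("  epsilon = ", x$globals$epsilon, " kcal/mol, Debye length = ",
      x$globals$debye_length, " A, cutoffs (LJ, Coul) = ",
      x$globals$lj_cutoff, ", ", x$globals$coul_cutoff, " A\n", sep = "")
  print(x$residues, n = 5)
  invisible(x)
}

#' The default residue parameter set
#'
#' Loads the parameter table shipped with the package: the hydrophobicity
#' scale (`lambda`), bead diameters (`sigma`), formal charges and masses of
#' the 20 canonical amino acids, together with the global constants of the
#' model. Histidine is treated as neutral. The shipped hydrophobicity scale
#' assigns glycine `lambda = 0.64865` (0.649 at the precision usually quoted).
#'
#' @return A [param_table()].
#' @export
#' @examples
#' tab <- default_param_table()
#' residue_params(tab, "G")$lambda
default_param_table <- function() {
  read_param_table(
    system.file("extdata", "aa_params.csv", package = "idpevolve"),
    globals = system.file("extdata", "hps_globals.yaml", package = "idpevolve"))
}

#' Read and write residue parameter tables
#'
#' The on-disk schema (version 1) is a CSV file with header
#' `code,lambda,sigma,charge,mass` (one row per bead type), an optional YAML
#' file of global constants, and an optional CSV pair-energy matrix for the
#' KH pair model (row and column labels are residue codes). `sigma` is the
#' pair-potential contact diameter in Angstrom; pairwise `sigma_ij` and
#' `lambda_ij` are arithmetic means of the per-residue values.
#'
#' @param path Path to the residue CSV file.
#' @param globals Path to a YAML file of global constants, or a named list.
#' @param kh_matrix Optional path to a KH pair-energy CSV matrix.
#' @return A [param_table()].
#' @export
read_param_table <- function(path, globals, kh_matrix = NULL) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(globals)) globals <- yaml::read_yaml(globals)
  kh <- NULL
  pair_model <- if (is.null(globals$pair_model)) "HPS" else globals$pair_model
  if (!is.null(kh_matrix)) {
    khdf <- utils::read.csv(kh_matrix, row.names = 1, check.names = FALSE)
    kh <- as.matrix(khdf)
    pair_model <- "KH"
  }
  param_table(res, globals, pair_model = pair_model, kh = kh)
}

#' @rdname read_param_table
#' @param table A [param_table()].
#' @param globals_path Optional path for the YAML globals; omitted when `NULL`.
#' @export
write_param_table <- function(table, path, globals_path = NULL) {
  res <- table$residues
  lines <- c("code,lambda,sigma,charge,mass",
             paste(res$code, as.character(res$lambda), as.character(res$sigma),
                   as.character(as.integer(res$charge)), as.character(res$mass),
                   sep = ","))
  writeLines(lines, path)
  if (!is.null(globals_path))
    yaml::write_yaml(table$globals, globals_path)
  invisible(path)
}

#' Look up per-residue parameters
#'
#' @param table A [param_table()].
#' @param codes Character vector of one-letter residue codes (a multi-letter
#'   string is split into single residues).
#' @return A tibble with one row per requested code.
#' @export
residue_params <- function(table, codes) {
  codes <- split_residues(codes)
  idx <- match(codes, table$residues$code)
  if (anyNA(idx))
    stop("unknown residue code(s): ",
         paste(unique(codes[is.na(idx)]), collapse = ", "))
  table$residues[idx, ]
}

# split "ACDE" or c("A","C") into single-letter vector
split_residues <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    strsplit(seq, "")[[1]]
  else as.character(seq)
}

# per-pair (eps, lambda, sigma) matrices plus per-type charge/mass vectors,
# in the layout the C++ engine expects
pair_coefficients <- function(table) {
  res <- table$residues
  nt <- nrow(res)
  sig <- outer(res$sigma, res$sigma, function(a, b) (a + b) / 2)
  if (table$pair_model == "HPS") {
    lam <- outer(res$lambda, res$lambda, function(a, b) (a + b) / 2)
    eps <- matrix(table$globals$epsilon, nt, nt)
  } else {
    e <- table$kh[res$code, res$code]
    alpha <- table$globals$kh_alpha %||% 0.228
    e0 <- table$globals$kh_e0 %||% -1.0
    scaled <- alpha * (e - e0)
    eps <- abs(scaled)
    lam <- ifelse(scaled <= 0, 1, -1)
  }
  dimnames(eps) <- dimnames(lam) <- dimnames(sig) <- list(res$code, res$code)
  list(eps = eps, lam = lam, sig = sig,
       q = setNames(as.numeric(res$charge), res$code),
       mass = setNames(res$mass, res$code), codes = res$code)
}

# globals in the layout the C++ engine expects
engine_globals <- function(table, shifted = TRUE) {
  g <- table$globals
  list(kc = .coulomb_k / g$dielectric, debye = g$debye_length,
       rc_lj = g$lj_cutoff, rc_coul = g$coul_cutoff, shifted = shifted,
       bond_k = g$bond_k, bond_r0 = g$bond_r0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
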