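#' Extended-XYZ trajectory output
#'
#' Writes configurations or trajectories in the extended-XYZ convention:
#' per frame, a bead count line, a comment line carrying the lattice and a
#' `Properties=species:S:1:pos:R:3:chain:I:1` declaration, then one line per
#' bead (`code x y z chain`). Positions are wrapped into the primary cell.
#'
#' @param x A `cg_configuration` or `cg_trajectory`.
#' @param path Output file.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(pos, box, type, chain) {
    pos <- wrap_positions(pos, box)
    writeLines(as.character(nrow(pos)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:chain:I:1',
      box[1], box[2], box[3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %d", type, pos[, 1], pos[, 2],
                       pos[, 3], chain), con)
  }
  if (inherits(x, "cg_configuration")) {
    emit(x$positions, x$box, x$type, x$chain_id)
  } else if (inherits(x, "cg_trajectory")) {
    for (f in seq_len(dim(x$frames)[3]))
      emit(x$frames[, , f], x$box, x$topology$type, x$topology$chain_id)
  } else stop("write_xyz handles cg_configuration and cg_trajectory objects")
  invisible(path)
}

#' Read a single-frame extended-XYZ configuration
#'
#' @param path File written by [write_xyz()].
#' @return A `cg_configuration` (bond list reconstructed from consecutive
#'   beads sharing a chain id).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  lat <- regmatches(lines[2], regexpr('Lattice="[^"]+"', lines[2]))
  box_vals <- as.numeric(strsplit(sub('Lattice="', '',
                                      sub('"$', '', lat)), " ")[[1]])
  box <- box_vals[c(1, 5, 9)]
  rows <- strsplit(lines[3:(2 + n)], "\\s+")
  type <- vapply(rows, `[`, "", 1)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  chain <- as.integer(vapply(rows, `[`, "", 5))
  bonds <- do.call(rbind, lapply(split(seq_len(n), chain), function(ix) {
    if (length(ix) < 2) return(NULL)
    cbind(ix[-length(ix)], ix[-1])
  }))
  sequences <- vapply(split(type, chain), paste, "", collapse = "")
  structure(list(positions = pos, box = box, type = type, chain_id = chain,
                 bonds = bonds, sequences = unname(sequences)),
            class = "cg_configuration")
}
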