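# Independent, named RNG substreams.
#
# One master seed spawns a fixed set of purpose-specific substreams so that,
# e.g., changing how many random numbers a fitness backend consumes cannot
# perturb the mutation/selection stream of a genetic-algorithm run.

new_rng_streams <- function(master_seed, names) {
  subseeds <- with_preserved_seed(master_seed,
                                  sample.int(2147483591L, length(names)))
  streams <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    state <- with_preserved_seed(subseeds[i],
                                 get(".Random.seed", envir = globalenv()))
    assign(names[i], state, envir = streams)
  }
  streams
}

# evaluate expr using (and advancing) the named substream, leaving the
# caller's global RNG untouched
stream_do <- function(streams, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  out <- force(expr)
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  out
}
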