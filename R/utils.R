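# Seed scoping: run a block under a fixed seed without disturbing the
# caller's RNG stream. Returns a restore function for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# One global seed fans out to independent per-component substreams so a
# component can be regenerated on its own yet reproducibly. Kept within
# 32-bit integer range.
substream_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
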