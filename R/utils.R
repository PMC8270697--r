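# shared helpers

vs_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vs_error", "error", "condition")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One user-facing seed fans out to per-purpose streams by fixed offsets;
# kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483647)
}

# tile attribute helpers ------------------------------------------------------

new_tile <- function(x, domain, range = c(0, 1)) {
  attr(x, "domain") <- domain
  attr(x, "range") <- range
  class(x) <- c("vs_tile", class(x))
  x
}

#' Domain tag of an image tile
#' @param tile A tile produced by the renderers or readers.
#' @return `"stained"` or `"unstained"` (or `NULL` if untagged).
#' @export
tile_domain <- function(tile) attr(tile, "domain", exact = TRUE)
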