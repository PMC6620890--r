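# Internal helpers shared across modules.

# Run `expr` with a private RNG stream seeded by `seed`, restoring the caller's
# stream afterwards so package functions never clobber user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-unit substream seed below 2^31 from a master seed and an index.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

tv_log <- function(..., verbose = getOption("tuitvig.verbose", TRUE)) {
  if (isTRUE(verbose)) inform(paste0(...))
}

`%0%` <- function(x, default) if (length(x) == 0 || all(is.na(x))) default else x

# Path to a bundled resource under inst/extdata.
tv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tuitvig")
  if (identical(path, "")) abort(paste0("bundled resource not found: ", file))
  path
}
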