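#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; independent
#' stages (simulation, class balancing, fold assignment, ...) draw from
#' named substreams so that changing one stage never perturbs another.
#'
#' @param root integer root seed.
#' @param name character substream name, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 2]`, deterministic in both
#'   arguments.
#' @export
#' @examples
#' substream_seed(42, "simulate")
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(root) * 48271 + h * 9973 + 12345) %% 2147483647)
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Polynomial rolling hash of a character scalar, reported as 8 hex digits.
# Used to stamp output artifacts with a digest of the configuration they
# came from (provenance, not cryptography).
text_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (code in utf8ToInt(x)) h <- (h * 33 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

config_hash <- function(cfg) {
  text_hash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                          digits = NA, force = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
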