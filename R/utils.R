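#' @keywords internal
"_PACKAGE"

# Run an expression with a private RNG state so simulators are pure functions
# of their seed and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-entity seed from a base seed and an index. Stable across
# versions: documented linear-congruential mix, kept inside 32-bit range.
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 48271 + as.double(index) * 104729) %% 2147483647)
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
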