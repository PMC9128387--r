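# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds below 2^31 from one parent seed.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_schema <- function(...) stop(errorCondition(paste0(...),
                                                class = c("frnet_schema_error", "error")))
stop_integrity <- function(...) stop(errorCondition(paste0(...),
                                                    class = c("frnet_integrity_error", "error")))

`%||%` <- function(a, b) if (is.null(a)) b else a
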