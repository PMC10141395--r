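# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL means "use the ambient stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a replicate-level seed from a master seed; keeps results inside the
# 32-bit signed range required by set.seed().
derive_seed <- function(master_seed, condition_index, replicate_index) {
  s <- (as.double(master_seed) * 100003 +
        as.double(condition_index) * 101 +
        as.double(replicate_index)) %% 2147483647
  as.integer(s)
}
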