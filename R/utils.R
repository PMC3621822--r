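# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed (< 2^31) from a master seed, a cycle index
# and a named stream, so that population, strategy and realization randomness
# come from separate but master-seed-determined streams.
derive_seed <- function(master, index = 0L, stream = 0L) {
  m <- (abs(as.numeric(master)) %% 1000003) + 1
  s <- (m * 2654435 + as.numeric(index) * 9973 + as.numeric(stream) * 7919) %%
    2147483629
  as.integer(s) + 1L
}

stream_id <- function(name) {
  switch(name,
    population = 11L,
    strategy = 23L,
    realization = 37L,
    fixture = 53L,
    stop("unknown stream: ", name)
  )
}

# key used to index per-ward, per-preference-class quantities
key_wb <- function(ward_id, preference) {
  paste(ward_id, preference, sep = "|")
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %s", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %s", name, min))
  invisible(x)
}

`%||%` <- rlang::`%||%`
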