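# Internal helpers: argument checking and reproducible sub-stream seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_adipo <- function(fmt, ..., class = "adipoCT_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_adipo("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_adipo("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stop_adipo("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Deterministic named sub-stream seed derived from a master seed.  FNV-1a style
# hash over the stream name folded with the master seed, reduced below 2^31 so
# it is a valid R integer seed.  Adding subjects/scans never perturbs the
# streams of existing ones because each stream name is independent.
substream_seed <- function(master_seed, name) {
  h <- 2166136261
  for (b in utf8ToInt(paste0(name, ":", master_seed))) {
    h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state (global .Random.seed is saved and restored).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
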