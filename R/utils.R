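# Internal helpers shared across the pipeline.

# Sample times in ms for an epoch: sample k (0-based) maps to (k - n_pre) / fs * 1000.
epoch_times_ms <- function(n_samples, n_pre, sampling_rate_hz) {
  (seq_len(n_samples) - 1L - n_pre) / sampling_rate_hz * 1000
}

# Indices of samples falling inside [lo, hi] ms (closed window at sample
# resolution). A small tolerance absorbs floating-point grid error; the same
# helper is used by the measurement stage and by the simulator's amplitude
# calibration so the two always agree sample-for-sample.
window_sample_idx <- function(times_ms, lo, hi, tol = 1e-9) {
  which(times_ms >= lo - tol & times_ms <= hi + tol)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Stable content hash used for provenance stamping of derived tables.
config_hash <- function(x) {
  rlang::hash(x)
}

stamp_provenance <- function(x, hash, seed) {
  attr(x, "config_hash") <- hash
  attr(x, "seed") <- seed
  x
}
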