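# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit seed derived from a master seed, a group label and a
# subject index: reproducible, distinct streams per subject.
derive_seed <- function(master, label, index) {
  m <- 2147483647 # 2^31 - 1, keeps derived seeds valid R integers
  s <- as.numeric(master) %% m
  for (b in utf8ToInt(as.character(label))) s <- (s * 31 + b) %% m
  s <- (s * 131 + 7 * as.numeric(index) + 1) %% m
  as.integer(s)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# Mean/SD over the strict upper triangle of a square matrix.
upper_tri_values <- function(m) m[upper.tri(m)]

is_symmetric_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# djb2-style rolling hash of a character representation, for config
# provenance (stays within exact double-precision integer arithmetic).
config_digest <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
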