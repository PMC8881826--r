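#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their `seed` argument here so
# that simulation calls are reproducible without clobbering the session RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream of child seeds from a master seed; kept below 2^31 - 1.
derive_seed <- function(master, k) {
  master <- as.double(master)
  s <- (master %% 2147483647) * 48271 + 15485863 * as.double(k)
  as.integer(s %% 2147483647) + 1L
}

stop_megconn <- function(msg, class) {
  stop(structure(
    class = c(class, "megconn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_megconn("cannot z-score a constant vector", "megconn_degenerate")
  }
  (x - mean(x)) / s
}
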