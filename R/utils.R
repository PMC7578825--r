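#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG state and restore the caller's state afterwards,
# so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for the i-th substream of a parent seed.
# Keeps every derived seed inside the 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483562L) + 1L
}

stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("trophicniche_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Levels in order of first appearance; all pairwise outputs follow this order.
appearance_factor <- function(x) factor(as.character(x), levels = unique(as.character(x)))

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number", name)
  }
  if (strict && x <= lower) stop_validation("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stop_validation("`%s` must be >= %g", name, lower)
  invisible(x)
}
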