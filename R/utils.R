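#' @keywords internal
"_PACKAGE"

# Typed error helpers: controller/rig misuse raises classed conditions so
# callers (and tests) can distinguish protocol bugs from ordinary errors.
abort_typed <- function(class, msg) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_protocol <- function(msg) abort_typed("protocol_violation", msg)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# stream afterwards. `seed = NULL` means: consume the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    stop(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}
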