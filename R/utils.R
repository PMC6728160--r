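#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after seeding R's RNG with `seed`, then restores the previous
#' global RNG state, so library functions never perturb a caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_bivseg <- function(msg, class) {
  stop(structure(class = c(class, "bivseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}

# Derive a stream of sub-seeds from a master seed, kept below 2^31.
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 1103515245 + 12345 * as.numeric(i)) %% 2147483647
}
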