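## Internal helpers: classed conditions, seed derivation, verbose logging.

sc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "spatcoloc_error")))
}

sc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "spatcoloc_warning")))
}

## Lightweight progress/log channel; silenced unless options(spatcoloc.verbose = TRUE).
sc_log <- function(...) {
  if (isTRUE(getOption("spatcoloc.verbose", FALSE))) {
    message("[spatcoloc] ", ...)
  }
  invisible(NULL)
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in multi-slide simulations and per-(slide, pair)
#' permutation tests flows from one master seed through this counter-based
#' split, so each unit is independently reproducible and results do not
#' depend on execution order. Values stay below 2^31 - 1 (R integer range).
#'
#' @param seed master seed (integer).
#' @param index non-negative counter (slide number, pair number, ...).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  ## splitmix-style affine mix kept in double precision (exact below 2^53)
  s <- (abs(seed) %% 2147483647) + 1
  v <- (s * 48271 + index * 2246822519) %% 2147483647
  as.integer(v)
}

## Evaluate expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min
}
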