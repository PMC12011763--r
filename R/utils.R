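# Small internal helpers shared across modules.

CLASS_LEVELS <- c("normal", "benign", "malignant")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mtloca <- function(fmt, ..., class = "mtloca_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, fmt, ..., class = "mtloca_error") {
  if (!isTRUE(ok)) stop_mtloca(fmt, ..., class = class)
  invisible(TRUE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_binary <- function(m) all(m == 0 | m == 1)

#' Derive a child RNG seed from a base seed
#'
#' Deterministic splitting of one user-facing seed into independent streams
#' (weight init, fold shuffling, augmentation, ...) while keeping every
#' derived seed a valid 32-bit integer.
#'
#' @param seed base integer seed.
#' @param ... integers identifying the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in as.double(ids)) h <- (h * 69069 + v + 1) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
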