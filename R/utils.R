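#' Derive a reproducible child seed from a master seed and labels
#'
#' Gives every randomized sub-task (a gene/trait cell of the Monte-Carlo test,
#' a simulation stage, ...) its own RNG stream derived deterministically from
#' the master seed, so results do not depend on execution order.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 0
  # 31-based polynomial rolling hash mod the Mersenne prime 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetry check with tolerance on a square numeric matrix.
check_symmetric <- function(S, tol = 1e-12, what = "matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stopf("%s must be a square matrix", what)
  if (max(abs(S - t(S))) > tol)
    stopf("%s is asymmetric beyond tolerance %g", what, tol)
  invisible(TRUE)
}
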