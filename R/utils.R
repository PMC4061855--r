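#' Derive a reproducible child seed
#'
#' Folds a master seed and a sequence of non-negative integer indices
#' (e.g. subject number, session number, block number) into a single
#' 31-bit seed by iterated multiply-add modulo a prime.  Used throughout the
#' synthetic-data generator so that any subject/session/block can be
#' regenerated in isolation from the master seed alone.
#'
#' @param master integer master seed.
#' @param ... non-negative integer indices, folded in order.
#' @return an integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
child_seed <- function(master, ...) {
  idx <- c(...)
  p <- 2147480009  # prime < 2^31; products stay exact in double precision
  s <- as.double(master) %% p
  for (i in idx) {
    s <- (s * 69069 + as.double(i) + 1) %% p
  }
  as.integer(s)
}

# run code under a temporary RNG state; NULL seed leaves the RNG alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wavepls <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wavepls_error")))
}

next_pow2 <- function(n) 2^ceiling(log2(n))
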