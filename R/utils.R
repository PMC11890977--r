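#' Derive a reproducible sub-stream seed from a master seed
#'
#' Deterministically maps a master seed plus any number of integer keys
#' (stage index, subject index, sparsity level, ...) to a new seed below
#' 2^31, so that every stage and subject of a run draws from its own
#' reproducible stream while the whole run is controlled by one seed.
#'
#' @param master integer master seed.
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
substream <- function(master, ...) {
  keys <- c(master, ...)
  m <- 2147483647
  h <- 0
  for (k in keys) {
    k <- as.numeric(k) %% m
    # multiplier kept small enough that h * 69069 + k stays exact in doubles
    h <- (h * 69069 + k + 1) %% m
  }
  as.integer(h)
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sfconn <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sfconn_error")))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
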