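# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  mid <- x > 18 & x <= 33
  out[lo] <- log1p(exp(x[lo]))
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed and a stream label to a 31-bit
#' integer seed, so that independent pipeline stages draw from distinct but
#' reproducible random streams.
#'
#' @param master integer master seed.
#' @param stream character label or integer index of the substream.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' childSeed(1, "participants")
childSeed <- function(master, stream) {
  stopifnot(length(master) == 1, is.finite(master))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 16807 + 12345
  as.integer(x %% m)
}

# truncated-normal draws via inverse-CDF (vectorised)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised Gauss-Hermite nodes/weights
.ghEnv <- new.env(parent = emptyenv())
ghCache <- function(n) {
  key <- as.character(n)
  if (is.null(.ghEnv[[key]])) .ghEnv[[key]] <- pracma::gaussHermite(n)
  .ghEnv[[key]]
}
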