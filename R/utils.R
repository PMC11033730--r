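## Internal helpers shared across modules.

#' @importFrom stats plogis rnorm runif uniroot var predict
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

# Polynomial rolling hash over non-negative integers, modulo the Mersenne
# prime 2^31 - 1.  Intermediate products stay below 2^53 so double
# arithmetic is exact; the result is a stable 31-bit identifier.
.hash_ints <- function(xs) {
  h <- 5381
  p <- 2147483647
  for (x in xs) h <- (h * 33 + x + 1) %% p
  h
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Draw k sub-seeds from a master seed without disturbing the caller's RNG
# more than once; used so composite generators are independently
# reproducible from (seed, purpose).
.derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, k)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
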