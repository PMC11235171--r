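# Internal helpers: deterministic hashing / PRNG independent of R's RNG
# (used by the surrogate affinity predictor so that affinities are a pure
# function of peptide and allele, never of the session seed), plus small
# validation utilities shared across modules.

MINSTD_M <- 2147483647

# polynomial rolling hash of a string onto [1, 2^31 - 2]
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 7
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% (MINSTD_M - 1)
  h + 1
}

# Park-Miller minimal standard generator; exact in double precision
minstd_next <- function(state) (16807 * state) %% MINSTD_M

minstd_runif <- function(state, n) {
  u <- numeric(n)
  for (i in seq_len(n)) {
    state <- minstd_next(state)
    u[i] <- state / MINSTD_M
  }
  list(u = u, state = state)
}

# deterministic permutation of 1..n keyed by a string (Fisher-Yates on minstd)
hash_permutation <- function(key, n) {
  state <- hash_string(key)
  perm <- seq_len(n)
  for (i in n:2) {
    state <- minstd_next(state)
    j <- 1L + as.integer(state %% i)
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
  }
  perm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")
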