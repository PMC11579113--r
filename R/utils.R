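# Internal helpers shared across modules.

#' @useDynLib ventbench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd cor predict
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and a context tag
#'
#' All stochastic stages derive their own seed from the experiment seed and a
#' stage label, so that adding or reordering stages never silently changes the
#' random stream of another stage. Results stay within the 32-bit integer
#' range R requires of `set.seed()`.
#'
#' @param seed integer base seed.
#' @param tag character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(as.double(utf8ToInt(tag)) * (seq_along(utf8ToInt(tag)) %% 97 + 1))
  as.integer((abs(as.double(seed)) * 1000003 + h * 7919) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Half-away-from-zero rounding (R's round() is half-to-even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Convert linear (1-based) voxel indices to an n x 3 coordinate matrix.
index_to_coord <- function(idx, dims) {
  idx0 <- idx - 1L
  d <- idx0 %% dims[1]
  h <- (idx0 %/% dims[1]) %% dims[2]
  w <- idx0 %/% (dims[1] * dims[2])
  cbind(d + 1L, h + 1L, w + 1L)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}
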