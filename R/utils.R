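# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so results are reproducible and side-effect free.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Number of samples on the canonical frame grid t_k = k/rate, k = 0..K with
# K = floor(duration * rate): samples span [0, duration].
n_frames_for <- function(duration, sampling_rate) {
  as.integer(floor(duration * sampling_rate)) + 1L
}

frame_times <- function(n_frames, sampling_rate) {
  (seq_len(n_frames) - 1) / sampling_rate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise sample standard deviation of a matrix (n-1 denominator).
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  m <- rowMeans(x)
  sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
}
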