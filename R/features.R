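# Interval feature extraction for the two forest classifiers.
#
# TSF summarises each random interval by mean, standard deviation and
# least-squares slope. RISE turns one random interval per tree into
# spectral coefficients: autocorrelations, Yule-Walker autoregressive
# coefficients and periodogram magnitudes, concatenated into a vector of
# fixed length (blocks zero-padded / truncated to the layout of the
# full-series interval).

# --- TSF -------------------------------------------------------------------

# Sample `n_intervals` random (start, end) pairs within 1..m.
sample_intervals <- function(m, n_intervals, min_length) {
  starts <- integer(n_intervals)
  ends <- integer(n_intervals)
  for (j in seq_len(n_intervals)) {
    s <- sample.int(m - min_length + 1L, 1L)
    len <- sample.int(m - s + 1L - (min_length - 1L), 1L) + (min_length - 1L)
    starts[j] <- s
    ends[j] <- s + len - 1L
  }
  cbind(start = starts, end = ends)
}

# Summary features (mean, sd, slope per frame) of X[, s:e] for each
# interval; X is segments x frames. Returns segments x (3 * n_intervals).
tsf_features <- function(X, intervals) {
  n_seg <- nrow(X)
  out <- matrix(0, n_seg, 3L * nrow(intervals))
  for (j in seq_len(nrow(intervals))) {
    s <- intervals[j, 1L]
    e <- intervals[j, 2L]
    sub <- X[, s:e, drop = FALSE]
    L <- e - s + 1L
    mu <- rowMeans(sub)
    sdv <- row_sds(sub)
    tt <- seq_len(L) - (L + 1) / 2      # centered frame index
    denom <- sum(tt^2)
    slope <- if (denom > 0) as.numeric(sub %*% tt) / denom else rep(0, n_seg)
    out[, 3L * j - 2L] <- mu
    out[, 3L * j - 1L] <- sdv
    out[, 3L * j] <- slope
  }
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

# --- RISE ------------------------------------------------------------------

# Fixed feature layout defined by the full-series interval of length m.
rise_layout <- function(m, max_acf_lag = 100L, ar_order = 12L) {
  list(acf = min(max_acf_lag, m - 1L),
       ar = min(ar_order, max(1L, floor(m / 4))),
       pgram = floor(m / 2),
       max_acf_lag = max_acf_lag, ar_order = ar_order)
}

# Sample autocorrelation (lags 1..lag_max, denominator n, matching
# stats::acf) computed in one pass via the Wiener-Khinchin theorem.
acf_fft <- function(xc, lag_max) {
  L <- length(xc)
  np <- stats::nextn(2L * L)
  sp <- Mod(stats::fft(c(xc, numeric(np - L))))^2
  acvf <- Re(stats::fft(sp, inverse = TRUE))[seq_len(lag_max + 1L)] / np
  acvf[-1L] / acvf[1L]
}

# Yule-Walker AR(p) coefficients from an autocorrelation sequence
# (Levinson-Durbin recursion; identical to stats::ar.yw on the same ACF).
levinson_durbin <- function(rho, p) {
  a <- numeric(0)
  e <- 1
  for (k in seq_len(p)) {
    lambda <- (rho[k] - sum(a * rev(rho[seq_len(k - 1L)]))) / e
    a <- c(a - lambda * rev(a), lambda)
    e <- e * (1 - lambda^2)
    if (e <= 0) break
  }
  c(a, numeric(p - length(a)))
}

# Spectral feature vector of one series under a fixed layout.
rise_features_one <- function(x, layout) {
  L <- length(x)
  out <- numeric(layout$acf + layout$ar + layout$pgram)
  xc <- x - mean(x)
  if (sum(xc^2) == 0) return(out)   # degenerate: all-zero features

  n_acf <- min(layout$max_acf_lag, L - 1L)
  p <- min(layout$ar_order, max(1L, floor(L / 4)))
  ac <- acf_fft(xc, max(n_acf, p))
  k <- min(n_acf, layout$acf)
  out[seq_len(k)] <- ac[seq_len(k)]

  ar_coef <- levinson_durbin(ac, p)
  k <- min(length(ar_coef), layout$ar)
  out[layout$acf + seq_len(k)] <- ar_coef[seq_len(k)]

  spec <- Mod(stats::fft(xc))^2 / L
  half <- spec[seq(2L, length.out = floor(L / 2))]
  k <- min(length(half), layout$pgram)
  out[layout$acf + layout$ar + seq_len(k)] <- half[seq_len(k)]
  out
}

rise_features <- function(X, interval, layout) {
  sub <- X[, interval[1L]:interval[2L], drop = FALSE]
  out <- t(apply(sub, 1L, rise_features_one, layout = layout))
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}

# One random RISE interval; length >= max(min_length, 2 * ar order target),
# resampling until the constraint is met.
sample_rise_interval <- function(m, min_length = 16L, ar_order = 12L) {
  min_len <- max(min_length, 2L * min(ar_order, max(1L, floor(m / 4))))
  min_len <- min(min_len, m)
  repeat {
    s <- sample.int(m - min_len + 1L, 1L)
    len <- sample.int(m - s + 1L - (min_len - 1L), 1L) + (min_len - 1L)
    if (len >= min_len) return(c(start = s, end = s + len - 1L))
  }
}
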