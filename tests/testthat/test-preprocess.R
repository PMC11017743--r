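make_tm <- function(values, rate = 1, normalized = FALSE) {
  trace_matrix(values, rate, normalized = normalized)
}

test_that("background subtraction is exact element-wise", {
  tm <- make_tm(matrix(100, 2, 5))
  expect_equal(subtract_background(tm, rep(0, 5))$values, tm$values)
  expect_true(all(subtract_background(tm, rep(10, 5))$values == 90))
  expect_error(subtract_background(tm, rep(1, 4)), "length")

  v <- with_seed(21, matrix(rnorm(5 * 50), 5, 50))
  bg <- with_seed(22, rnorm(50))
  got <- subtract_background(make_tm(v), bg)$values
  oracle <- v
  for (i in 1:5) for (t in 1:50) oracle[i, t] <- v[i, t] - bg[t]
  expect_identical(unname(got), unname(oracle))
})

test_that("dF/F0 matches the hand-computed examples", {
  # constant trace -> all zeros
  expect_true(all(delta_f_over_f0(make_tm(matrix(7, 2, 10)))$values == 0))
  # [10,10,20], baseline = first 2 samples at 1 Hz -> [0, 0, 100] percent
  got <- delta_f_over_f0(make_tm(matrix(c(10, 10, 20), 1)),
                         baseline_spec(window = 2))
  expect_equal(unname(got$values[1, ]), c(0, 0, 100))
  expect_true(got$normalized)
  # clamp rule: F0 = 0.5 -> denominator 1, numerator unclamped
  got <- delta_f_over_f0(make_tm(matrix(c(0.5, 0.5, 2), 1)),
                         baseline_spec(window = 2))
  expect_equal(unname(got$values[1, 3]), 100 * (2 - 0.5) / 1)
})

test_that("zero F0 without the clamp is rejected per neuron", {
  tm <- make_tm(matrix(c(0, 0, 5, 10, 10, 20), 2, byrow = TRUE))
  expect_error(
    delta_f_over_f0(tm, baseline_spec(window = 2,
                                      clamp_denominator_below_one = FALSE)),
    "n1")
})

test_that("dF/F0 is invariant to positive rescaling without the clamp", {
  v <- with_seed(23, matrix(rexp(4 * 60) + 5, 4, 60))
  spec <- baseline_spec(clamp_denominator_below_one = FALSE)
  d1 <- delta_f_over_f0(make_tm(v), spec)$values
  d2 <- delta_f_over_f0(make_tm(3.7 * v), spec)$values
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("vectorised dF/F0 agrees with a per-sample oracle in all modes", {
  v <- with_seed(24, matrix(runif(5 * 60, 0.2, 50), 5, 60))
  rate <- 3.65
  for (method in c("fixed_window", "percentile")) {
    for (clamp in c(TRUE, FALSE)) {
      spec <- baseline_spec(method = method,
                            clamp_denominator_below_one = clamp)
      got <- delta_f_over_f0(trace_matrix(v, rate), spec)$values
      oracle <- v * 0
      for (i in seq_len(nrow(v))) {
        f0 <- if (method == "fixed_window") {
          w <- round(spec$window * rate)
          s <- 0
          for (t in seq_len(w)) s <- s + v[i, t]
          s / w
        } else {
          unname(quantile(v[i, ], spec$percentile / 100))
        }
        denom <- if (clamp && f0 < 1) 1 else f0
        for (t in seq_len(ncol(v))) {
          oracle[i, t] <- 100 * (v[i, t] - f0) / denom
        }
      }
      expect_lt(max(abs(got - oracle) / pmax(abs(oracle), 1)), 1e-12)
    }
  }
})

test_that("moving-average smoothing matches a windowed-mean oracle", {
  v <- with_seed(25, matrix(rnorm(3 * 40), 3, 40))
  tm <- trace_matrix(v, 4)   # 4 Hz
  # window of one frame -> identity
  expect_equal(smooth_traces(tm, 0.25)$values, tm$values, tolerance = 1e-12)
  # constant trace unchanged
  expect_true(all(abs(smooth_traces(make_tm(matrix(3, 1, 20), 4), 1)$values - 3)
                  < 1e-12))
  # brute-force shrunk-window oracle, 1 s window = 4 frames
  got <- smooth_traces(tm, 1)$values
  w <- 4
  oracle <- v * 0
  for (i in 1:3) for (t in 1:40) {
    lo <- max(1, t - floor((w - 1) / 2))
    hi <- min(40, t + floor(w / 2))
    oracle[i, t] <- mean(v[i, lo:hi])
  }
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  expect_error(smooth_traces(tm, 100), "longer than the recording")
})

test_that("linear resampling is exact on identity and affine signals", {
  v <- with_seed(26, matrix(rnorm(2 * 50), 2, 50))
  tm <- trace_matrix(v, 10)
  same <- resample_linear(tm, 10)
  expect_equal(same$values, tm$values, tolerance = 1e-12)
  # affine signal: exact at any rate
  tt <- (0:499) / 32
  aff <- trace_matrix(rbind(2 + 3 * tt, -1 + 0.5 * tt), 32)
  res <- resample_linear(aff, 3.65)
  tt2 <- (seq_len(ncol(res$values)) - 1) / 3.65
  expect_lt(max(abs(res$values[1, ] - (2 + 3 * tt2))), 1e-9)
  expect_lt(max(abs(res$values[2, ] - (-1 + 0.5 * tt2))), 1e-9)
})

test_that("downsampling a band-limited sinusoid stays within the interpolation bound", {
  f <- 0.1; A <- 10; src <- 32
  tt <- (0:9632) / src
  tm <- trace_matrix(rbind(A * sin(2 * pi * f * tt)), src)
  res <- resample_linear(tm, 3.65)
  tt2 <- (seq_len(ncol(res$values)) - 1) / 3.65
  bound <- A * (2 * pi * f)^2 * (1 / src)^2 / 8
  expect_lt(max(abs(res$values[1, ] - A * sin(2 * pi * f * tt2))), bound)
  # grid length follows the floor rule
  expect_identical(ncol(res$values),
                   as.integer(floor(9632 / 32 * 3.65)) + 1L)
})

test_that("segment extraction follows head/tail half-open conventions", {
  v <- matrix(rep(1:2400, each = 2), 2, byrow = FALSE)
  tm <- trace_matrix(matrix(1:2400, 1), 3.65)
  head1100 <- extract_segment(tm, "first", 1100)
  expect_equal(unname(head1100$values[1, ]), 1:1100)
  expect_equal(extract_segment(tm, "first", 2400)$values, tm$values)
  tail3 <- extract_segment(trace_matrix(matrix(1:5, 1), 1), "last", 3)
  expect_equal(unname(tail3$values[1, ]), 3:5)
  expect_error(extract_segment(tm, "first", 5000), "2400")
})

test_that("preprocessing preserves neuron identity and count", {
  b <- bench_fixture()
  ops <- list(
    delta_f_over_f0(b$traces),
    smooth_traces(b$dff, 1),
    resample_linear(b$dff, 2),
    extract_segment(b$dff, "last", 500))
  for (out in ops) {
    expect_identical(out$neuron_ids, b$traces$neuron_ids)
    expect_identical(nrow(out$values), nrow(b$traces$values))
  }
  # smoothing then resampling a constant trace returns the constant exactly
  const <- trace_matrix(matrix(42, 2, 400), 10, normalized = TRUE)
  out <- resample_linear(smooth_traces(const, 1), 3.65)
  expect_true(all(abs(out$values - 42) < 1e-12))
})
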