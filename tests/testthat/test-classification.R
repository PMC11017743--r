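test_that("the lidocaine protocol assembles active and inactive segments", {
  cfg <- sim_config(n_neurons = 40, fraction_active = 0.25, duration = 615,
                    lidocaine_time = 305, sampling_rate = 3.65, seed = 41L)
  bench <- generate_benchmark(cfg)
  dff <- delta_f_over_f0(bench$traces)
  verdicts <- bench$labels$label   # 10 SA (peripherally driven) + 30 silent
  ts <- build_training_set(list(list(traces = dff, lidocaine_time = 305,
                                     verdicts = verdicts)),
                           segment_length = 1100)
  expect_identical(ts$metadata$n_active, 10L)
  expect_identical(ts$metadata$n_inactive, 40L)
  expect_equal(ts$metadata$imbalance_ratio, 0.25)
  expect_setequal(unique(ts$provenance),
                  c("pre_lidocaine_sa", "post_lidocaine_sa",
                    "post_lidocaine_non_sa"))
  expect_identical(ts$metadata$segment_length, 1100L)
})

test_that("ambiguous neurons are excluded and empty sets refuse to train", {
  cfg <- sim_config(n_neurons = 10, duration = 615, lidocaine_time = 305,
                    seed = 42L)
  bench <- generate_benchmark(cfg)
  dff <- delta_f_over_f0(bench$traces)
  ts <- build_training_set(list(list(traces = dff, lidocaine_time = 305,
                                     verdicts = rep("ambiguous", 10))))
  expect_identical(ts$metadata$n_segments, 0L)
  expect_error(train_tsf(ts, n_trees = 2), "empty")
  expect_error(train_rise(ts, n_trees = 2), "empty")
})

test_that("too-short recordings are skipped with a message", {
  cfg <- sim_config(n_neurons = 5, duration = 120, seed = 43L)
  dff <- delta_f_over_f0(generate_benchmark(cfg)$traces)
  expect_message(
    ts <- build_training_set(list(list(traces = dff, lidocaine_time = 60,
                                       verdicts = rep("inactive", 5)))),
    "skipped")
  expect_identical(ts$metadata$n_segments, 0L)
})

test_that("single-class training sets are rejected", {
  ts <- training_set(matrix(rnorm(200), 10, 20), rep("inactive", 10),
                     sampling_rate = 1)
  expect_error(train_tsf(ts, n_trees = 2), "both classes")
})

test_that("the TSF slope feature is an exact least-squares fit", {
  feats <- spontact:::tsf_features(rbind(c(0, 1, 2, 3)),
                                   cbind(start = 1L, end = 4L))
  expect_equal(unname(feats[1, ]), c(1.5, sd(0:3), 1))  # mean, SD, slope/frame
})

test_that("TSF separates an easily separable toy problem perfectly", {
  ts <- separable_training_set()
  parts <- split_training_set(ts)
  model <- train_tsf(parts$train, n_trees = 50, seed = 7L)
  expect_equal(holdout_accuracy(model, parts$test_segments,
                                parts$test_labels, ts$sampling_rate), 1)
})

test_that("RISE separates periodic from white-noise traces spectrally", {
  ts <- periodic_training_set()
  parts <- split_training_set(ts)
  model <- train_rise(parts$train, n_trees = 50, seed = 7L)
  expect_gte(holdout_accuracy(model, parts$test_segments,
                              parts$test_labels, ts$sampling_rate), 0.95)
})

test_that("training and prediction are deterministic under a fixed seed", {
  ts <- separable_training_set(n_per_class = 20)
  probe <- trace_matrix(ts$segments[1:10, ], ts$sampling_rate,
                        normalized = TRUE)
  for (trainer in list(train_tsf, train_rise)) {
    m1 <- trainer(ts, n_trees = 10, seed = 3L)
    m2 <- trainer(ts, n_trees = 10, seed = 3L)
    p1 <- predict(m1, probe)
    p2 <- predict(m2, probe)
    expect_identical(p1$label, p2$label)
    expect_identical(p1$vote_fraction, p2$vote_fraction)
  }
})

test_that("degenerate constant traces give all-zero spectral features", {
  layout <- spontact:::rise_layout(200)
  expect_true(all(spontact:::rise_features_one(rep(3, 200), layout) == 0))
})

test_that("the periodogram block peaks at the bin nearest the tone frequency", {
  rate <- 3.65; L <- 1099; f <- 0.3
  tt <- (0:(L - 1)) / rate
  layout <- spontact:::rise_layout(L)
  feats <- spontact:::rise_features_one(sin(2 * pi * f * tt), layout)
  pgram <- feats[(layout$acf + layout$ar + 1):length(feats)]
  freqs <- (seq_len(layout$pgram)) * rate / L
  expect_identical(which.max(pgram), which.min(abs(freqs - f)))
})

test_that("the frame-budget rule is enforced exactly and padding warns", {
  ts <- separable_training_set(n_per_class = 10, len = 1100)
  model <- train_tsf(ts, n_trees = 5, seed = 1L)
  long_probe <- trace_matrix(matrix(rnorm(1101), 1), ts$sampling_rate,
                             normalized = TRUE)
  expect_error(predict(model, long_probe),
               "must not exceed the number of frames used for training")
  short_probe <- trace_matrix(matrix(rnorm(900), 1), ts$sampling_rate,
                              normalized = TRUE)
  expect_warning(p <- predict(model, short_probe), "right-padding")
  expect_identical(nrow(p), 1L)
})

test_that("a tied ensemble vote goes to the inactive class", {
  # two majority-class stumps that always disagree -> vote fraction 0.5
  always <- function(lab) {
    other <- setdiff(c("active", "inactive"), lab)
    spontact:::fit_tree(matrix(0, 4, 1, dimnames = list(NULL, "f1")),
                        c(rep(lab, 3), other))
  }
  iv <- cbind(start = 1L, end = 10L)
  model <- structure(list(
    algorithm = "TSF",
    trees = list(list(intervals = iv, tree = always("active")),
                 list(intervals = iv, tree = always("inactive"))),
    n_trees = 2L, training_length = 10L, sampling_rate = 1,
    class_labels = c("inactive", "active"), seed = 1L,
    normalization_mode = "dff0", format_version = 1L),
    class = "forest_model")
  probe <- trace_matrix(matrix(rnorm(10), 1), 1, normalized = TRUE)
  p <- predict(model, probe)
  expect_equal(p$vote_fraction, 0.5)
  expect_identical(p$label, "inactive")
})

test_that("predictions are per-neuron: permuting input permutes output", {
  ts <- separable_training_set(n_per_class = 20)
  model <- train_tsf(ts, n_trees = 10, seed = 5L)
  probe <- trace_matrix(ts$segments[1:12, ], ts$sampling_rate,
                        normalized = TRUE,
                        neuron_ids = paste0("p", 1:12))
  perm <- with_seed(6, sample(12))
  probe_perm <- trace_matrix(ts$segments[1:12, ][perm, ], ts$sampling_rate,
                             normalized = TRUE,
                             neuron_ids = paste0("p", 1:12)[perm])
  p1 <- predict(model, probe)
  p2 <- predict(model, probe_perm)
  expect_identical(p1$label[match(p2$neuron_id, p1$neuron_id)], p2$label)
})

test_that("faster-rate inputs are auto-downsampled with a warning", {
  ts <- separable_training_set(n_per_class = 10, len = 400, rate = 3.65)
  model <- train_tsf(ts, n_trees = 5, seed = 2L)
  hi <- trace_matrix(matrix(rnorm(3200), 1), 32, normalized = TRUE)
  expect_warning(expect_warning(predict(model, hi), "downsampling"),
                 "right-padding")
})

test_that("stratified k-fold CV partitions every segment exactly once", {
  ts <- separable_training_set(n_per_class = 50, len = 100)
  cv <- crossvalidate(ts, "tsf", k = 5, seed = 9L, n_trees = 10)
  expect_identical(sum(cv$folds$n_test), 100L)
  expect_true(all(cv$folds$n_test == 20L))
  expect_equal(unname(cv$mean["accuracy"]), 1)
})

test_that("CV with too-small classes is rejected", {
  ts <- training_set(matrix(rnorm(6 * 50), 6, 50),
                     c("active", "active", rep("inactive", 4)),
                     sampling_rate = 1)
  expect_error(crossvalidate(ts, "tsf", k = 5, n_trees = 2), "fewer than")
})

test_that("label-shuffled data yields chance-level accuracy", {
  ts <- separable_training_set(n_per_class = 50, len = 100)
  shuffled <- with_seed(77, sample(ts$labels))
  # rebalance to 30:70 so majority-class accuracy is well defined
  shuffled <- with_seed(78, sample(rep(c("active", "inactive"), c(30, 70))))
  ts_null <- training_set(ts$segments, shuffled,
                          sampling_rate = ts$sampling_rate)
  cv <- crossvalidate(ts_null, "tsf", k = 5, seed = 10L, n_trees = 20)
  se <- sd(cv$folds$accuracy) / sqrt(nrow(cv$folds))
  # no information: mean accuracy must not beat the majority class by > 3 SE
  expect_lte(mean(cv$folds$accuracy), 0.70 + 3 * max(se, 0.02))
})

test_that("an 80:20 holdout around CV reports both evaluations", {
  ts <- separable_training_set(n_per_class = 25, len = 100)
  cv <- crossvalidate(ts, "tsf", k = 5, seed = 11L, n_trees = 10,
                      holdout_fraction = 0.2)
  expect_identical(sum(cv$folds$n_test), 40L)
  expect_equal(cv$holdout$accuracy, 1)
})
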