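# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The fixed-seed benchmark recording used throughout: 200 neurons, 25%
# active at 0.1-0.5 Hz, 301 s @ 3.65 Hz, noise 5% dF/F0.
bench_fixture <- function() {
  fixture("bench", {
    b <- generate_benchmark(sim_config(seed = 20230601L))
    b$dff <- delta_f_over_f0(b$traces)
    b$train <- training_set_from_labels(b$dff, b$labels)
    b
  })
}

# Linearly separable toy segments: flat noise vs one large transient.
separable_training_set <- function(n_per_class = 50, len = 200, rate = 3.65,
                                   seed = 4242) {
  with_seed(seed, {
    flat <- matrix(rnorm(n_per_class * len, sd = 2), n_per_class, len)
    burst <- matrix(rnorm(n_per_class * len, sd = 2), n_per_class, len)
    for (i in seq_len(n_per_class)) {
      at <- sample(20:(len - 40), 1)
      burst[i, at:(at + 20)] <- burst[i, at:(at + 20)] +
        50 * exp(-(0:20) / 6)
    }
    training_set(rbind(burst, flat),
                 rep(c("active", "inactive"), each = n_per_class),
                 sampling_rate = rate)
  })
}

# Periodic (0.3 Hz transient train) vs white-noise segments.
periodic_training_set <- function(n_per_class = 50, len = 400, rate = 3.65,
                                  seed = 777) {
  with_seed(seed, {
    tt <- (seq_len(len) - 1) / rate
    wave <- as.numeric((tt %% (1 / 0.3)) < 1) * 20
    periodic <- matrix(rnorm(n_per_class * len, sd = 4), n_per_class, len)
    periodic <- periodic + matrix(wave, n_per_class, len, byrow = TRUE)
    noise <- matrix(rnorm(n_per_class * len, sd = 4), n_per_class, len)
    training_set(rbind(periodic, noise),
                 rep(c("active", "inactive"), each = n_per_class),
                 sampling_rate = rate)
  })
}

# Stratified 80:20 split of a training set; returns list(train, test_idx).
split_training_set <- function(ts, test_fraction = 0.2, seed = 99) {
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(ts$labels), ts$labels), function(i) {
      sample(i, max(1, round(test_fraction * length(i))))
    }), use.names = FALSE)
  })
  keep <- setdiff(seq_along(ts$labels), idx)
  list(train = training_set(ts$segments[keep, , drop = FALSE],
                            ts$labels[keep], ts$provenance[keep],
                            ts$sampling_rate),
       test_segments = ts$segments[idx, , drop = FALSE],
       test_labels = ts$labels[idx])
}

# Score held-out segments with a model; returns accuracy.
holdout_accuracy <- function(model, segments, labels, rate) {
  probe <- trace_matrix(segments, rate, normalized = TRUE,
                        neuron_ids = paste0("p", seq_len(nrow(segments))))
  pred <- suppressWarnings(predict(model, probe))
  truth <- label_set(probe$neuron_ids, labels, source = "simulated_truth")
  evaluation_metrics(confusion(truth, pred))$accuracy
}

with_seed <- spontact:::with_seed
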