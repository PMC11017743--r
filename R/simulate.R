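#' GCaMP indicator kernel
#'
#' Double-exponential (difference of exponentials) calcium-transient kernel
#' used by the forward simulator. The kernel is scaled so that a single
#' action potential produces a transient whose peak equals `unit_amplitude`
#' percent dF/F0. Summed transients are soft-capped at `saturation_ceiling`,
#' reproducing the saturation of slow indicators such as GCaMP6s under
#' sustained firing (in DRG neurons saturation sets in around 0.5 Hz).
#'
#' The defaults describe a slow GCaMP6s-like indicator. They are simulator
#' defaults chosen to reproduce that regime, not measured kinetics, and are
#' fully configurable.
#'
#' @param indicator_name Indicator label (metadata only).
#' @param rise_tau Rise time constant, seconds.
#' @param decay_tau Decay time constant, seconds; must exceed `rise_tau`.
#' @param unit_amplitude Peak dF/F0 (percent) of a single-spike transient.
#' @param saturation_ceiling Soft cap (percent dF/F0) on the summed
#'   transient signal.
#'
#' @return An object of class `gcamp_kernel`.
#' @export
gcamp_kernel <- function(indicator_name = "GCaMP6s", rise_tau = 0.18,
                         decay_tau = 1.5, unit_amplitude = 30,
                         saturation_ceiling = 300) {
  stopifnot(rise_tau > 0, decay_tau > 0, unit_amplitude > 0,
            saturation_ceiling > 0)
  if (decay_tau <= rise_tau) {
    stop("decay_tau must exceed rise_tau", call. = FALSE)
  }
  structure(list(indicator_name = indicator_name, rise_tau = rise_tau,
                 decay_tau = decay_tau, unit_amplitude = unit_amplitude,
                 saturation_ceiling = saturation_ceiling),
            class = "gcamp_kernel")
}

# Kernel evaluated at times t >= 0 (vectorised); peak equals unit_amplitude.
eval_kernel <- function(kernel, t) {
  rt <- kernel$rise_tau
  dt <- kernel$decay_tau
  # analytic peak time of exp(-t/dt) - exp(-t/rt)
  t_peak <- log(dt / rt) * rt * dt / (dt - rt)
  peak <- exp(-t_peak / dt) - exp(-t_peak / rt)
  out <- ifelse(t < 0, 0, (exp(-t / dt) - exp(-t / rt)) / peak)
  kernel$unit_amplitude * out
}

#' Simulation configuration
#'
#' Parameters of the synthetic DRG recording generator. Defaults describe
#' the bundled benchmark: 200 neurons, a quarter spontaneously active at
#' low Poisson rates (0.1-0.5 Hz, the sub-1 Hz regime typical of
#' inflammation-induced spontaneous activity), 301 s recorded at 3.65 Hz,
#' Gaussian noise of 5 percent dF/F0, mild slow drift and occasional
#' shared movement artifacts.
#'
#' @param n_neurons Number of neurons.
#' @param fraction_active Proportion of spontaneously active neurons in
#'   `[0, 1]`.
#' @param firing_rate_range Two-element Hz vector `(low, high)`; each
#'   active neuron's Poisson rate is drawn uniformly from this range.
#' @param sampling_rate Acquisition rate, Hz.
#' @param duration Recording length, seconds. `duration * sampling_rate`
#'   must be at least 200 frames.
#' @param noise_sd Per-frame i.i.d. Gaussian noise SD, percent dF/F0.
#' @param baseline_mean,baseline_sd Per-neuron baseline fluorescence
#'   (arbitrary units): mean and across-neuron SD.
#' @param drift_amplitude Slow per-neuron drift amplitude as a fraction of
#'   baseline.
#' @param artifact_rate Shared movement-artifact events per minute.
#' @param artifact_amplitude Artifact amplitude as a fraction of baseline.
#' @param lidocaine_time Seconds, or `NULL`: time of a nerve block that
#'   silences peripherally driven neurons for the rest of the recording.
#' @param evoked_epochs Optional data frame with columns `onset`, `offset`
#'   (seconds) and `response_probability`: stimulus epochs during which
#'   each neuron responds with the given probability.
#' @param evoked_amplitude Peak dF/F0 (percent) of an evoked response.
#' @param seed Integer seed; the entire simulation is reproducible from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 200, fraction_active = 0.25,
                       firing_rate_range = c(0.1, 0.5),
                       sampling_rate = 3.65, duration = 301,
                       noise_sd = 5, baseline_mean = 100, baseline_sd = 20,
                       drift_amplitude = 0.02, artifact_rate = 0.5,
                       artifact_amplitude = 0.05, lidocaine_time = NULL,
                       evoked_epochs = NULL, evoked_amplitude = 50,
                       seed = 1L) {
  stopifnot(n_neurons >= 1, sampling_rate > 0, duration > 0,
            noise_sd >= 0, baseline_mean > 0, baseline_sd >= 0,
            drift_amplitude >= 0, artifact_rate >= 0,
            artifact_amplitude >= 0, evoked_amplitude >= 0)
  if (fraction_active < 0 || fraction_active > 1) {
    stop("fraction_active must lie in [0, 1]", call. = FALSE)
  }
  if (length(firing_rate_range) != 2L ||
      firing_rate_range[2] < firing_rate_range[1]) {
    stop("firing_rate_range must be (low, high) with high >= low",
         call. = FALSE)
  }
  if (firing_rate_range[1] <= 0) {
    stop("firing rates must be positive", call. = FALSE)
  }
  if (duration * sampling_rate < 200) {
    stop("duration x sampling_rate must be at least 200 frames",
         call. = FALSE)
  }
  if (!is.null(evoked_epochs)) {
    evoked_epochs <- as.data.frame(evoked_epochs)
    stopifnot(all(c("onset", "offset", "response_probability") %in%
                    names(evoked_epochs)))
  }
  structure(list(
    n_neurons = as.integer(n_neurons), fraction_active = fraction_active,
    firing_rate_range = as.numeric(firing_rate_range),
    sampling_rate = sampling_rate, duration = duration, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    drift_amplitude = drift_amplitude, artifact_rate = artifact_rate,
    artifact_amplitude = artifact_amplitude,
    lidocaine_time = lidocaine_time, evoked_epochs = evoked_epochs,
    evoked_amplitude = evoked_amplitude, seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate ground-truth spike trains
#'
#' Draws the per-neuron ground truth underlying a synthetic recording:
#' `round(fraction_active * n_neurons)` neurons are marked active and each
#' receives a homogeneous Poisson spike train at a rate sampled uniformly
#' from `firing_rate_range`. Active neurons are peripherally driven, so if
#' `lidocaine_time` is set their spikes are truncated at that time —
#' mirroring a lidocaine nerve block that silences peripherally generated
#' activity. Inactive neurons have no spontaneous spikes.
#'
#' Spike times are drawn in continuous time, so the truth for a given seed
#' is identical regardless of the sampling rate used to render it.
#'
#' @param config A [sim_config()].
#' @return An object of class `simulation_truth`: a list with `labels`
#'   (character), `spike_times` (list of numeric vectors, seconds),
#'   `rates` (Hz, `NA` for inactive neurons), `peripherally_driven`
#'   (logical), `neuron_ids`, and the draw of evoked responders
#'   (`evoked_responders`, neurons x epochs logical matrix, when the config
#'   has evoked epochs).
#' @export
generate_spike_trains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_neurons
  n_active <- as.integer(round(config$fraction_active * n))
  with_seed(config$seed, {
    active_idx <- if (n_active > 0) sort(sample.int(n, n_active)) else integer(0)
    labels <- rep("inactive", n)
    labels[active_idx] <- "active"
    rates <- rep(NA_real_, n)
    spike_times <- vector("list", n)
    for (i in seq_len(n)) spike_times[[i]] <- numeric(0)
    for (i in active_idx) {
      r <- stats::runif(1, config$firing_rate_range[1],
                        config$firing_rate_range[2])
      rates[i] <- r
      k <- stats::rpois(1, r * config$duration)
      spike_times[[i]] <- sort(stats::runif(k, 0, config$duration))
    }
    peripherally_driven <- labels == "active"
    if (!is.null(config$lidocaine_time)) {
      for (i in which(peripherally_driven)) {
        spike_times[[i]] <-
          spike_times[[i]][spike_times[[i]] < config$lidocaine_time]
      }
    }
    evoked_responders <- NULL
    if (!is.null(config$evoked_epochs)) {
      n_ep <- nrow(config$evoked_epochs)
      evoked_responders <- matrix(FALSE, n, n_ep)
      for (e in seq_len(n_ep)) {
        p <- config$evoked_epochs$response_probability[e]
        evoked_responders[, e] <- stats::runif(n) < p
      }
    }
    structure(list(labels = labels, spike_times = spike_times,
                   rates = rates, peripherally_driven = peripherally_driven,
                   evoked_responders = evoked_responders,
                   neuron_ids = paste0("n", seq_len(n)),
                   config = config),
              class = "simulation_truth")
  })
}

# Shared movement-artifact series: Poisson-timed bursts of a smoothed
# random walk, identical across neurons (fraction-of-baseline units).
artifact_series <- function(config, times) {
  a <- numeric(length(times))
  n_events <- stats::rpois(1, config$artifact_rate * config$duration / 60)
  if (n_events == 0 || config$artifact_amplitude == 0) return(a)
  for (e in seq_len(n_events)) {
    onset <- stats::runif(1, 0, config$duration)
    len_s <- stats::runif(1, 0.5, 3)
    idx <- which(times >= onset & times <= onset + len_s)
    if (length(idx) < 2) next
    walk <- cumsum(stats::rnorm(length(idx)))
    walk <- walk - seq(walk[1], walk[length(walk)], length.out = length(walk))
    m <- max(abs(walk))
    if (m > 0) a[idx] <- a[idx] + config$artifact_amplitude * walk / m
  }
  a
}

#' Render raw fluorescence from ground truth
#'
#' Forward model standing in for the microscope: each neuron's spike train
#' is convolved with the indicator kernel, the summed transient is
#' soft-capped at the kernel's saturation ceiling, evoked responses are
#' added for responding neurons, and the dF/F0-scale signal is mapped onto
#' a raw-fluorescence baseline with slow drift, shared movement artifacts
#' and i.i.d. Gaussian noise:
#' `F(t) = baseline * (1 + drift + artifact) * (1 + S(t)/100) + noise`,
#' clipped at zero.
#'
#' @param truth A `simulation_truth` from [generate_spike_trains()].
#' @param kernel A [gcamp_kernel()].
#' @param config The [sim_config()] used to generate `truth`.
#' @return A raw (non-normalised) [trace_matrix()].
#' @export
render_fluorescence <- function(truth, kernel = gcamp_kernel(),
                                config = truth$config) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(kernel, "gcamp_kernel"))
  n <- config$n_neurons
  nf <- n_frames_for(config$duration, config$sampling_rate)
  times <- frame_times(nf, config$sampling_rate)
  bad <- vapply(truth$spike_times,
                function(s) length(s) && (min(s) < 0 || max(s) > config$duration),
                logical(1))
  if (any(bad)) stop("spike times outside [0, duration]", call. = FALSE)

  with_seed(config$seed + 1L, {
    baselines <- config$baseline_mean +
      config$baseline_sd * stats::rnorm(n)
    baselines <- pmax(baselines, 1e-3)
    # per-neuron slow drift (one sinusoid period comparable to the recording)
    drift_period <- stats::runif(n, 0.5, 1.5) * config$duration
    drift_phase <- stats::runif(n, 0, 2 * pi)
    artifact <- artifact_series(config, times)

    values <- matrix(0, n, nf)
    for (i in seq_len(n)) {
      s_sum <- numeric(nf)
      for (ts in truth$spike_times[[i]]) {
        j0 <- which(times >= ts)[1]
        if (is.na(j0)) next
        idx <- j0:nf
        s_sum[idx] <- s_sum[idx] + eval_kernel(kernel, times[idx] - ts)
      }
      if (!is.null(truth$evoked_responders)) {
        for (e in seq_len(nrow(config$evoked_epochs))) {
          if (!truth$evoked_responders[i, e]) next
          onset <- config$evoked_epochs$onset[e]
          j0 <- which(times >= onset)[1]
          if (is.na(j0)) next
          idx <- j0:nf
          s_sum[idx] <- s_sum[idx] +
            (config$evoked_amplitude / kernel$unit_amplitude) *
              eval_kernel(kernel, times[idx] - onset)
        }
      }
      s_sum <- pmin(s_sum, kernel$saturation_ceiling)
      drift <- if (config$drift_amplitude > 0) {
        config$drift_amplitude *
          sin(2 * pi * times / drift_period[i] + drift_phase[i])
      } else 0
      values[i, ] <- baselines[i] * (1 + drift + artifact) * (1 + s_sum / 100)
    }
    if (config$noise_sd > 0) {
      values <- values + (baselines * config$noise_sd / 100) *
        matrix(stats::rnorm(n * nf), n, nf)
    }
    values[values < 0] <- 0
    trace_matrix(values, config$sampling_rate, normalized = FALSE,
                 neuron_ids = truth$neuron_ids,
                 provenance = list(sprintf("simulate(seed=%d)", config$seed)))
  })
}

#' Generate a benchmark recording with ground truth
#'
#' Convenience bundle: spike-train truth, rendered raw traces, and the
#' matching ground-truth label set (a neuron is `active` iff it has at
#' least one spontaneous spike).
#'
#' @param config A [sim_config()].
#' @param kernel A [gcamp_kernel()].
#' @return A list with elements `traces` (raw [trace_matrix()]),
#'   `labels` ([label_set()], source `"simulated_truth"`) and `truth`.
#' @export
generate_benchmark <- function(config = sim_config(),
                               kernel = gcamp_kernel()) {
  truth <- generate_spike_trains(config)
  traces <- render_fluorescence(truth, kernel, config)
  n_spont <- vapply(truth$spike_times, length, integer(1))
  labels <- label_set(truth$neuron_ids,
                      ifelse(n_spont >= 1, "active", "inactive"),
                      source = "simulated_truth")
  list(traces = traces, labels = labels, truth = truth)
}
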