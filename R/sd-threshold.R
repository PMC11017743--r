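#' Standard-deviation threshold rule
#'
#' The baseline comparator for spontaneous activity: a neuron is called
#' active when its dF/F0 trace exceeds `mean + k * SD` of its own trace on
#' more than `min_occasions` occasions within a `window`-second evaluation
#' window (defaults: 2.5 x SD, more than 30 occasions in 5 minutes).
#'
#' An "occasion" defaults to an upward crossing — a sample above the
#' threshold whose predecessor is at or below it — so a single long
#' transient counts once rather than once per sample; `"sample_above"`
#' counts every suprathreshold sample, for sensitivity analysis.
#'
#' @param k SD multiplier (> 0).
#' @param min_occasions Occasion count that must be strictly exceeded.
#' @param window Evaluation window, seconds.
#' @param occasion_definition `"upward_crossing"` or `"sample_above"`.
#' @return An object of class `sd_rule`.
#' @export
sd_rule <- function(k = 2.5, min_occasions = 30, window = 300,
                    occasion_definition = c("upward_crossing",
                                            "sample_above")) {
  occasion_definition <- match.arg(occasion_definition)
  stopifnot(k > 0, min_occasions >= 1, window > 0)
  structure(list(k = k, min_occasions = min_occasions, window = window,
                 occasion_definition = occasion_definition),
            class = "sd_rule")
}

count_occasions <- function(x, threshold, definition) {
  above <- x > threshold
  if (definition == "sample_above") return(sum(above))
  n <- length(x)
  sum(above[-1] & !above[-n])
}

#' Classify neurons by the SD-threshold rule
#'
#' Applies [sd_rule()] per neuron. The threshold uses the mean and sample
#' (n-1) SD of the neuron's own trace over the evaluation window. For
#' recordings longer than the window, the first window is evaluated
#' (matching the training-segment convention); for shorter recordings,
#' `min_occasions` is scaled down proportionally and rounded up. A
#' zero-variance trace is labelled inactive with a warning.
#'
#' @param traces A normalised [trace_matrix()].
#' @param rule An [sd_rule()].
#' @return A [label_set()] (source `"predicted_sd"`) with an attached
#'   per-neuron report (`attr(x, "report")`): SD, threshold, occasion
#'   count and effective occasion cutoff.
#' @export
sd_classify <- function(traces, rule = sd_rule()) {
  stopifnot(inherits(traces, "trace_matrix"), inherits(rule, "sd_rule"))
  assert_normalized(traces, "sd_classify")
  nf <- n_frames(traces)
  w_frames <- min(nf, max(2L, round(rule$window * traces$sampling_rate)))
  dur_s <- w_frames / traces$sampling_rate
  min_occ <- if (dur_s < rule$window) {
    ceiling(rule$min_occasions * dur_s / rule$window)
  } else {
    rule$min_occasions
  }
  v <- traces$values[, seq_len(w_frames), drop = FALSE]
  sds <- row_sds(v)
  means <- rowMeans(v)
  thresholds <- means + rule$k * sds
  occasions <- integer(nrow(v))
  labels <- character(nrow(v))
  degenerate <- sds == 0
  for (i in seq_len(nrow(v))) {
    if (degenerate[i]) {
      occasions[i] <- 0L
      labels[i] <- "inactive"
      next
    }
    occasions[i] <- count_occasions(v[i, ], thresholds[i],
                                    rule$occasion_definition)
    labels[i] <- if (occasions[i] > min_occ) "active" else "inactive"
  }
  if (any(degenerate)) {
    warning(sum(degenerate),
            " zero-variance trace(s) labelled inactive (degenerate)",
            call. = FALSE)
  }
  out <- label_set(traces$neuron_ids, labels, source = "predicted_sd")
  attr(out, "report") <- data.frame(
    neuron_id = traces$neuron_ids, sd = sds, threshold = thresholds,
    occasions = occasions, min_occasions = min_occ,
    stringsAsFactors = FALSE)
  out
}

#' Per-neuron SD summary
#'
#' Reports each neuron's sample SD (percent dF/F0) and, when labels are
#' supplied, the fraction of each label class whose SD falls below a
#' cutoff — the style of summary used to show that active and inactive
#' SD distributions overlap too much for variance alone to separate them.
#'
#' @param traces A normalised [trace_matrix()].
#' @param labels Optional [label_set()] aligned with `traces`.
#' @param sd_cutoff SD cutoff, percent dF/F0 (default 15).
#' @return A list with `per_neuron` (data frame: `neuron_id`, `sd`) and,
#'   when labels are given, `fraction_below` (data frame: `label`,
#'   `fraction_below_cutoff`, `n`) and the `sd_cutoff` used.
#' @export
sd_statistics <- function(traces, labels = NULL, sd_cutoff = 15) {
  stopifnot(inherits(traces, "trace_matrix"))
  assert_normalized(traces, "sd_statistics")
  per_neuron <- data.frame(neuron_id = traces$neuron_ids,
                           sd = row_sds(traces$values),
                           stringsAsFactors = FALSE)
  out <- list(per_neuron = per_neuron, sd_cutoff = sd_cutoff)
  if (!is.null(labels)) {
    merged <- merge(per_neuron, as.data.frame(labels)[, c("neuron_id", "label")],
                    by = "neuron_id")
    frac <- do.call(rbind, lapply(split(merged, merged$label), function(d) {
      data.frame(label = d$label[1],
                 fraction_below_cutoff = mean(d$sd < sd_cutoff),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
    rownames(frac) <- NULL
    out$fraction_below <- frac
  }
  out
}
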