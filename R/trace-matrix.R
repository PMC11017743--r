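#' Fluorescence trace matrix
#'
#' The package's central container: a neurons-by-frames matrix of
#' fluorescence values (arbitrary units for raw data, percent dF/F0 once
#' normalised) together with the acquisition rate and stable neuron
#' identifiers. Every preprocessing operation consumes and returns a
#' `trace_matrix`, appending a record of itself to the provenance log.
#'
#' @param values Numeric matrix, rows = neurons, columns = frames. All
#'   values must be finite and there must be at least 2 frames.
#' @param sampling_rate Acquisition rate in Hz (> 0).
#' @param normalized Logical; `TRUE` once values are percent dF/F0.
#' @param neuron_ids Character vector of unique per-neuron identifiers;
#'   defaults to `"n1"`, `"n2"`, ...
#' @param provenance List of character strings recording the operations
#'   applied so far.
#'
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, sampling_rate, normalized = FALSE,
                         neuron_ids = NULL, provenance = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("trace values must all be finite", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("a trace matrix needs at least 2 frames", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  if (is.null(neuron_ids)) {
    neuron_ids <- paste0("n", seq_len(nrow(values)))
  }
  neuron_ids <- as.character(neuron_ids)
  if (length(neuron_ids) != nrow(values) || anyDuplicated(neuron_ids)) {
    stop("neuron_ids must be unique and match the number of rows",
         call. = FALSE)
  }
  rownames(values) <- neuron_ids
  structure(
    list(values = values,
         sampling_rate = as.numeric(sampling_rate),
         normalized = isTRUE(normalized),
         neuron_ids = neuron_ids,
         provenance = provenance),
    class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf(
    "<trace_matrix> %d neurons x %d frames @ %.4g Hz (%s, %.1f s)\n",
    nrow(x$values), ncol(x$values), x$sampling_rate,
    if (x$normalized) "percent dF/F0" else "raw fluorescence",
    (ncol(x$values) - 1) / x$sampling_rate))
  if (length(x$provenance)) {
    cat("provenance:", paste(unlist(x$provenance), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

n_neurons <- function(x) nrow(x$values)
n_frames <- function(x) ncol(x$values)

trace_duration <- function(x) (n_frames(x) - 1) / x$sampling_rate

log_op <- function(x, op, ...) {
  args <- c(...)
  entry <- if (length(args)) {
    paste0(op, "(", paste(names(args), args, sep = "=", collapse = ", "), ")")
  } else {
    op
  }
  x$provenance <- c(x$provenance, entry)
  x
}

assert_normalized <- function(x, op) {
  if (!x$normalized) {
    stop(sprintf("%s expects dF/F0-normalised traces; run delta_f_over_f0() first", op),
         call. = FALSE)
  }
  invisible(x)
}

#' Per-neuron activity labels
#'
#' A data frame of per-neuron labels (`active`, `inactive` or `ambiguous`)
#' with the labelling source, used both for ground truth (lidocaine verdicts,
#' simulation truth) and classifier predictions.
#'
#' @param neuron_ids Character vector of neuron identifiers (unique).
#' @param labels Character vector in `{active, inactive, ambiguous}`.
#' @param source Labelling source, e.g. `"simulated_truth"`,
#'   `"predicted_rise"`, `"ground_truth_lidocaine"`.
#' @param vote_fraction Optional numeric vector of ensemble vote fractions.
#'
#' @return A data frame of class `label_set` with columns `neuron_id`,
#'   `label`, `source` (and `vote_fraction` when supplied).
#' @export
label_set <- function(neuron_ids, labels, source = "unknown",
                      vote_fraction = NULL) {
  neuron_ids <- as.character(neuron_ids)
  labels <- as.character(labels)
  if (length(labels) != length(neuron_ids)) {
    stop("labels and neuron_ids lengths differ", call. = FALSE)
  }
  if (anyDuplicated(neuron_ids)) {
    stop("neuron_ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("active", "inactive", "ambiguous"))
  if (length(bad)) {
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(neuron_id = neuron_ids, label = labels,
                    source = source, stringsAsFactors = FALSE)
  if (!is.null(vote_fraction)) out$vote_fraction <- as.numeric(vote_fraction)
  class(out) <- c("label_set", "data.frame")
  out
}
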