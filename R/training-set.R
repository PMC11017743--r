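#' Training set of fixed-length trace segments
#'
#' Container for classifier training data: equal-length dF/F0 segments,
#' their activity labels, and the provenance of each segment (which part
#' of which protocol it came from).
#'
#' @param segments Numeric matrix, segments x frames.
#' @param labels Character vector in `{active, inactive}`.
#' @param provenance Character vector, one entry per segment.
#' @param sampling_rate Acquisition rate of the segments, Hz.
#' @return An object of class `training_set`. Its `metadata` element
#'   records class counts and the active:inactive imbalance ratio.
#' @export
training_set <- function(segments, labels, provenance = "unspecified",
                         sampling_rate) {
  segments <- as.matrix(segments)
  storage.mode(segments) <- "double"
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(segments), sampling_rate > 0)
  bad <- setdiff(unique(labels), c("active", "inactive"))
  if (length(bad)) {
    stop("training labels must be active/inactive; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  provenance <- rep_len(as.character(provenance), nrow(segments))
  n_active <- sum(labels == "active")
  n_inactive <- sum(labels == "inactive")
  structure(list(
    segments = segments, labels = labels, provenance = provenance,
    sampling_rate = as.numeric(sampling_rate),
    metadata = list(
      n_segments = nrow(segments), segment_length = ncol(segments),
      n_active = n_active, n_inactive = n_inactive,
      imbalance_ratio = if (n_inactive > 0) n_active / n_inactive else NA_real_)),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "<training_set> %d segments x %d frames @ %.4g Hz (%d active, %d inactive, ratio %.3f)\n",
    x$metadata$n_segments, x$metadata$segment_length, x$sampling_rate,
    x$metadata$n_active, x$metadata$n_inactive, x$metadata$imbalance_ratio))
  invisible(x)
}

#' Build a training set from lidocaine-anchored recordings
#'
#' Implements the ground-truth training protocol: in each recording a
#' nerve block (lidocaine) is applied mid-recording, silencing
#' peripherally driven spontaneous activity. For every neuron an observer
#' verdict states whether it was spontaneously active (`"active"`: clear
#' activity before the block, silent after), `"inactive"` (silent
#' throughout) or `"ambiguous"` (excluded — its activity may originate at
#' a site the block does not reach).
#'
#' Segments are assembled as:
#' * **active** — the first `segment_length` frames (pre-block head) of
#'   every `"active"` neuron;
#' * **inactive** — the last `segment_length` frames (post-block tail) of
#'   every `"active"` neuron, plus the post-block tail of every
#'   `"inactive"` neuron (so the inactive class also contains baseline
#'   traces of neuron types that were never active).
#'
#' Recordings shorter than `2 * segment_length` frames, or whose head/tail
#' segments would straddle the block, are skipped with a message.
#'
#' @param recordings A list; each element a list with `traces` (normalised
#'   [trace_matrix()]), `lidocaine_time` (seconds) and `verdicts`
#'   (character per neuron: active/inactive/ambiguous).
#' @param segment_length Segment length in frames (default 1100, about 5
#'   minutes at 3.65 Hz).
#' @return A [training_set()].
#' @export
build_training_set <- function(recordings, segment_length = 1100) {
  seg_list <- list()
  lab_list <- character(0)
  prov_list <- character(0)
  rate <- NULL
  for (r in seq_along(recordings)) {
    rec <- recordings[[r]]
    tr <- rec$traces
    stopifnot(inherits(tr, "trace_matrix"))
    assert_normalized(tr, "build_training_set")
    verdicts <- as.character(rec$verdicts)
    stopifnot(length(verdicts) == n_neurons(tr))
    if (is.null(rate)) rate <- tr$sampling_rate
    if (abs(tr$sampling_rate - rate) / rate > 0.01) {
      stop("recordings have inconsistent sampling rates", call. = FALSE)
    }
    nf <- n_frames(tr)
    if (nf < 2 * segment_length) {
      message(sprintf(
        "recording %d skipped: %d frames < 2 x segment_length (%d)",
        r, nf, 2 * segment_length))
      next
    }
    lt <- rec$lidocaine_time
    head_end_t <- (segment_length - 1) / tr$sampling_rate
    tail_start_t <- (nf - segment_length) / tr$sampling_rate
    if (!is.null(lt) && (head_end_t >= lt || tail_start_t <= lt)) {
      message(sprintf(
        "recording %d skipped: head/tail segments straddle the lidocaine event",
        r))
      next
    }
    head_v <- tr$values[, seq_len(segment_length), drop = FALSE]
    tail_v <- tr$values[, (nf - segment_length + 1L):nf, drop = FALSE]
    act <- which(verdicts == "active")
    inact <- which(verdicts == "inactive")
    if (length(act)) {
      seg_list <- c(seg_list, list(head_v[act, , drop = FALSE]))
      lab_list <- c(lab_list, rep("active", length(act)))
      prov_list <- c(prov_list, rep("pre_lidocaine_sa", length(act)))
      seg_list <- c(seg_list, list(tail_v[act, , drop = FALSE]))
      lab_list <- c(lab_list, rep("inactive", length(act)))
      prov_list <- c(prov_list, rep("post_lidocaine_sa", length(act)))
    }
    if (length(inact)) {
      seg_list <- c(seg_list, list(tail_v[inact, , drop = FALSE]))
      lab_list <- c(lab_list, rep("inactive", length(inact)))
      prov_list <- c(prov_list, rep("post_lidocaine_non_sa", length(inact)))
    }
  }
  if (!length(seg_list)) {
    return(structure(list(
      segments = matrix(0, 0, segment_length), labels = character(0),
      provenance = character(0), sampling_rate = rate %||% NA_real_,
      metadata = list(n_segments = 0L, segment_length = segment_length,
                      n_active = 0L, n_inactive = 0L,
                      imbalance_ratio = NA_real_)),
      class = "training_set"))
  }
  training_set(do.call(rbind, seg_list), lab_list, prov_list, rate)
}

#' Build a training set directly from labelled traces
#'
#' For simulated recordings the per-neuron ground truth is known, so each
#' neuron's whole trace becomes one training segment with its truth label.
#' Ambiguous neurons are excluded.
#'
#' @param traces A normalised [trace_matrix()].
#' @param labels A [label_set()] aligned with `traces`.
#' @return A [training_set()].
#' @export
training_set_from_labels <- function(traces, labels) {
  stopifnot(inherits(traces, "trace_matrix"))
  assert_normalized(traces, "training_set_from_labels")
  lab <- as.data.frame(labels)
  lab <- lab[match(traces$neuron_ids, lab$neuron_id), ]
  keep <- lab$label %in% c("active", "inactive")
  training_set(traces$values[keep, , drop = FALSE], lab$label[keep],
               provenance = lab$source[keep],
               sampling_rate = traces$sampling_rate)
}
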