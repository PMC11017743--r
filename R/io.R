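#' Read and write trace matrices
#'
#' Traces are stored as comma-separated text: one row per neuron, an
#' optional leading `neuron_id` column, one column per frame. Metadata
#' (sampling rate, normalisation state, provenance) lives in a JSON
#' sidecar at `<path>.json`; if the sidecar is missing the sampling rate
#' must be supplied explicitly.
#'
#' @param path File path of the CSV.
#' @param sampling_rate Hz; overrides / replaces the sidecar value.
#' @param normalized Normalisation state when no sidecar is present.
#' @return [read_traces()] returns a [trace_matrix()];
#'   [write_traces()] returns `path` invisibly.
#' @export
read_traces <- function(path, sampling_rate = NULL, normalized = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  widths <- utils::count.fields(path, sep = ",")
  if (length(unique(widths)) > 1L) {
    stop(sprintf("ragged rows in %s: line %d has %d fields, line 1 has %d",
                 path, which(widths != widths[1])[1],
                 widths[widths != widths[1]][1], widths[1]), call. = FALSE)
  }
  first <- strsplit(readLines(path, n = 1L), ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(
    setdiff(first, c("neuron_id", ""))))))
  raw <- utils::read.csv(path, header = has_header, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- NULL
  if ("neuron_id" %in% names(raw)) {
    ids <- as.character(raw$neuron_id)
    raw$neuron_id <- NULL
  } else if (!is.numeric(raw[[1]]) &&
             any(is.na(suppressWarnings(as.numeric(raw[[1]]))))) {
    ids <- as.character(raw[[1]])
    raw[[1]] <- NULL
  }
  for (j in seq_along(raw)) {
    col <- suppressWarnings(as.numeric(raw[[j]]))
    if (any(is.na(col) & !is.na(raw[[j]]))) {
      bad_row <- which(is.na(col) & !is.na(raw[[j]]))[1]
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   bad_row, j + !is.null(ids), path), call. = FALSE)
    }
    if (anyNA(col)) {
      stop(sprintf("missing value at row %d, column %d of %s",
                   which(is.na(col))[1], j + !is.null(ids), path),
           call. = FALSE)
    }
    raw[[j]] <- col
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  rate <- sampling_rate %||% meta$sampling_rate
  if (is.null(rate)) {
    stop("no sampling rate: supply `sampling_rate` or a metadata sidecar",
         call. = FALSE)
  }
  m <- as.matrix(raw)
  dimnames(m) <- NULL
  trace_matrix(m, rate,
               normalized = normalized %||% meta$normalized %||% FALSE,
               neuron_ids = ids %||% meta$neuron_ids,
               provenance = as.list(meta$provenance %||% list()))
}

#' @rdname read_traces
#' @param traces A [trace_matrix()] to write.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  df <- data.frame(neuron_id = traces$neuron_ids, traces$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("neuron_id", paste0("f", seq_len(n_frames(traces))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = traces$sampling_rate,
         normalized = traces$normalized,
         neuron_ids = traces$neuron_ids,
         provenance = unlist(traces$provenance) %||% character(0)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write label tables
#'
#' Label tables are CSV with columns `neuron_id`, `label` and optionally
#' `source` and `vote_fraction`.
#'
#' @param path CSV file path.
#' @return [read_labels()] returns a [label_set()].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("neuron_id", "label") %in% names(df)))
  label_set(df$neuron_id, df$label,
            source = if ("source" %in% names(df)) df$source else "unknown",
            vote_fraction = if ("vote_fraction" %in% names(df))
              df$vote_fraction else NULL)
}

#' @rdname read_labels
#' @param labels A [label_set()] to write.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' Save and load trained forest models
#'
#' A model archive is a directory holding `metadata.json` (format
#' version, algorithm, hyperparameters, training length, sampling rate,
#' class labels, seed) and `trees.rds` (the fitted trees and their
#' interval definitions). Loading verifies the format version and refuses
#' mismatches.
#'
#' @param model A `forest_model`.
#' @param path Directory to create.
#' @return [load_model()] returns the `forest_model`;
#'   [save_model()] returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "forest_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- model[c("algorithm", "n_trees", "training_length",
                  "sampling_rate", "class_labels", "seed",
                  "normalization_mode", "format_version")]
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model[c("trees", "feature_layout")],
          file.path(path, "trees.rds"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("not a model archive (no metadata.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$format_version), MODEL_FORMAT_VERSION)) {
    stop(sprintf(
      "model archive format version %s does not match supported version %d",
      meta$format_version %||% "<missing>", MODEL_FORMAT_VERSION),
      call. = FALSE)
  }
  store <- readRDS(file.path(path, "trees.rds"))
  structure(c(list(algorithm = meta$algorithm, trees = store$trees,
                   n_trees = as.integer(meta$n_trees),
                   training_length = as.integer(meta$training_length),
                   sampling_rate = meta$sampling_rate,
                   class_labels = meta$class_labels,
                   seed = as.integer(meta$seed),
                   normalization_mode = meta$normalization_mode,
                   format_version = as.integer(meta$format_version)),
              if (!is.null(store$feature_layout))
                list(feature_layout = store$feature_layout)),
            class = "forest_model")
}

#' Read a stimulus-epoch table
#'
#' CSV with columns `onset`, `offset` (seconds) and optionally
#' `modality`.
#'
#' @param path CSV file path.
#' @return A [stimulus_protocol()].
#' @export
read_stimulus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stimulus_protocol(df[, c("onset", "offset")],
                    modality = if ("modality" %in% names(df))
                      df$modality[1] else "unspecified")
}
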