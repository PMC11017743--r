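#' Confusion counts between truth and prediction
#'
#' Matches two [label_set()]s on `neuron_id` (neurons labelled
#' `ambiguous` in either set are dropped, with the dropped count recorded)
#' and tallies the four counts against the ground truth: TP = truly
#' active neurons called active, FP = truly inactive called active,
#' TN = truly inactive called inactive, FN = truly active called
#' inactive.
#'
#' @param truth Ground-truth [label_set()].
#' @param predicted Predicted [label_set()].
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN`, `n` and `n_ambiguous_dropped`.
#' @export
confusion <- function(truth, predicted) {
  t_df <- as.data.frame(truth)[, c("neuron_id", "label")]
  p_df <- as.data.frame(predicted)[, c("neuron_id", "label")]
  m <- merge(t_df, p_df, by = "neuron_id", suffixes = c("_truth", "_pred"))
  if (!nrow(m)) {
    stop("truth and prediction share no neuron_ids", call. = FALSE)
  }
  amb <- m$label_truth == "ambiguous" | m$label_pred == "ambiguous"
  m <- m[!amb, ]
  if (!nrow(m)) {
    stop("no unambiguous neurons to compare", call. = FALSE)
  }
  structure(list(
    TP = sum(m$label_truth == "active" & m$label_pred == "active"),
    FP = sum(m$label_truth == "inactive" & m$label_pred == "active"),
    TN = sum(m$label_truth == "inactive" & m$label_pred == "inactive"),
    FN = sum(m$label_truth == "active" & m$label_pred == "inactive"),
    n = nrow(m), n_ambiguous_dropped = sum(amb)),
    class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`. A ratio with a zero
#' denominator is reported as `NA` with the corresponding
#' `undefined` flag set — never silently as 0 or 1.
#'
#' @param counts A `confusion_counts` object (or list with TP/FP/TN/FN).
#' @return List with `sensitivity`, `specificity`, `accuracy`, the raw
#'   counts, and an `undefined` character vector naming any undefined
#'   metrics.
#' @export
evaluation_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / total,
       counts = list(TP = tp, FP = fp, TN = tn, FN = fn),
       undefined = undefined)
}

#' Proportion of active neurons
#'
#' The per-recording summary statistic: active / (active + inactive),
#' ambiguous neurons excluded.
#'
#' @param labels A [label_set()].
#' @return List with `proportion`, `n_active`, `n` (unambiguous count).
#' @export
proportion_active <- function(labels) {
  lab <- as.data.frame(labels)$label
  lab <- lab[lab != "ambiguous"]
  if (!length(lab)) stop("no unambiguous neurons", call. = FALSE)
  list(proportion = mean(lab == "active"),
       n_active = sum(lab == "active"), n = length(lab))
}

#' Compare proportion-active between two groups of recordings
#'
#' Unpaired two-sample t test on per-recording proportions (pooled
#' variance Student test by default; set `var_equal = FALSE` for Welch).
#' Group summaries are mean +/- SEM (SD / sqrt(n) over recordings). When
#' both groups are constant with equal means the comparison is
#' uninformative: t = 0, p = 1, flagged.
#'
#' @param group_a,group_b Numeric vectors of per-recording proportions
#'   (each of length >= 2).
#' @param var_equal Pooled-variance Student test (default `TRUE`).
#' @return List with `t`, `p_value`, `df`, `mean_a`, `sem_a`, `mean_b`,
#'   `sem_b`, `degenerate` flag.
#' @export
compare_groups <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(mean_a = mean(group_a), sem_a = sem(group_a),
              mean_b = mean(group_b), sem_b = sem(group_b),
              degenerate = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      out$t <- 0; out$p_value <- 1
      out$df <- length(group_a) + length(group_b) - 2
      out$degenerate <- TRUE
      return(out)
    }
    # constant but different groups: infinite evidence under the model
    out$t <- Inf * sign(mean(group_a) - mean(group_b))
    out$p_value <- 0
    out$df <- length(group_a) + length(group_b) - 2
    out$degenerate <- TRUE
    return(out)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  out$t <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$df <- unname(tt$parameter)
  out
}
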