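#' Convert detection p-values to boolean calls
#'
#' Detection-above-background p-values (one per probe-sample pair) are
#' thresholded into the boolean call matrix the filter consumes.
#'
#' @param p_matrix numeric matrix of detection p-values in [0, 1].
#' @param alpha detection threshold; a pair is called detected when p < alpha.
#' @return logical matrix of the same shape.
#' @export
detection_calls <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (any(p_matrix < 0 | p_matrix > 1, na.rm = TRUE))
    stop("detection p-values must lie in [0, 1]", call. = FALSE)
  p_matrix < alpha
}

#' Filter probes by species flag and detection
#'
#' Retains probes flagged human (unless `keep_nonhuman`) that were detected
#' above background in at least one sample; everything else is removed.
#'
#' @param exp an [expression_experiment()].
#' @param keep_nonhuman keep probes whose `human` flag is `FALSE`?
#' @return list with `experiment` (the filtered `ExpressionExperiment`) and
#'   `summary`, a `filter_summary` with `total`, `retained` and `pct`
#'   (retained percentage, truncated to 2 decimals).
#' @examples
#' # a 3-probe toy where one probe is never detected
#' m <- matrix(rnorm(6, 8), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' det <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), 3, 2,
#'               dimnames = dimnames(m))
#' des <- data.frame(sample = c("s1", "s2"), patient = c("c1", "c2"),
#'                   phase = "control", sex = "F", treatment = "none")
#' ex <- expression_experiment(m, det, des)
#' detection_filter(ex)$summary
#' @export
detection_filter <- function(exp, keep_nonhuman = FALSE) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  total <- nrow(exp$intensities)
  if (total == 0L) stop("empty intensity matrix", call. = FALSE)
  human_ok <- exp$probe_meta$human | keep_nonhuman
  ever_detected <- rowSums(exp$detected, na.rm = TRUE) >= 1L
  keep <- rownames(exp$intensities)[human_ok & ever_detected]
  summary <- filter_summary(total, length(keep))
  if (length(keep) == 0L) {
    warning("all probes removed by detection filter", call. = FALSE)
    out <- exp
    out$intensities <- exp$intensities[keep, , drop = FALSE]
    out$detected <- exp$detected[keep, , drop = FALSE]
    out$probe_meta <- exp$probe_meta[0L, , drop = FALSE]
    return(list(experiment = out, summary = summary))
  }
  list(experiment = subset_experiment(exp, probes = keep), summary = summary)
}

filter_summary <- function(total, retained) {
  # truncated, not rounded: 1113/1769 reports as 62.91
  structure(list(total = total, retained = retained,
                 pct = floor(100 * 100 * retained / total) / 100),
            class = "filter_summary")
}

#' @export
print.filter_summary <- function(x, ...) {
  cat(sprintf("%d / %d probes retained (%.2f%%)\n", x$retained, x$total, x$pct))
  invisible(x)
}

#' Quantile normalization of a log2-intensity matrix
#'
#' Forces every sample (column) onto the identical empirical distribution:
#' the row-wise mean of the column-sorted values, re-assigned by within-column
#' rank, with ties receiving the mean of their candidate quantile values.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param intensities numeric matrix, probes x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(intensities) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  if (anyNA(intensities))
    stop("missing values present: impute or remove them upstream before normalizing",
         call. = FALSE)
  out <- limma::normalizeQuantiles(intensities, ties = TRUE)
  dimnames(out) <- dimnames(intensities)
  out
}

#' Preprocess an experiment: detection calls, normalization, probe filter
#'
#' Applies the standard order detect -> normalize -> filter (normalization
#' over all probes, filtering afterwards); set `normalize_after_filter` to
#' normalize only the retained probes.
#'
#' @param exp an [expression_experiment()].
#' @param keep_nonhuman passed to [detection_filter()].
#' @param normalize_after_filter logical; reverse the normalize/filter order.
#' @return list with `experiment` and the detection-filter `summary`.
#' @export
preprocess_experiment <- function(exp, keep_nonhuman = FALSE,
                                  normalize_after_filter = FALSE) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  if (!normalize_after_filter)
    exp$intensities <- quantile_normalize(exp$intensities)
  res <- detection_filter(exp, keep_nonhuman = keep_nonhuman)
  if (normalize_after_filter && nrow(res$experiment$intensities) > 0L)
    res$experiment$intensities <- quantile_normalize(res$experiment$intensities)
  res
}
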