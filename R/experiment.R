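#' Probe-level expression experiment
#'
#' The container every upstream stage transforms: a probe x sample matrix of
#' log2 intensities, a same-shape logical matrix of detection calls (detected
#' above background), a sample design table, and per-probe annotation.
#'
#' @param intensities numeric matrix of log2 intensities, probes in rows
#'   (rownames = probe ids), samples in columns (colnames = sample ids).
#' @param detected logical matrix with identical dimnames: `TRUE` where the
#'   probe was called detected above background in that sample.
#' @param design data.frame with columns `sample`, `patient`, `phase`
#'   (one of `"relapse"`, `"remission"`, `"control"`), `sex` (`"F"`/`"M"`),
#'   `treatment`. One row per sample; every relapse sample's patient must
#'   also own a remission sample.
#' @param probe_meta data.frame with columns `probe`, `class` (one of
#'   `"miRNA"`, `"snoRNA"`, `"other"`), `human` (logical species flag).
#'   Defaults to all-human `"other"` probes.
#' @return An object of class `ExpressionExperiment` (a list with the four
#'   validated components).
#' @export
expression_experiment <- function(intensities, detected, design, probe_meta = NULL) {
  intensities <- as.matrix(intensities)
  detected <- as.matrix(detected)
  if (!is.numeric(intensities)) stop("intensities must be numeric", call. = FALSE)
  if (nrow(intensities) == 0L || ncol(intensities) == 0L)
    stop("empty intensity matrix", call. = FALSE)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensities must carry probe rownames and sample colnames", call. = FALSE)
  if (!identical(dim(intensities), dim(detected)) ||
      !identical(dimnames(intensities), dimnames(detected)))
    stop("intensities and detected must share identical probe/sample indexing",
         call. = FALSE)
  mode(detected) <- "logical"

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample", "patient", "phase", "sex", "treatment")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$sample))
    stop("every sample id must appear exactly once in design", call. = FALSE)
  if (!setequal(design$sample, colnames(intensities)))
    stop("design samples and matrix columns disagree", call. = FALSE)
  design <- design[match(colnames(intensities), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  bad <- setdiff(unique(design$phase), c("relapse", "remission", "control"))
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rel <- design$patient[design$phase == "relapse"]
  rem <- design$patient[design$phase == "remission"]
  orphan <- setdiff(rel, rem)
  if (length(orphan))
    stop("relapse patient(s) without a remission sample: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  if (is.null(probe_meta)) {
    probe_meta <- data.frame(probe = rownames(intensities),
                             class = "other", human = TRUE,
                             stringsAsFactors = FALSE)
  }
  probe_meta <- as.data.frame(probe_meta, stringsAsFactors = FALSE)
  if (!all(c("probe", "class", "human") %in% names(probe_meta)))
    stop("probe_meta needs columns probe, class, human", call. = FALSE)
  if (!setequal(probe_meta$probe, rownames(intensities)))
    stop("probe_meta probes and matrix rows disagree", call. = FALSE)
  probe_meta <- probe_meta[match(rownames(intensities), probe_meta$probe), , drop = FALSE]
  rownames(probe_meta) <- NULL

  structure(list(intensities = intensities, detected = detected,
                 design = design, probe_meta = probe_meta),
            class = "ExpressionExperiment")
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  cat(sprintf("ExpressionExperiment: %d probes x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  tab <- table(x$design$phase, x$design$sex)
  print(tab)
  invisible(x)
}

#' Subset an experiment to a set of probes and/or samples
#'
#' @param exp an `ExpressionExperiment`.
#' @param probes character vector of probe ids to keep (default all).
#' @param samples character vector of sample ids to keep (default all).
#' @return the subsetted `ExpressionExperiment`.
#' @export
subset_experiment <- function(exp, probes = NULL, samples = NULL) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  probes <- probes %||% rownames(exp$intensities)
  samples <- samples %||% colnames(exp$intensities)
  structure(list(
    intensities = exp$intensities[probes, samples, drop = FALSE],
    detected = exp$detected[probes, samples, drop = FALSE],
    design = exp$design[exp$design$sample %in% samples, , drop = FALSE],
    probe_meta = exp$probe_meta[exp$probe_meta$probe %in% probes, , drop = FALSE]
  ), class = "ExpressionExperiment")
}

stratum_samples <- function(design, stratum = c("all", "females", "males")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         all = design$sample,
         females = design$sample[design$sex == "F"],
         males = design$sample[design$sex == "M"])
}
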