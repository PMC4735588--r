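#' Collapse qPCR replicate CT values
#'
#' Replicate wells of each (sample, assay) pair collapse to their arithmetic
#' mean; pairs whose replicate standard deviation exceeds 0.5 cycles are
#' flagged for review.
#'
#' @param plate data.frame with columns `sample`, `assay`, `ct` (one row per
#'   replicate well) and `is_control` (endogenous-control flag).
#' @param sd_flag flag threshold on the replicate SD, in cycles (default 0.5).
#' @return data.frame (`sample`, `assay`, `is_control`, `ct`, `ct_sd`,
#'   `n_replicates`, `flagged`).
#' @export
collapse_replicates <- function(plate, sd_flag = 0.5) {
  plate <- check_plate(plate)
  key <- interaction(plate$sample, plate$assay, drop = TRUE)
  agg <- lapply(split(plate, key), function(d) {
    data.frame(sample = d$sample[1], assay = d$assay[1],
               is_control = d$is_control[1],
               ct = mean(d$ct), ct_sd = if (nrow(d) > 1) stats::sd(d$ct) else 0,
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$flagged <- out$ct_sd > sd_flag
  rownames(out) <- NULL
  out
}

check_plate <- function(plate) {
  plate <- as.data.frame(plate, stringsAsFactors = FALSE)
  need <- c("sample", "assay", "ct", "is_control")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(plate$ct < 0 | plate$ct > 45))
    stop("CT values outside the plausible 0-45 range", call. = FALSE)
  samples_with_ctrl <- unique(plate$sample[plate$is_control])
  no_ctrl <- setdiff(unique(plate$sample), samples_with_ctrl)
  if (length(no_ctrl))
    stop("sample(s) lack an endogenous-control assay: ",
         paste(no_ctrl, collapse = ", "), call. = FALSE)
  plate
}

#' Relative quantification by the 2^-ddCT method
#'
#' Per sample, `dCT(assay) = CT(assay) - mean CT of the endogenous-control
#' assays` in that sample (arithmetic mean of the controls' CTs, i.e. the
#' geometric mean of their expression). Per target assay and group,
#' `ddCT = mean dCT(group) - mean dCT(reference group)` and relative
#' expression `fold = 2^-ddCT`.
#'
#' @param plate replicate-level plate (see [collapse_replicates()]).
#' @param design data.frame with columns `sample` and `group`.
#' @param reference_group the calibrator group label (fold = 1 by
#'   construction).
#' @return data.frame (`assay`, `group`, `mean_dct`, `ddct`, `fold`,
#'   `log2_fold`) for every non-control assay x group.
#' @export
delta_delta_ct <- function(plate, design, reference_group) {
  collapsed <- collapse_replicates(plate)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design)))
    stop("design needs columns sample, group", call. = FALSE)
  if (!reference_group %in% design$group)
    stop("reference group '", reference_group, "' absent from design",
         call. = FALSE)

  ctrl <- collapsed[collapsed$is_control, ]
  ctrl_ct <- tapply(ctrl$ct, ctrl$sample, mean)
  targets <- collapsed[!collapsed$is_control, ]
  targets$dct <- targets$ct - ctrl_ct[targets$sample]
  targets$group <- design$group[match(targets$sample, design$sample)]
  if (anyNA(targets$group))
    stop("sample(s) missing from design: ",
         paste(unique(targets$sample[is.na(targets$group)]), collapse = ", "),
         call. = FALSE)

  out <- do.call(rbind, lapply(split(targets, targets$assay), function(d) {
    mean_dct <- tapply(d$dct, d$group, mean)
    ref <- mean_dct[[reference_group]]
    data.frame(assay = d$assay[1], group = names(mean_dct),
               mean_dct = as.numeric(mean_dct),
               ddct = as.numeric(mean_dct) - ref,
               stringsAsFactors = FALSE)
  }))
  out$fold <- 2^(-out$ddct)
  out$log2_fold <- -out$ddct
  rownames(out) <- NULL
  out
}

#' Cross-platform fold-change concordance
#'
#' Pearson correlation (with its two-sided p-value) between array and qPCR
#' log2 fold changes over their shared assays/probes.
#'
#' @param array_log2fc,qpcr_log2fc named numeric vectors of log2 fold
#'   changes, named by assay/probe id.
#' @return list with `r`, `p`, `n` (pairs used).
#' @export
platform_concordance <- function(array_log2fc, qpcr_log2fc) {
  shared <- intersect(names(array_log2fc), names(qpcr_log2fc))
  if (length(shared) < 3L)
    stop("need >= 3 paired values for a correlation", call. = FALSE)
  ct <- stats::cor.test(array_log2fc[shared], qpcr_log2fc[shared],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk assesses normality (of the paired differences when
#' `paired`); if normality is not rejected at `alpha` in every tested set,
#' a (paired) t-test is used, otherwise a (paired) Wilcoxon test.
#'
#' @param values_a,values_b numeric vectors (>= 3 values each; equal length
#'   when paired).
#' @param paired logical; pairwise comparison (relapse vs remission of the
#'   same patients).
#' @param alpha Shapiro-Wilk gate level (default 0.05).
#' @return list with `test` (`"t"` or `"wilcoxon"`), `statistic`, `p`,
#'   `shapiro_p` (named vector of the gate p-values), `paired`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE, alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("need >= 3 values per group", call. = FALSE)
  if (paired && length(values_a) != length(values_b))
    stop("paired comparison requires equal-length groups", call. = FALSE)

  # degenerate no-signal input: identical paired measurements (or two
  # identical constant groups) carry no evidence either way
  if ((paired && all(values_a == values_b)) ||
      (!paired && stats::sd(c(values_a, values_b)) == 0))
    return(list(test = "t", statistic = 0, p = 1,
                shapiro_p = c(degenerate = NA_real_), paired = paired))

  safe_shapiro <- function(x) {
    # constant vectors are degenerate for Shapiro-Wilk; treat as non-normal
    if (stats::sd(x) == 0) return(0)
    stats::shapiro.test(x)$p.value
  }
  sw <- if (paired) c(differences = safe_shapiro(values_a - values_b))
        else c(a = safe_shapiro(values_a), b = safe_shapiro(values_b))
  normal <- all(sw >= alpha)

  if (normal) {
    tt <- stats::t.test(values_a, values_b, paired = paired)
    res <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, paired = paired))
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value)
  }
  c(res, list(shapiro_p = sw, paired = paired))
}
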