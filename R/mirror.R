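#' Exact one-sided sign test for direction concordance
#'
#' Null: each shared probe changes in opposite directions in the two phases
#' with probability 1/2, independently. The p-value is the exact binomial
#' upper tail `P(X >= k)` with `X ~ Binomial(n, 1/2)`, one-sided toward
#' excess opposition.
#'
#' @param n number of shared probes (>= 1).
#' @param k number of opposite-direction probes (0 <= k <= n).
#' @return exact one-sided p-value.
#' @examples
#' sign_test(8, 8)   # 0.00390625
#' sign_test(10, 8)  # 0.0546875
#' @export
sign_test <- function(n, k) {
  n <- check_count(n, "n", min = 1L)
  k <- check_count(k, "k", min = 0L)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
}

#' Shared signature and mirror classification between two phases
#'
#' Intersects the significant probe sets of two differential results and
#' labels each shared probe as mirror (opposite-direction) or concordant
#' using its control-referenced fold-change signs in the two phases. A zero
#' fold change counts as concordant (no opposition demonstrable).
#'
#' @param de_a,de_b `DifferentialResult` objects for the two phases (e.g.
#'   relapse and remission), sharing a probe universe.
#' @param fc_reference data.frame with columns `probe`, `fc_a`, `fc_b`:
#'   control-referenced log2 fold changes of each probe in phase a and
#'   phase b. Must cover every shared probe.
#' @return a `MirrorReport`: list with `shared` (data.frame `probe`,
#'   `fc_a`, `fc_b`, `opposite`), `n_shared`, `n_opposite`, `pct_opposite`
#'   (rounded half-up to the integer), and `p_sign` (exact one-sided sign
#'   test; `NA` when no probes are shared).
#' @export
shared_signature <- function(de_a, de_b, fc_reference) {
  stopifnot(inherits(de_a, "DifferentialResult"),
            inherits(de_b, "DifferentialResult"))
  shared_ids <- intersect(names(significant_probes(de_a)),
                          names(significant_probes(de_b)))
  fc_reference <- as.data.frame(fc_reference, stringsAsFactors = FALSE)
  if (!all(c("probe", "fc_a", "fc_b") %in% names(fc_reference)))
    stop("fc_reference needs columns probe, fc_a, fc_b", call. = FALSE)
  missing_fc <- setdiff(shared_ids, fc_reference$probe[
    !is.na(fc_reference$fc_a) & !is.na(fc_reference$fc_b)])
  if (length(missing_fc))
    stop("missing control-referenced fold change for shared probe(s): ",
         paste(missing_fc, collapse = ", "), call. = FALSE)

  idx <- match(shared_ids, fc_reference$probe)
  shared <- data.frame(probe = shared_ids,
                       fc_a = fc_reference$fc_a[idx],
                       fc_b = fc_reference$fc_b[idx],
                       stringsAsFactors = FALSE)
  shared$opposite <- sign(shared$fc_a) * sign(shared$fc_b) < 0
  n_shared <- nrow(shared)
  n_opposite <- sum(shared$opposite)
  structure(list(
    shared = shared, n_shared = n_shared, n_opposite = n_opposite,
    pct_opposite = if (n_shared) round_half_up(100 * n_opposite / n_shared) else NA_real_,
    p_sign = if (n_shared) sign_test(n_shared, n_opposite) else NA_real_,
    empty = n_shared == 0L
  ), class = "MirrorReport")
}

#' @export
print.MirrorReport <- function(x, ...) {
  if (x$empty) {
    cat("MirrorReport: no shared probes between the two phases\n")
    return(invisible(x))
  }
  cat(sprintf("MirrorReport: %d shared, %d opposite (%d%%), sign-test p = %.4g\n",
              x$n_shared, x$n_opposite, x$pct_opposite, x$p_sign))
  invisible(x)
}

#' Compare two direction-labelled probe lists
#'
#' Partitions the union of two lists into four disjoint sets: probes present
#' in both with the same direction, present in both with opposite direction,
#' and those private to either list. Used to relate the blood-leucocyte
#' signatures to the cultured-PBMC lists.
#'
#' @param list_a,list_b named character vectors: directions (`"up"`/`"down"`)
#'   named by probe id.
#' @return list with character vectors `same`, `opposite`, `a_only`, `b_only`.
#' @export
compare_lists <- function(list_a, list_b) {
  if (is.null(names(list_a)) || is.null(names(list_b)))
    stop("lists must be named by probe id with direction values", call. = FALSE)
  both <- intersect(names(list_a), names(list_b))
  same <- both[list_a[both] == list_b[both]]
  list(same = same,
       opposite = setdiff(both, same),
       a_only = setdiff(names(list_a), both),
       b_only = setdiff(names(list_b), both))
}

#' Control-referenced fold changes for two phases
#'
#' Convenience builder of the `fc_reference` table consumed by
#' [shared_signature()]: per probe, mean log2 intensity of each phase's
#' samples minus the mean of the control samples, within a stratum.
#'
#' @param exp an [expression_experiment()].
#' @param phase_a,phase_b phase labels (default relapse and remission).
#' @param stratum `"all"`, `"females"` or `"males"`.
#' @return data.frame with columns `probe`, `fc_a`, `fc_b` (log2 scale,
#'   control group as reference).
#' @export
control_referenced_fc <- function(exp, phase_a = "relapse", phase_b = "remission",
                                  stratum = c("all", "females", "males")) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(exp, "ExpressionExperiment"))
  des <- exp$design
  keep <- des$sample %in% stratum_samples(des, stratum)
  phase_mean <- function(phase) {
    s <- des$sample[keep & des$phase == phase]
    if (!length(s)) stop("no ", phase, " samples in stratum ", stratum, call. = FALSE)
    rowMeans(exp$intensities[, s, drop = FALSE])
  }
  ctrl <- phase_mean("control")
  data.frame(probe = rownames(exp$intensities),
             fc_a = phase_mean(phase_a) - ctrl,
             fc_b = phase_mean(phase_b) - ctrl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-panel fold-change bar plot of a mirror report
#'
#' Plots each shared probe's control-referenced log2 fold change in the two
#' phases side by side; mirror probes show bars of opposite sign.
#'
#' @param report a `MirrorReport`.
#' @param phase_names labels for the two panels.
#' @return invisibly, the matrix of plotted fold changes.
#' @export
plot_mirror <- function(report, phase_names = c("relapse", "remission")) {
  stopifnot(inherits(report, "MirrorReport"))
  if (report$empty) stop("nothing to plot: no shared probes", call. = FALSE)
  m <- t(as.matrix(report$shared[, c("fc_a", "fc_b")]))
  rownames(m) <- phase_names
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in 1:2) {
    graphics::barplot(m[i, ], names.arg = report$shared$probe, las = 2,
                      ylab = "log2 FC vs control", main = phase_names[i],
                      col = ifelse(m[i, ] >= 0, "firebrick", "steelblue"))
    graphics::abline(h = 0)
  }
  invisible(m)
}
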