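#' Define a two-class comparison
#'
#' @param name label for the comparison (used in reports and file names).
#' @param class_a,class_b phase selectors from
#'   `{"relapse", "remission", "control"}`; `class_b` is the reference for
#'   ratios and reported fold changes.
#' @param paired logical; pair class_a and class_b samples by patient id.
#' @param stratum `"all"`, `"females"` or `"males"`; applied before pairing.
#' @param same_treatment_only keep only patients whose class_a and class_b
#'   samples carry the same treatment label (only meaningful when paired).
#' @return a `comparison` object.
#' @export
comparison <- function(name, class_a, class_b, paired = FALSE,
                       stratum = c("all", "females", "males"),
                       same_treatment_only = FALSE) {
  stratum <- match.arg(stratum)
  phases <- c("relapse", "remission", "control")
  if (!class_a %in% phases || !class_b %in% phases)
    stop("class_a/class_b must be phase labels", call. = FALSE)
  structure(list(name = name, class_a = class_a, class_b = class_b,
                 paired = isTRUE(paired), stratum = stratum,
                 same_treatment_only = isTRUE(same_treatment_only)),
            class = "comparison")
}

#' Build the per-comparison log2-ratio matrix
#'
#' Paired designs produce one column per patient (class_a minus class_b
#' log2 value); unpaired designs produce one column per (a, b) cross-pair
#' of samples, the usual one-sample reduction for rank products.
#'
#' @param exp an [expression_experiment()].
#' @param comp a [comparison()].
#' @return numeric matrix of log2 ratios (probes x K columns), with
#'   attribute `K` recording the column count.
#' @export
build_ratio_matrix <- function(exp, comp) {
  stopifnot(inherits(exp, "ExpressionExperiment"), inherits(comp, "comparison"))
  des <- exp$design
  des <- des[des$sample %in% stratum_samples(des, comp$stratum), , drop = FALSE]
  a <- des[des$phase == comp$class_a, , drop = FALSE]
  b <- des[des$phase == comp$class_b, , drop = FALSE]
  X <- exp$intensities

  if (comp$paired) {
    patients <- intersect(a$patient, b$patient)
    dropped <- setdiff(union(a$patient, b$patient), patients)
    if (length(dropped))
      warning("patient(s) missing one phase excluded from paired design: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    if (comp$same_treatment_only) {
      same <- vapply(patients, function(p) {
        identical(a$treatment[match(p, a$patient)],
                  b$treatment[match(p, b$patient)])
      }, logical(1))
      patients <- patients[same]
    }
    if (length(patients) < 2L)
      stop("fewer than 2 usable ratio columns for comparison '", comp$name, "'",
           call. = FALSE)
    sa <- a$sample[match(patients, a$patient)]
    sb <- b$sample[match(patients, b$patient)]
    ratios <- X[, sa, drop = FALSE] - X[, sb, drop = FALSE]
    colnames(ratios) <- patients
  } else {
    if (nrow(a) == 0L || nrow(b) == 0L || nrow(a) * nrow(b) < 2L)
      stop("fewer than 2 usable ratio columns for comparison '", comp$name, "'",
           call. = FALSE)
    grid <- expand.grid(ai = a$sample, bi = b$sample, stringsAsFactors = FALSE)
    ratios <- X[, grid$ai, drop = FALSE] - X[, grid$bi, drop = FALSE]
    colnames(ratios) <- paste(grid$ai, grid$bi, sep = "/")
    # cross-pair columns are dependent (each array feeds many columns); keep
    # the underlying arrays so the permutation null can preserve that
    attr(ratios, "arrays") <- list(
      a = X[, a$sample, drop = FALSE], b = X[, b$sample, drop = FALSE],
      ai = match(grid$ai, a$sample), bi = match(grid$bi, b$sample))
  }
  attr(ratios, "K") <- ncol(ratios)
  ratios
}

# per-column ranks for the "down" direction (most negative ratio -> rank 1),
# average ranks on ties; "up" ranks are n + 1 - down ranks.
rank_columns <- function(ratios) {
  apply(ratios, 2L, rank, ties.method = "average")
}

#' Rank product of a ratio matrix
#'
#' Per column, probes are ranked by ratio — ascending for direction `down`
#' (most negative first), descending for `up` — with average ranks on ties.
#' The rank product is the geometric mean of a probe's ranks across columns;
#' a small value flags consistent extreme regulation.
#'
#' @param ratios numeric matrix of log2 ratios, probes x columns.
#' @param direction `"up"` or `"down"`.
#' @return named numeric vector of per-probe rank products (>= 1).
#' @export
rank_product <- function(ratios, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ratios <- as.matrix(ratios)
  if (nrow(ratios) < 2L) stop("rank product needs >= 2 probes", call. = FALSE)
  r <- rank_columns(ratios)
  if (direction == "up") r <- nrow(ratios) + 1 - r
  rp <- exp(rowMeans(log(r)))
  names(rp) <- rownames(ratios)
  rp
}

#' Permutation null for rank products
#'
#' By default each permutation independently shuffles probe labels within
#' every ratio column (preserving each column's rank multiset) and recomputes
#' both directions' rank products from the same shuffle — appropriate when
#' the columns are independent, as in a paired design where each column is
#' one patient's difference. When `arrays` is supplied (the unpaired
#' cross-pair design, where every array feeds many columns and the columns
#' are strongly dependent), probe labels are instead shuffled within every
#' underlying array and the cross-pair ratio columns are rebuilt from the
#' shuffled arrays, so the permuted rank products carry the same
#' between-column dependence as the observed ones. Per probe g:
#' `p_perm(g) = (1 + #permuted RP <= RP(g)) / (1 + n_permutations * n_probes)`;
#' `E[FP](g) = #permuted RP <= RP(g) / n_permutations`; and
#' `pFP(g) = E[FP](g) / rank(g)`, capped at 1 and made non-decreasing in RP
#' by a cumulative minimum from worst to best rank.
#'
#' @param ratios numeric matrix of log2 ratios.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed; every random draw flows from it.
#' @param arrays optional list (`a`, `b`, `ai`, `bi`) of the underlying
#'   class arrays and the column-pairing indices, as attached to unpaired
#'   ratio matrices by [build_ratio_matrix()].
#' @return data.frame with one row per probe per direction: `probe`,
#'   `direction`, `rp`, `rank`, `p_perm`, `e_fp`, `pfp`.
#' @export
permutation_null <- function(ratios, n_permutations = 1000, seed,
                             arrays = NULL) {
  ratios <- as.matrix(ratios)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- nrow(ratios)
  K <- ncol(ratios)
  r_down <- rank_columns(ratios)
  lr_down <- log(r_down)
  lr_up <- log(n + 1 - r_down)

  perm_down <- matrix(0, n, n_permutations)
  perm_up <- matrix(0, n, n_permutations)
  withr::with_seed(seed, {
    if (is.null(arrays)) {
      for (p in seq_len(n_permutations)) {
        sd_ <- numeric(n); su_ <- numeric(n)
        for (j in seq_len(K)) {
          idx <- sample.int(n)
          sd_ <- sd_ + lr_down[idx, j]
          su_ <- su_ + lr_up[idx, j]
        }
        perm_down[, p] <- sd_
        perm_up[, p] <- su_
      }
    } else {
      A <- arrays$a; B <- arrays$b
      for (p in seq_len(n_permutations)) {
        Ap <- apply(A, 2L, function(col) col[sample.int(n)])
        Bp <- apply(B, 2L, function(col) col[sample.int(n)])
        rd <- rank_columns(Ap[, arrays$ai, drop = FALSE] -
                             Bp[, arrays$bi, drop = FALSE])
        perm_down[, p] <- rowSums(log(rd))
        perm_up[, p] <- rowSums(log(n + 1 - rd))
      }
    }
  })

  one_direction <- function(lr_obs, perm_logsums, direction) {
    rp_obs <- exp(rowSums(lr_obs) / K)
    perm_rp <- exp(sort(as.numeric(perm_logsums) / K))
    # count of permuted RP values <= each observed RP (ties included)
    cnt <- findInterval(rp_obs, perm_rp)
    p_perm <- (1 + cnt) / (1 + n_permutations * n)
    e_fp <- cnt / n_permutations
    rk <- rank(rp_obs, ties.method = "min")
    pfp <- pmin(e_fp / rk, 1)
    # enforce monotone non-decreasing pFP along increasing RP
    o <- order(rp_obs)
    pfp[o] <- rev(cummin(rev(pfp[o])))
    data.frame(probe = rownames(ratios) %||% as.character(seq_len(n)),
               direction = direction, rp = rp_obs, rank = rk,
               p_perm = p_perm, e_fp = e_fp, pfp = pfp,
               stringsAsFactors = FALSE, row.names = NULL)
  }

  rbind(one_direction(lr_down, perm_down, "down"),
        one_direction(lr_up, perm_up, "up"))
}

#' Rank-product differential expression for one comparison
#'
#' Runs [build_ratio_matrix()], [permutation_null()] and assembles a
#' `DifferentialResult`: one row per probe carrying its winning direction
#' (the direction with the smaller permutation p-value, rank product as
#' tie-break), the control-referenced log2 fold change, and a significance
#' flag (`p_perm <= p_cut` and `pfp < fdr_cut`).
#'
#' @param exp an [expression_experiment()].
#' @param comp a [comparison()]; `class_b` is the fold-change reference.
#' @param n_permutations permutations for the null (default 1000).
#' @param seed integer seed (required).
#' @param p_cut permutation p-value cutoff (default 0.001).
#' @param fdr_cut pFP (expected false-positive proportion) cutoff (default 0.05).
#' @return a `DifferentialResult`: data.frame (`probe`, `direction`, `rp`,
#'   `p_perm`, `pfp`, `log2_fc`, `significant`) with comparison metadata in
#'   attributes `comparison`, `n_permutations`, `seed`, `K`.
#' @export
differential_expression <- function(exp, comp, n_permutations = 1000, seed,
                                    p_cut = 0.001, fdr_cut = 0.05) {
  ratios <- build_ratio_matrix(exp, comp)
  null <- permutation_null(ratios, n_permutations, seed,
                           arrays = attr(ratios, "arrays"))
  log2_fc <- rowMeans(ratios)

  down <- null[null$direction == "down", ]
  up <- null[null$direction == "up", ]
  up <- up[match(down$probe, up$probe), ]
  pick_up <- (up$p_perm < down$p_perm) |
    (up$p_perm == down$p_perm & up$rp < down$rp)
  win <- down
  win[pick_up, ] <- up[pick_up, ]

  res <- data.frame(probe = win$probe, direction = win$direction,
                    rp = win$rp, p_perm = win$p_perm, pfp = win$pfp,
                    log2_fc = log2_fc[win$probe],
                    significant = win$p_perm <= p_cut & win$pfp < fdr_cut,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("DifferentialResult", "data.frame"),
            comparison = comp, n_permutations = n_permutations, seed = seed,
            K = attr(ratios, "K"), p_cut = p_cut, fdr_cut = fdr_cut)
}

#' Significant probes of a DifferentialResult
#'
#' @param de a `DifferentialResult`.
#' @return named character vector: directions (`"up"`/`"down"`) named by
#'   significant probe ids.
#' @export
significant_probes <- function(de) {
  stopifnot(inherits(de, "DifferentialResult"))
  sig <- de[de$significant, ]
  stats::setNames(sig$direction, sig$probe)
}

#' @export
print.DifferentialResult <- function(x, ...) {
  comp <- attr(x, "comparison")
  cat(sprintf("DifferentialResult '%s' (%s vs %s, %s%s, stratum %s)\n",
              comp$name, comp$class_a, comp$class_b,
              if (comp$paired) "paired" else "unpaired",
              if (comp$same_treatment_only) ", same treatment" else "",
              comp$stratum))
  cat(sprintf("  %d probes, K = %d columns, %d permutations, %d significant\n",
              nrow(x), attr(x, "K"), attr(x, "n_permutations"),
              sum(x$significant)))
  invisible(x)
}

#' Select probes by absolute linear fold change
#'
#' Retains probes with fold change above 2-fold in either direction
#' (`FC > threshold` or `FC < 1/threshold`, strict), the selection rule used
#' for the stimulated-PBMC lists.
#'
#' @param fc_table data.frame with columns `probe` and `fc` (linear-scale
#'   fold changes), or a named numeric vector.
#' @param threshold strict fold-change bound (default 2).
#' @return character vector of retained probe ids.
#' @export
fold_change_filter <- function(fc_table, threshold = 2) {
  if (is.numeric(fc_table) && !is.null(names(fc_table)))
    fc_table <- data.frame(probe = names(fc_table), fc = unname(fc_table),
                           stringsAsFactors = FALSE)
  if (any(fc_table$fc <= 0)) stop("fold changes must be on the linear scale (> 0)",
                                  call. = FALSE)
  fc_table$probe[fc_table$fc > threshold | fc_table$fc < 1 / threshold]
}
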