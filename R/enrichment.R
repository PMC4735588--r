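#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH step-up: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the input
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) && (any(is.na(p_values)) ||
                           any(p_values < 0) || any(p_values > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation of a gene set collection
#'
#' For each term, tests whether the query over-represents the term relative
#' to random draws from the background: `p = P(X >= overlap)` with `X`
#' hypergeometric (population = background size, successes = term genes in
#' background, draws = query size). Terms are intersected with the
#' background before testing; BH step-up is applied across all tested terms.
#'
#' @param query character vector of genes, a subset of `background`.
#' @param background character vector: the sampling frame (e.g. the
#'   blood-expressed genes).
#' @param collection named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param alpha significance threshold on the BH q-value (default 0.05).
#' @return an `EnrichmentResult`: data.frame (`term`, `term_size`, `overlap`,
#'   `overlap_genes`, `p_hyper`, `q_bh`, `significant`) ordered by `p_hyper`,
#'   with `alpha` as an attribute.
#' @export
hypergeom_enrich <- function(query, background, collection, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene(s) not in background: ", paste(outside, collapse = ", "),
         call. = FALSE)
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(collection)))
    stop("collection must be a named list of gene sets", call. = FALSE)

  N <- length(background)
  k <- length(query)
  rows <- lapply(names(collection), function(term) {
    genes <- intersect(unique(collection[[term]]), background)
    ov <- intersect(genes, query)
    m <- length(genes)
    p <- if (m == 0L) 1 else
      stats::phyper(length(ov) - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, term_size = m, overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p_hyper = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_bh <- bh_adjust(res$p_hyper)
  res$significant <- res$q_bh < alpha
  res <- res[order(res$p_hyper, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"), alpha = alpha)
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: %d terms tested, %d significant at q < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print.data.frame(utils::head(x, 10))
  invisible(x)
}
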