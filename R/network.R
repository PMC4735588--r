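#' Filter target predictions by supporting sources and confidence score
#'
#' Retains predicted miRNA-gene interactions supported by at least
#' `min_sources` prediction algorithms and an average standard score of at
#' least `min_score` (both thresholds inclusive; scores live on a 0-100
#' scale).
#'
#' @param records data.frame with columns `mirna`, `gene`, `n_sources`,
#'   `score`.
#' @param min_sources minimum number of predicting algorithms (default 3).
#' @param min_score minimum average standard score (default 40).
#' @return the retained rows of `records`.
#' @export
filter_predictions <- function(records, min_sources = 3, min_score = 40) {
  records <- check_prediction_records(records)
  records[records$n_sources >= min_sources & records$score >= min_score, ,
          drop = FALSE]
}

check_prediction_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("mirna", "gene", "n_sources", "score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("prediction records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) && (any(records$score < 0) || any(records$score > 100)))
    stop("scores must lie in [0, 100]", call. = FALSE)
  if (nrow(records) && any(records$n_sources < 1))
    stop("n_sources must be >= 1", call. = FALSE)
  records
}

#' Keep predictions whose target gene is expressed in the tissue
#'
#' miRNA regulation requires the target to be expressed in the same tissue;
#' the expressed set is supplied (here, blood-expressed genes from the
#' companion transcriptome experiment).
#'
#' @param records prediction records (see [filter_predictions()]).
#' @param expressed_genes non-empty character vector of expressed gene symbols.
#' @return the retained rows.
#' @export
expression_filter <- function(records, expressed_genes) {
  records <- check_prediction_records(records)
  if (!length(expressed_genes))
    stop("expressed_genes must be non-empty", call. = FALSE)
  records[records$gene %in% expressed_genes, , drop = FALSE]
}

#' Keep predictions with anti-correlated fold changes
#'
#' Retains records whose gene moved in the opposite direction to its
#' predicted regulator miRNA (`sign(fc_mirna) * sign(fc_gene) < 0`); a zero
#' fold change on either endpoint demonstrates no opposition and is dropped.
#' Records with a missing fold change on either endpoint are dropped with a
#' warning.
#'
#' @param records prediction records.
#' @param mirna_fc,gene_fc named numeric vectors of log2 fold changes,
#'   named by miRNA id / gene symbol.
#' @return the retained rows.
#' @export
anticorrelation_filter <- function(records, mirna_fc, gene_fc) {
  records <- check_prediction_records(records)
  if (!nrow(records)) return(records)
  fm <- mirna_fc[records$mirna]
  fg <- gene_fc[records$gene]
  known <- !is.na(fm) & !is.na(fg)
  if (any(!known))
    warning(sum(!known), " record(s) dropped: fold change missing for an endpoint",
            call. = FALSE)
  records[known & sign(fm) * sign(fg) < 0, , drop = FALSE]
}

#' Build the annotated bipartite miRNA-target network
#'
#' Nodes are the distinct miRNAs and genes of the (already filtered)
#' prediction records; edges run miRNA -> gene. Genes are annotated as
#' transcription factors (`tf_set`) or plain protein-coding genes, flagged
#' when GWAS-associated with the disease, and every node carries its log2
#' fold change and degree. Duplicate predictions of the same pair collapse
#' to one edge keeping the maximum score.
#'
#' @param records filtered prediction records.
#' @param tf_set character vector of transcription-factor gene symbols.
#' @param gwas_set character vector of GWAS-associated gene symbols.
#' @param mirna_fc,gene_fc named numeric vectors of log2 fold changes.
#' @return a `RegulatoryNetwork`: list with `nodes` (data.frame `id`, `kind`,
#'   `log2_fc`, `gwas_flag`, `degree`), `edges` (data.frame `mirna`, `gene`,
#'   `score`), `components` (weakly connected component count) and `graph`
#'   (the underlying [igraph::graph]).
#' @export
build_network <- function(records, tf_set = character(), gwas_set = character(),
                          mirna_fc = numeric(), gene_fc = numeric()) {
  records <- check_prediction_records(records)
  bad <- intersect(unique(records$gene), unique(records$mirna))
  if (length(bad))
    stop("bipartite violation: id(s) appear as both miRNA and target: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!nrow(records)) {
    g <- igraph::make_empty_graph(directed = TRUE)
    nodes <- data.frame(id = character(), kind = character(),
                        log2_fc = numeric(), gwas_flag = logical(),
                        degree = integer(), stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes,
                          edges = records[, c("mirna", "gene", "score")],
                          components = 0L, graph = g),
                     class = "RegulatoryNetwork"))
  }
  # collapse duplicate pairs, keeping the best score
  key <- paste(records$mirna, records$gene, sep = "\r")
  records <- records[order(key, -records$score), , drop = FALSE]
  records <- records[!duplicated(paste(records$mirna, records$gene, sep = "\r")), ,
                     drop = FALSE]

  mirnas <- unique(records$mirna)
  genes <- unique(records$gene)
  ids <- c(mirnas, genes)
  kind <- c(rep("miRNA", length(mirnas)),
            ifelse(genes %in% tf_set, "TF", "gene"))
  fc <- c(unname(mirna_fc[mirnas]), unname(gene_fc[genes]))
  nodes <- data.frame(id = ids, kind = kind,
                      log2_fc = ifelse(is.na(fc), NA_real_, fc),
                      gwas_flag = ids %in% gwas_set,
                      stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(
    records[, c("mirna", "gene", "score")], directed = TRUE, vertices = nodes)
  nodes$degree <- igraph::degree(g, mode = "all")[nodes$id]
  igraph::V(g)$degree <- nodes$degree

  structure(list(nodes = nodes,
                 edges = records[, c("mirna", "gene", "score")],
                 components = igraph::components(g, mode = "weak")$no,
                 graph = g),
            class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d nodes (%d miRNA, %d TF, %d gene), %d edges, %d component(s)\n",
              nrow(x$nodes), sum(x$nodes$kind == "miRNA"),
              sum(x$nodes$kind == "TF"), sum(x$nodes$kind == "gene"),
              nrow(x$edges), x$components))
  invisible(x)
}

#' Genes (TF and non-TF) of a regulatory network
#'
#' @param net a `RegulatoryNetwork`.
#' @return character vector of target-gene node ids.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  net$nodes$id[net$nodes$kind != "miRNA"]
}
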