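#' Read / write a probe x sample matrix as tab-separated text
#'
#' Format: header row of sample ids, first column of probe ids.
#'
#' @param path file path.
#' @return for the reader, a numeric (or logical) matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_expression_matrix
#' @param m matrix with probe rownames and sample colnames.
#' @export
write_expression_matrix <- function(m, path) {
  d <- data.frame(probe = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One term per line: term id, description, then member genes, all
#' tab-separated.
#'
#' @param path file path.
#' @return for the reader, a named list of character vectors with term
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors; descriptions taken from the
#'   `descriptions` attribute (or `"NA"`).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("NA", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a regulatory network as GraphML
#'
#' Node attributes `kind`, `log2_fc`, `gwas_flag` and `degree` round-trip.
#'
#' @param net a `RegulatoryNetwork` from [build_network()].
#' @param path file path.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  g <- net$graph
  if (igraph::vcount(g)) {
    igraph::V(g)$kind <- net$nodes$kind
    igraph::V(g)$log2_fc <- net$nodes$log2_fc
    # GraphML has no boolean attribute through igraph; store as 0/1
    igraph::V(g)$gwas_flag <- as.integer(net$nodes$gwas_flag)
    igraph::V(g)$degree <- net$nodes$degree
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @return for the reader, a node data.frame (`id`, `kind`, `log2_fc`,
#'   `gwas_flag`, `degree`) and edge data.frame in a list, plus the igraph
#'   object.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g)) {
    nodes <- data.frame(id = igraph::V(g)$name,
                        kind = igraph::V(g)$kind,
                        log2_fc = igraph::V(g)$log2_fc,
                        gwas_flag = as.logical(igraph::V(g)$gwas_flag),
                        degree = igraph::V(g)$degree,
                        stringsAsFactors = FALSE)
    edges <- igraph::as_data_frame(g, what = "edges")
  } else {
    nodes <- data.frame(id = character(), kind = character(),
                        log2_fc = numeric(), gwas_flag = logical(),
                        degree = integer(), stringsAsFactors = FALSE)
    edges <- data.frame(from = character(), to = character())
  }
  list(nodes = nodes, edges = edges, graph = g)
}

#' Write a regulatory network in SIF format
#'
#' Simple interaction format: `source<TAB>targets<TAB>target`.
#'
#' @param net a `RegulatoryNetwork`.
#' @param path file path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  lines <- sprintf("%s\ttargets\t%s", net$edges$mirna, net$edges$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a replicate-level qPCR plate as tab-separated text
#'
#' Columns: `sample`, `assay`, `replicate`, `ct`, `is_control`.
#'
#' @param path file path.
#' @export
read_qpcr_plate <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$is_control <- as.logical(d$is_control)
  d
}

#' @rdname read_qpcr_plate
#' @param plate replicate-level plate data.frame.
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an experiment to disk as three tab-separated files plus truth JSON
#'
#' @param exp an [expression_experiment()].
#' @param dir output directory (created if needed).
#' @param truth optional `SyntheticTruth`, serialized as JSON alongside.
#' @return the directory, invisibly.
#' @export
write_experiment <- function(exp, dir, truth = NULL) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(exp$intensities, file.path(dir, "intensities.tsv"))
  write_expression_matrix(exp$detected * 1L, file.path(dir, "detected.tsv"))
  utils::write.table(exp$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$probe_meta, file.path(dir, "probe_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(
      list(de_membership = lapply(truth$de_membership, as.list),
           mirror_set = truth$mirror_set,
           regulation_pairs = truth$regulation_pairs,
           gene_fc = as.list(truth$gene_fc)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment written by [write_experiment()]
#'
#' @param dir directory holding `intensities.tsv`, `detected.tsv`,
#'   `design.tsv` and optionally `probe_meta.tsv`.
#' @return an [expression_experiment()].
#' @export
read_experiment <- function(dir) {
  ints <- read_expression_matrix(file.path(dir, "intensities.tsv"))
  det <- read_expression_matrix(file.path(dir, "detected.tsv")) > 0
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "probe_meta.tsv")
  meta <- if (file.exists(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(meta)) meta$human <- as.logical(meta$human)
  expression_experiment(ints, det, design, meta)
}
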