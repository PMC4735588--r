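#' Read a pipeline run configuration from YAML
#'
#' A run is configured declaratively. Either a `synthetic` block (fields of
#' [cohort_config()]) or an `experiment_dir` (layout of
#' [write_experiment()]) supplies the expression data; optional
#' `predictions_tsv`, `gene_fc_tsv`, `tf_genes`, `gwas_genes` and `gmt`
#' paths supply the network/enrichment inputs (synthetic runs generate
#' them). Thresholds default to 0.001 (permutation p), 0.05 (pFP), 3
#' (prediction sources), 40 (prediction score) and 0.05 (enrichment q).
#'
#' @param path YAML file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a list with the same structure as the YAML file.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("run config requires a seed", call. = FALSE)
  cfg$seed <- check_count(cfg$seed, "seed")
  cfg$n_permutations <- check_count(cfg$n_permutations %||% 1000,
                                    "n_permutations", min = 1L)
  th <- cfg$thresholds %||% list()
  cfg$thresholds <- list(
    p_cut = th$p_cut %||% 0.001, fdr_cut = th$fdr_cut %||% 0.05,
    min_sources = th$min_sources %||% 3, min_score = th$min_score %||% 40,
    alpha = th$alpha %||% 0.05)
  with(cfg$thresholds, {
    if (p_cut < 0 || p_cut > 1) stop_field("p_cut", "must lie in [0, 1]")
    if (fdr_cut < 0 || fdr_cut > 1) stop_field("fdr_cut", "must lie in [0, 1]")
    if (min_score < 0 || min_score > 100) stop_field("min_score", "must lie in [0, 100]")
    if (alpha <= 0 || alpha > 1) stop_field("alpha", "must lie in (0, 1]")
  })
  cfg$n_decoys <- check_count(cfg$n_decoys %||% 100, "n_decoys")
  if (is.null(cfg$synthetic)) {
    if (is.null(cfg$experiment_dir))
      stop("config needs a 'synthetic' block or an 'experiment_dir'",
           call. = FALSE)
    for (f in c("experiment_dir", "predictions_tsv", "gene_fc_tsv", "gmt")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("configured path does not exist: ", cfg[[f]], call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess -> sex-stratified differential expression (both
#' comparisons: relapse vs remission, paired within same-treatment patients,
#' and remission vs control, unpaired) -> mirror-pattern analysis ->
#' prediction-filtered regulatory networks -> gene-set enrichment -> qPCR
#' concordance, writing every stage's tables plus a JSON run report to
#' `outdir`. Identical config and seed give identical outputs.
#'
#' @param config a `run_config` (from [read_run_config()] /
#'   [as_run_config()]).
#' @param outdir output directory.
#' @return the run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  report <- list(seed = config$seed, n_permutations = config$n_permutations,
                 thresholds = th, stages = list())

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- syn$seed %||% config$seed
    cohort <- simulate_cohort(do.call(cohort_config, syn))
    exp <- cohort$experiment
    truth <- cohort$truth
    predictions <- simulate_predictions(truth, n_decoys = config$n_decoys,
                                        seed = config$seed + 1L)
    gene_fc <- truth$gene_fc
  } else {
    exp <- read_experiment(config$experiment_dir)
    predictions <- if (!is.null(config$predictions_tsv))
      utils::read.delim(config$predictions_tsv, stringsAsFactors = FALSE)
    gene_fc <- if (!is.null(config$gene_fc_tsv)) {
      d <- utils::read.delim(config$gene_fc_tsv, stringsAsFactors = FALSE)
      stats::setNames(d$log2_fc, d$gene)
    }
  }
  tf_set <- config$tf_genes %||% default_gene_subset(gene_fc, 5L)
  gwas_set <- config$gwas_genes %||% default_gene_subset(gene_fc, 7L)

  # --- preprocess ---------------------------------------------------------
  pre <- preprocess_experiment(exp)
  expf <- pre$experiment
  report$stages$preprocess <- list(
    total_probes = pre$summary$total, retained_probes = pre$summary$retained,
    retained_pct = pre$summary$pct)

  # --- differential expression, per stratum -------------------------------
  strata <- c("all", "females", "males")
  de <- list(); fcref <- list()
  report$stages$differential_expression <- list()
  for (s in strata) {
    for (cmp in c("relapse", "remission")) {
      comp <- if (cmp == "relapse")
        comparison("relapse", "relapse", "remission", paired = TRUE,
                   stratum = s, same_treatment_only = TRUE)
      else
        comparison("remission", "remission", "control", stratum = s)
      key <- paste(cmp, s, sep = ".")
      res <- tryCatch(
        withCallingHandlers(
          differential_expression(expf, comp, config$n_permutations,
                                  seed = config$seed + 10L,
                                  p_cut = th$p_cut, fdr_cut = th$fdr_cut),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("stage de.", key, " skipped: ", conditionMessage(res),
                call. = FALSE)
        report$stages$differential_expression[[key]] <-
          list(skipped = TRUE, reason = conditionMessage(res))
        next
      }
      de[[key]] <- res
      tab <- as.data.frame(res)
      utils::write.table(tab, file.path(outdir, paste0("de_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$differential_expression[[key]] <- list(
        skipped = FALSE, n_probes = nrow(tab), K = attr(res, "K"),
        n_significant = sum(tab$significant))
    }
    fcref[[s]] <- tryCatch(control_referenced_fc(expf, stratum = s),
                           error = function(e) NULL)
  }

  # --- mirror analysis ----------------------------------------------------
  report$stages$mirror <- list()
  mirrors <- list()
  for (s in strata) {
    ka <- paste0("relapse.", s); kb <- paste0("remission.", s)
    if (is.null(de[[ka]]) || is.null(de[[kb]]) || is.null(fcref[[s]])) {
      report$stages$mirror[[s]] <- list(skipped = TRUE)
      next
    }
    rep_s <- shared_signature(de[[ka]], de[[kb]], fcref[[s]])
    mirrors[[s]] <- rep_s
    utils::write.table(rep_s$shared,
                       file.path(outdir, paste0("mirror_shared_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$mirror[[s]] <- list(
      skipped = FALSE, n_shared = rep_s$n_shared,
      n_opposite = rep_s$n_opposite, pct_opposite = rep_s$pct_opposite,
      p_sign = rep_s$p_sign)
  }

  # --- regulatory networks + enrichment ------------------------------------
  report$stages$network <- list()
  report$stages$enrichment <- list()
  networks <- list()
  if (!is.null(predictions) && !is.null(gene_fc)) {
    expressed <- names(gene_fc)
    collection <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
    for (key in names(de)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      s <- parts[2]
      if (is.null(fcref[[s]])) next
      sig <- significant_probes(de[[key]])
      mir_probes <- intersect(
        names(sig), expf$probe_meta$probe[expf$probe_meta$class == "miRNA"])
      recs <- predictions[predictions$mirna %in% mir_probes, , drop = FALSE]
      if (!nrow(recs)) {
        report$stages$network[[key]] <- list(skipped = TRUE,
                                             reason = "no significant miRNAs")
        next
      }
      fc_col <- if (parts[1] == "relapse") "fc_a" else "fc_b"
      mirna_fc <- stats::setNames(fcref[[s]][[fc_col]], fcref[[s]]$probe)
      recs <- filter_predictions(recs, th$min_sources, th$min_score)
      recs <- expression_filter(recs, expressed)
      recs <- suppressWarnings(anticorrelation_filter(recs, mirna_fc, gene_fc))
      net <- build_network(recs, tf_set, gwas_set, mirna_fc, gene_fc)
      networks[[key]] <- net
      write_graphml(net, file.path(outdir, paste0("network_", key, ".graphml")))
      utils::write.table(net$nodes,
                         file.path(outdir, paste0("network_nodes_", key, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$network[[key]] <- list(
        skipped = FALSE, n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
        n_mirna = sum(net$nodes$kind == "miRNA"),
        n_tf = sum(net$nodes$kind == "TF"),
        n_gene = sum(net$nodes$kind == "gene"),
        components = net$components)

      genes <- network_genes(net)
      if (length(genes)) {
        if (is.null(collection))
          collection <- simulate_genesets(
            expressed, n_terms = 20,
            enriched_term_genes = genes[seq_len(min(10, length(genes)))],
            seed = config$seed + 2L)
        enr <- hypergeom_enrich(genes, expressed, collection, alpha = th$alpha)
        utils::write.table(as.data.frame(enr),
                           file.path(outdir, paste0("enrichment_", key, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$stages$enrichment[[key]] <- list(
          n_terms = nrow(enr), n_significant = sum(enr$significant))
      }
    }
  }

  # --- qPCR concordance ----------------------------------------------------
  if (!is.null(truth) && length(truth$planted_fc)) {
    n_assay <- min(10L, length(truth$planted_fc))
    fc <- truth$planted_fc[seq_len(n_assay)]
    q <- simulate_qpcr(fc, seed = config$seed + 3L)
    dd <- delta_delta_ct(q$plate, q$design, reference_group = "reference")
    case <- dd[dd$group == "case", ]
    conc <- if (nrow(case) >= 3)
      platform_concordance(log2(fc), stats::setNames(case$log2_fold, case$assay))
    else NULL
    utils::write.table(dd, file.path(outdir, "qpcr_ddct.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$qpcr <- list(
      n_assays = n_assay,
      concordance_r = conc$r %||% NA_real_, concordance_p = conc$p %||% NA_real_)
  }

  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(report = report, de = de, mirrors = mirrors,
                 networks = networks, truth = truth))
}

default_gene_subset <- function(gene_fc, every) {
  if (is.null(gene_fc)) return(character())
  g <- sort(names(gene_fc))
  g[seq_along(g) %% every == 0L]
}
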