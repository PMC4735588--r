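test_that("prediction filter applies inclusive source and score thresholds", {
  recs <- data.frame(
    mirna = paste0("mir", 1:4), gene = paste0("G", 1:4),
    n_sources = c(2, 3, 12, 5), score = c(90, 40, 39.5, 70),
    stringsAsFactors = FALSE)
  kept <- filter_predictions(recs)
  expect_setequal(kept$gene, c("G2", "G4"))  # 2 sources out; 39.5 out; 3/40 in
  expect_equal(nrow(filter_predictions(recs[0, ])), 0)
  expect_error(filter_predictions(transform(recs, score = c(101, 1, 1, 1))),
               "\\[0, 100\\]")
})

test_that("expression filter keeps records with blood-expressed targets", {
  recs <- make_predictions(10)
  expressed <- unique(recs$gene)[1:4]
  kept <- expression_filter(recs, expressed)
  expect_equal(nrow(kept), sum(recs$gene %in% expressed))
  expect_true(all(kept$gene %in% expressed))
  expect_equal(nrow(expression_filter(recs, unique(recs$gene))), nrow(recs))
  expect_error(expression_filter(recs, character()), "non-empty")
})

test_that("anticorrelation filter demands strictly opposite FC signs", {
  recs <- data.frame(mirna = c("m1", "m1", "m2", "m3"),
                     gene = c("g1", "g2", "g3", "g4"),
                     n_sources = 3, score = 50, stringsAsFactors = FALSE)
  mirna_fc <- c(m1 = 1.2, m2 = 1, m3 = -2)
  gene_fc <- c(g1 = -0.8, g2 = 0.5, g3 = 0, g4 = 1)
  kept <- anticorrelation_filter(recs, mirna_fc, gene_fc)
  expect_setequal(kept$gene, c("g1", "g4"))  # up/down and down/up; zero dropped
  # missing endpoint FC drops the record with a warning
  expect_warning(
    k2 <- anticorrelation_filter(recs, mirna_fc[-3], gene_fc), "dropped")
  expect_setequal(k2$gene, "g1")
})

test_that("the three filters commute and are threshold-monotone", {
  recs <- make_predictions(300, seed = 5)
  expressed <- paste0("G", 1:25)
  mirna_fc <- setNames(rnorm(8), paste0("mir", 1:8))
  gene_fc <- setNames(rnorm(40), paste0("G", 1:40))
  f1 <- function(r) filter_predictions(r)
  f2 <- function(r) expression_filter(r, expressed)
  f3 <- function(r) suppressWarnings(anticorrelation_filter(r, mirna_fc, gene_fc))
  key <- function(r) sort(paste(r$mirna, r$gene, r$n_sources, r$score))
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  fs <- list(f1, f2, f3)
  ref <- key(f3(f2(f1(recs))))
  for (o in orders)
    expect_identical(key(fs[[o[3]]](fs[[o[2]]](fs[[o[1]]](recs)))), ref)
  # raising thresholds never adds records
  loose <- filter_predictions(recs, min_sources = 2, min_score = 20)
  strict <- filter_predictions(recs, min_sources = 5, min_score = 60)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("network construction annotates the bipartite graph", {
  recs <- data.frame(mirna = rep(c("m1", "m2"), each = 3),
                     gene = rep(c("g1", "g2", "g3"), 2),
                     n_sources = 4, score = 60, stringsAsFactors = FALSE)
  net <- build_network(recs, tf_set = "g1", gwas_set = "g2",
                       mirna_fc = c(m1 = 1, m2 = -1),
                       gene_fc = c(g1 = -1, g2 = 1, g3 = 0.5))
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 6)
  expect_equal(net$components, 1)
  gene_deg <- net$nodes$degree[net$nodes$kind != "miRNA"]
  expect_true(all(gene_deg == 2))
  expect_equal(net$nodes$kind[net$nodes$id == "g1"], "TF")
  expect_true(net$nodes$gwas_flag[net$nodes$id == "g2"])
  # degree conservation: miRNA out-degree total = gene in-degree total = edges
  expect_equal(sum(net$nodes$degree[net$nodes$kind == "miRNA"]), nrow(net$edges))
  expect_equal(sum(gene_deg), nrow(net$edges))

  # four disjoint pairs -> four weak components
  recs4 <- data.frame(mirna = paste0("m", 1:4), gene = paste0("g", 1:4),
                      n_sources = 3, score = 50, stringsAsFactors = FALSE)
  expect_equal(build_network(recs4)$components, 4)

  # empty input -> empty network with zero components
  empty <- build_network(recs4[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(empty$components, 0)

  # bipartite violation: an id on both sides
  bad <- data.frame(mirna = c("m1", "g1"), gene = c("g1", "g2"),
                    n_sources = 3, score = 50, stringsAsFactors = FALSE)
  expect_error(build_network(bad), "bipartite")
})

test_that("duplicate predicted pairs collapse to one edge keeping the best score", {
  recs <- data.frame(mirna = c("m1", "m1", "m1"), gene = c("g1", "g1", "g2"),
                     n_sources = 3, score = c(50, 80, 60),
                     stringsAsFactors = FALSE)
  net <- build_network(recs)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$score[net$edges$gene == "g1"], 80)
})
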