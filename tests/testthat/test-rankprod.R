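test_that("rank product matches hand-ranked cases", {
  ratios <- matrix(c(-2, 0, 2, -1, 0, 1), 3, 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(rank_product(ratios, "down"), c(a = 1, b = 2, c = 3))
  expect_equal(rank_product(ratios, "up"), c(a = 3, b = 2, c = 1))

  # probe most negative in every column -> RP = 1 for down
  withr::with_seed(1, R <- matrix(rnorm(20), 5, 4))
  R[3, ] <- -10
  expect_equal(unname(rank_product(R, "down")[3]), 1)

  # all probes identical -> every RP = (n+1)/2 by the average-tie rule
  expect_equal(unname(rank_product(matrix(1, 4, 3), "down")), rep(2.5, 4))
})

test_that("per-column ranks always sum to n(n+1)/2, ties included", {
  withr::with_seed(7, {
    for (i in 1:10) {
      R <- matrix(sample(1:4, 18, replace = TRUE), 6, 3)  # heavy ties
      ranks <- apply(R, 2, rank, ties.method = "average")
      expect_equal(unname(colSums(ranks)), rep(21, 3))
    }
  })
})

test_that("sampled permutation p-values agree with exhaustive enumeration", {
  withr::with_seed(5, ratios <- matrix(rnorm(6), 3, 2,
                                       dimnames = list(c("a", "b", "c"), NULL)))
  nperm <- 2000
  null <- permutation_null(ratios, nperm, seed = 9)
  for (dir in c("down", "up")) {
    pool <- enumerate_null_rps(ratios, dir)   # all (3!)^2 shuffles, pooled
    obs <- rank_product(ratios, dir)
    d <- null[null$direction == dir, ]
    for (g in names(obs)) {
      p_exact <- mean(pool <= obs[[g]])
      se <- sqrt(p_exact * (1 - p_exact) / nperm)
      expect_lt(abs(d$p_perm[d$probe == g] - p_exact), 3 * se + 1e-3)
    }
  }
})

test_that("permutation null is deterministic and respects its bounds", {
  withr::with_seed(2, ratios <- matrix(rnorm(40), 10, 4))
  a <- permutation_null(ratios, 200, seed = 4)
  b <- permutation_null(ratios, 200, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$p_perm > 0 & a$p_perm <= 1))
  expect_true(all(a$p_perm >= 1 / (1 + 200 * 10)))
  expect_true(all(a$pfp >= 0 & a$pfp <= 1))
  # best-ranked probe's pFP equals its E[FP]/1 before monotonization, never negative
  for (dir in c("down", "up")) {
    d <- a[a$direction == dir, ]
    d <- d[order(d$rp), ]
    expect_true(all(diff(d$pfp) >= 0))  # monotone along increasing RP
  }
  expect_error(permutation_null(ratios, 0, seed = 1), "n_permutations")
})

test_that("negating every ratio swaps the up and down results exactly", {
  withr::with_seed(3, ratios <- matrix(rnorm(60), 15, 4,
                                       dimnames = list(sprintf("g%02d", 1:15), NULL)))
  a <- permutation_null(ratios, 300, seed = 11)
  b <- permutation_null(-ratios, 300, seed = 11)
  au <- a[a$direction == "up", ]; bd <- b[b$direction == "down", ]
  ad <- a[a$direction == "down", ]; bu <- b[b$direction == "up", ]
  rownames(au) <- rownames(bd) <- rownames(ad) <- rownames(bu) <- NULL
  expect_equal(au[setdiff(names(au), "direction")],
               bd[setdiff(names(bd), "direction")])
  expect_equal(ad[setdiff(names(ad), "direction")],
               bu[setdiff(names(bu), "direction")])
})

test_that("ratio matrix construction follows the paired and unpaired designs", {
  # paired with same-treatment restriction: 24 patients, 13 on one treatment
  sim <- simulate_cohort(cohort_config(n_patients = 24, n_controls = 24,
                                       n_probes = 50, n_same_treatment = 13,
                                       n_de_relapse_f = 0, n_de_remission_f = 0,
                                       n_de_remission_m = 0, n_mirror = 0,
                                       seed = 21))
  comp <- comparison("relapse", "relapse", "remission", paired = TRUE,
                     same_treatment_only = TRUE)
  expect_equal(ncol(build_ratio_matrix(sim$experiment, comp)), 13)
  comp_all <- comparison("relapse", "relapse", "remission", paired = TRUE)
  expect_equal(ncol(build_ratio_matrix(sim$experiment, comp_all)), 24)

  # unpaired 3 x 2 cross pairs
  m <- matrix(rnorm(18), 3, 6)
  ex <- tiny_experiment(m)
  ex$design$phase <- c("relapse", "relapse", "relapse", "control", "control",
                       "remission")
  ex$design$patient <- c("P1", "P2", "P3", "C1", "C2", "P1")
  comp2 <- comparison("rvc", "relapse", "control")
  expect_equal(ncol(build_ratio_matrix(ex, comp2)), 6)

  # a patient with only a remission sample is excluded with a warning
  ex2 <- tiny_experiment(matrix(rnorm(18), 3, 6))
  ex2$design$phase <- c("relapse", "remission", "remission", "remission",
                        "relapse", "control")
  ex2$design$patient <- c("P1", "P9", "P1", "P2", "P2", "C2")
  expect_warning(r <- build_ratio_matrix(
    ex2, comparison("x", "relapse", "remission", paired = TRUE)), "P9")
  expect_setequal(colnames(r), c("P1", "P2"))
  # ... and fewer than 2 usable columns is an error
  ex3 <- subset_experiment(ex2, samples = c("P1_rel", "P1_rem", "C1", "C2"))
  expect_error(suppressWarnings(build_ratio_matrix(
    ex3, comparison("x", "relapse", "remission", paired = TRUE))),
    "fewer than 2")
})

test_that("differential expression recovers planted effects and stays silent in males", {
  cfg <- cohort_config(n_patients = 13, n_controls = 13, n_probes = 200,
                       sex_ratio = 1, n_de_relapse_f = 10, n_de_remission_f = 0,
                       n_de_remission_m = 0, n_mirror = 0, effect_log2 = 2,
                       noise_sd = 0.3, seed = 31)
  sim <- simulate_cohort(cfg)
  exp <- detection_filter(sim$experiment)$experiment
  comp <- comparison("relapse", "relapse", "remission", paired = TRUE,
                     stratum = "females")
  de <- differential_expression(exp, comp, 500, seed = 8)
  truth <- sim$truth$de_membership$relapse.females
  found <- significant_probes(de)
  expect_gte(mean(names(truth) %in% names(found)), 0.9)
  # recovered directions match the planted ones
  hits <- intersect(names(truth), names(found))
  expect_equal(found[hits], truth[hits])
  # fold-change orientation: up probes have positive log2 FC vs class_b
  up <- de$probe[de$significant & de$direction == "up"]
  expect_true(all(de$log2_fc[match(up, de$probe)] > 0))

  # p_cut = 0 can never be met (p_perm > 0)
  de0 <- differential_expression(exp, comp, 100, seed = 8, p_cut = 0)
  expect_equal(sum(de0$significant), 0)

  # determinism
  expect_identical(differential_expression(exp, comp, 100, seed = 8),
                   differential_expression(exp, comp, 100, seed = 8))
})

test_that("fold-change filter applies the strict two-fold rule", {
  fc <- c(a = 2.0, b = 0.4, c = 1.0, d = 2.01, e = 0.5, f = 5)
  expect_setequal(fold_change_filter(fc), c("b", "d", "f"))
  expect_error(fold_change_filter(c(x = -1)), "linear scale")
})
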