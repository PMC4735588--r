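test_that("sign test reproduces exact binomial tails", {
  expect_equal(sign_test(8, 8), 0.5^8)            # 0.00390625
  expect_equal(round(sign_test(8, 8), 3), 0.004)
  expect_equal(sign_test(10, 8), 0.0546875)       # exact 8-of-10 tail
  expect_equal(sign_test(1, 1), 0.5)
  expect_error(sign_test(0, 0), "n")
  expect_error(sign_test(3, 4), "exceed")
})

test_that("sign test properties: boundaries and monotonicity", {
  for (n in c(1, 5, 10, 20)) {
    expect_equal(sign_test(n, 0), 1)
    expect_equal(sign_test(n, n), 2^-n)
    ps <- vapply(0:n, function(k) sign_test(n, k), numeric(1))
    expect_true(all(diff(ps) < 0))
  }
})

test_that("sign test is super-uniform under independent random directions", {
  withr::with_seed(99, {
    n <- 10
    ps <- vapply(1:2000, function(i) sign_test(n, rbinom(1, n, 0.5)), numeric(1))
    for (alpha in c(0.01, 0.05, 0.1, 0.25))
      expect_lte(mean(ps <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 2000))
  })
})

make_de <- function(sig, universe, comp_name = "x") {
  # minimal DifferentialResult carrying a significant set, for unit tests
  d <- data.frame(probe = universe, direction = "up", rp = 1, p_perm = 1,
                  pfp = 1, log2_fc = 0, significant = universe %in% names(sig),
                  stringsAsFactors = FALSE)
  d$direction[match(names(sig), d$probe)] <- unname(sig)
  structure(d, class = c("DifferentialResult", "data.frame"),
            comparison = comparison(comp_name, "relapse", "remission"),
            n_permutations = 1, seed = 1, K = 2)
}

test_that("shared signature intersects lists and labels opposition by FC signs", {
  universe <- letters[1:6]
  de_a <- make_de(c(a = "up", b = "up", c = "up"), universe)
  de_b <- make_de(c(b = "down", c = "up", d = "up"), universe)
  fc <- data.frame(probe = universe,
                   fc_a = c(1, 1, 1, 1, 1, 1),
                   fc_b = c(1, -1, 1, 1, 1, 1))
  rep <- shared_signature(de_a, de_b, fc)
  expect_setequal(rep$shared$probe, c("b", "c"))
  expect_equal(rep$n_opposite, 1)
  expect_equal(rep$pct_opposite, 50)
  expect_equal(rep$p_sign, sign_test(2, 1))

  # zero fold change counts as concordant
  fc0 <- fc; fc0$fc_b[2] <- 0
  expect_equal(shared_signature(de_a, de_b, fc0)$n_opposite, 0)

  # disjoint lists -> empty report, p undefined
  de_c <- make_de(c(e = "up"), universe)
  empty <- shared_signature(de_a, de_c, fc)
  expect_true(empty$empty)
  expect_true(is.na(empty$p_sign))

  # missing control FC for a shared probe is an error naming it
  fcm <- fc[fc$probe != "b", ]
  expect_error(shared_signature(de_a, de_b, fcm), "b")
})

test_that("compare_lists partitions the union into four disjoint sets", {
  a <- c(x = "up", y = "down", z = "up")
  expect_equal(compare_lists(a, a)$same, names(a))
  flipped <- c(x = "down", y = "up", z = "down")
  expect_setequal(compare_lists(a, flipped)$opposite, names(a))

  # overlap shaped like the stimulated-PBMC comparison: 4 same + 6 opposite
  blood <- c(SNORD68 = "down", mir18b = "up", mir210 = "up", mir98 = "up",
             m1 = "up", m2 = "up", m3 = "down", m4 = "down", m5 = "up",
             m6 = "down", only_a = "up")
  pbmc <- c(SNORD68 = "down", mir18b = "up", mir210 = "up", mir98 = "up",
            m1 = "down", m2 = "down", m3 = "up", m4 = "up", m5 = "down",
            m6 = "up", only_b = "down")
  res <- compare_lists(blood, pbmc)
  expect_length(res$same, 4)
  expect_length(res$opposite, 6)
  expect_equal(res$a_only, "only_a")
  expect_equal(res$b_only, "only_b")
  expect_setequal(c(res$same, res$opposite, res$a_only, res$b_only),
                  union(names(blood), names(pbmc)))
})

test_that("mirror probes show opposite control-referenced FC signs by construction", {
  cfg <- cohort_config(n_patients = 13, n_controls = 13, n_probes = 120,
                       sex_ratio = 1, n_de_relapse_f = 4, n_de_remission_f = 4,
                       n_de_remission_m = 0, n_mirror = 4, effect_log2 = 2,
                       noise_sd = 0.3, seed = 13)
  sim <- simulate_cohort(cfg)
  fc <- control_referenced_fc(sim$experiment, stratum = "females")
  m <- fc[fc$probe %in% sim$truth$mirror_set, ]
  expect_true(all(sign(m$fc_a) * sign(m$fc_b) < 0))

  # exact opposition in the noise-free degenerate cohort
  cfg0 <- cohort_config(n_patients = 6, n_controls = 6, n_probes = 60,
                        sex_ratio = 1, n_de_relapse_f = 3, n_de_remission_f = 3,
                        n_de_remission_m = 0, n_mirror = 3, effect_log2 = 1.5,
                        noise_sd = 0, patient_sd = 0, seed = 17)
  sim0 <- simulate_cohort(cfg0)
  fc0 <- control_referenced_fc(sim0$experiment, stratum = "females")
  m0 <- fc0[fc0$probe %in% sim0$truth$mirror_set, ]
  expect_equal(sign(m0$fc_a), -sign(m0$fc_b))
})
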