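# One moderately sized admixture simulation reused across blocks (the
# individual checks are deterministic given it).
sim_cache <- new.env()
get_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- simulate_scenario(
      make_admixture_scenario(alpha = 0.57, n_snps = 8000, seed = 321))
  }
  sim_cache$sim
}

test_that("population allele frequencies match a group-by oracle and mask", {
  m <- tiny_matrix()
  fr <- pop_allele_freqs(m, c("A", "B", "C"))
  # population A at SNP 1: calls (0, 1) -> 1/4
  expect_equal(fr$freq["A", 1], 0.25)
  # population A at SNP 4: calls (0, NA) -> 0
  expect_equal(fr$freq["A", 4], 0)
  expect_equal(fr$n_chrom["A", 4], 2)
  # population C at SNP 4 with calls (2, 0) -> 0.5
  expect_equal(fr$freq["C", 4], 0.5)
  # full oracle recount
  for (p in c("A", "B", "C")) {
    g <- m$calls[m$samples$population == p, , drop = FALSE]
    expect_equal(unname(fr$freq[p, ]),
                 unname(colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))))
  }
  # all-missing site masked as NA
  m$calls[3:4, 2] <- NA_integer_
  m2 <- genotype_matrix(m$calls, m$samples, m$snps)
  expect_true(is.na(pop_allele_freqs(m2, "B")$freq["B", 2]))
  expect_error(pop_allele_freqs(m, "Nope"), "unknown populations")
})

test_that("f4 equals its naive two-pass oracle and obeys exact linearity", {
  sim <- get_sim()
  m <- sim$matrix
  v <- f4(m, "SourceA", "SourceB", "Outgroup1", "Outgroup2")
  expect_equal(v$value, naive_f4(m, "SourceA", "SourceB", "Outgroup1",
                                 "Outgroup2"), tolerance = 1e-12)
  # antisymmetry, exact
  expect_equal(f4(m, "SourceB", "SourceA", "Outgroup1", "Outgroup2")$value,
               -v$value, tolerance = 1e-15)
  expect_equal(f4(m, "SourceA", "SourceB", "Outgroup2", "Outgroup1")$value,
               -v$value, tolerance = 1e-15)
  # identical first pair: exactly zero
  expect_identical(f4(m, "SourceA", "SourceA", "Outgroup1", "Outgroup2")$value, 0)
  expect_true(v$se >= 0)
  expect_equal(v$z, v$value / v$se)
})

test_that("f4 of a drift-free symmetric quartet has |Z| < 3 in most seeds", {
  zs <- sapply(1:10, function(s) {
    spec <- scenario_spec(
      6000,
      data.frame(label = c("Anc1", "A", "B", "Anc2", "C", "D"),
                 fst = c(0.05, 0.03, 0.03, 0.05, 0.03, 0.03),
                 n = c(0, 15, 15, 0, 15, 15),
                 parent = c(NA, "Anc1", "Anc1", NA, "Anc2", "Anc2")),
      missing_rate = 0.1, seed = 6000 + s)
    m <- simulate_scenario(spec)$matrix
    f4(m, "A", "B", "C", "D")$z
  })
  expect_gte(sum(abs(zs) < 3), 9)
})

test_that("f2 of undrifted copies is near zero (bias-corrected estimator)", {
  spec <- scenario_spec(
    8000, data.frame(label = c("P1", "P2"), fst = c(1e-12, 1e-12), n = 25),
    missing_rate = 0.1, seed = 55)
  m <- simulate_scenario(spec)$matrix
  v <- f2(m, "P1", "P2")
  expect_lt(abs(v$value), 3 * v$se + 1e-4)
  expect_lt(abs(v$value), 0.002)
})

test_that("fewer than 2 usable blocks errors", {
  m <- random_matrix(n = 8, m = 50, miss = 0, n_pops = 4, seed = 10)
  expect_error(f4(m, "pop1", "pop2", "pop3", "pop4", block_size_snps = 100),
               "2 usable blocks")
})

test_that("qpadm recovers a degenerate copy target as alpha = (1, 0)", {
  sim <- simulate_scenario(
    make_admixture_scenario(copy_of = "SourceA", n_snps = 8000, seed = 17))
  fit <- qpadm_fit(sim$matrix, "Target", c("SourceA", "SourceB"),
                   scenario_right_panel(sim$spec))
  expect_equal(unname(fit$weights["SourceA"]), 1, tolerance = 0.05)
  expect_equal(unname(fit$weights["SourceB"]), 0, tolerance = 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("qpadm recovers a 57/43 two-source mixture within 0.05", {
  sim <- get_sim()
  fit <- qpadm_fit(sim$matrix, "Target", c("SourceA", "SourceB"),
                   scenario_right_panel(sim$spec))
  expect_equal(unname(fit$weights["SourceA"]), 0.57, tolerance = 0.08)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(fit$feasible)
  expect_gt(fit$p_value, 0.01)
  expect_true(all(fit$se > 0))
})

test_that("qpadm recovers a three-source mixture within 0.07 per weight", {
  alpha <- c(0.592, 0.209, 0.199)
  pops <- rbind(
    do.call(rbind, lapply(c("S1", "S2", "S3"), function(lab) {
      data.frame(label = c(paste0(lab, "_br"), lab, paste0(lab, "_ref")),
                 fst = c(0.06, 0.03, 0.03), n = c(0, 30, 12),
                 parent = c(NA, paste0(lab, "_br"), paste0(lab, "_br")))
    })),
    data.frame(label = c("Outgroup1", "Outgroup2"), fst = 0.35, n = 12,
               parent = NA),
    data.frame(label = "Target", fst = 0.01, n = 30, parent = NA))
  spec <- scenario_spec(
    20000, pops,
    list(list(target = "Target", sources = c("S1", "S2", "S3"),
              proportions = alpha, post_drift = 0)),
    missing_rate = 0.3, seed = 2718)
  sim <- simulate_scenario(spec)
  fit <- qpadm_fit(sim$matrix, "Target", c("S1", "S2", "S3"),
                   c("S1_ref", "S2_ref", "S3_ref", "Outgroup1", "Outgroup2"))
  expect_true(all(abs(fit$weights - alpha) < 0.07))
  expect_true(fit$feasible)
})

test_that("weights are invariant to right-population reordering", {
  sim <- get_sim()
  right <- scenario_right_panel(sim$spec)
  f1 <- qpadm_fit(sim$matrix, "Target", c("SourceA", "SourceB"), right)
  f2 <- qpadm_fit(sim$matrix, "Target", c("SourceA", "SourceB"),
                  rev(right))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
})

test_that("collinear sources are refused by name", {
  sim <- simulate_scenario(
    make_admixture_scenario(alpha = 0.5, n_snps = 4000, seed = 31))
  # a literal duplicate population of SourceA under another label
  m <- sim$matrix
  dup_rows <- m$samples$population == "SourceA"
  m2 <- genotype_matrix(
    rbind(m$calls, m$calls[dup_rows, ]),
    rbind(m$samples,
          data.frame(sample_id = paste0(m$samples$sample_id[dup_rows], "_d"),
                     population = "SourceA2", sex = "U",
                     date_start = NA_integer_, date_end = NA_integer_,
                     role = "unknown")),
    m$snps)
  expect_error(qpadm_fit(m2, "Target", c("SourceA", "SourceA2"),
                         scenario_right_panel(sim$spec)),
               "near-collinear.*SourceA")
  expect_error(qpadm_fit(sim$matrix, "Target", "SourceA",
                         scenario_right_panel(sim$spec)),
               "between 2 and 5")
  expect_error(qpadm_fit(sim$matrix, "Target", c("SourceA", "SourceB"),
                         c("RefA", "RefB")),
               "right populations")
})

test_that("qpwave rank test separates one-stream and two-stream left sets", {
  sim <- get_sim()
  right <- scenario_right_panel(sim$spec)
  # duplicate-population left set: rank 0 fits
  m <- sim$matrix
  a_rows <- which(m$samples$population == "SourceA")
  half <- a_rows[seq_len(floor(length(a_rows) / 2))]
  relab <- m$samples
  relab$population[half] <- "SourceA_bis"
  m2 <- genotype_matrix(m$calls, relab, m$snps)
  p_null <- qpwave_rank_test(m2, c("SourceA", "SourceA_bis"), right)$p_value
  expect_gt(p_null, 0.05)
  # deeply diverged left pair: rank 0 rejected
  p_alt <- qpwave_rank_test(m, c("SourceA", "SourceB"), right)$p_value
  expect_lt(p_alt, 0.01)
  # rank 1 with three left pops descending from two streams is accepted
  relab2 <- m$samples
  relab2$population[half] <- "SourceA_bis"
  m3 <- genotype_matrix(m$calls, relab2, m$snps)
  r1 <- qpwave_rank_test(m3, c("SourceA", "SourceA_bis", "SourceB"), right,
                         rank = 1)
  expect_gt(r1$p_value, 0.01)
  expect_equal(r1$df, (3 - 1 - 1) * (4 - 1 - 1))
})

test_that("model_scan bounds, counting and selection rules hold", {
  sim <- simulate_scenario(
    make_admixture_scenario(alpha = 0.6, n_snps = 6000, n_decoys = 1,
                            seed = 99))
  right <- scenario_right_panel(sim$spec)
  # min_k = max_k = 2 with 3 candidates: exactly C(3, 2) = 3 models
  ms <- model_scan(sim$matrix, "Target", c("SourceA", "SourceB", "DecoyC"),
                   right, min_k = 2, max_k = 2)
  expect_equal(nrow(ms$models), 3)
  # impossible gate: p > 1 never holds, nothing selected
  ms1 <- model_scan(sim$matrix, "Target", c("SourceA", "SourceB", "DecoyC"),
                    right, p_threshold = 1.0, min_k = 2, max_k = 2)
  expect_true(is.na(ms1$selected))
  expect_equal(sum(ms1$models$accepted), 0)
  # the true pair is selected under the standard gate
  expect_equal(ms$models$model[ms$selected], "SourceA+SourceB")
})

test_that("block bootstrap is seed-deterministic and brackets the truth", {
  sim <- get_sim()
  right <- scenario_right_panel(sim$spec)
  fit1 <- block_bootstrap_ci(sim$matrix, "Target", c("SourceA", "SourceB"),
                             right, n_reps = 200, seed = 12)
  fit2 <- block_bootstrap_ci(sim$matrix, "Target", c("SourceA", "SourceB"),
                             right, n_reps = 200, seed = 12)
  expect_identical(fit1$ci, fit2$ci)
  expect_true(all(fit1$ci[, "lower"] <= fit1$ci[, "upper"]))
  expect_true(fit1$ci["SourceA", "lower"] <= 0.62 &&
                fit1$ci["SourceA", "upper"] >= 0.52)
  expect_warning(
    block_bootstrap_ci(sim$matrix, "Target", c("SourceA", "SourceB"),
                       right, n_reps = 50, seed = 1),
    "fewer than 100")
  # zero-admixture truth: the null source's lower CI reaches ~0
  sim0 <- simulate_scenario(
    make_admixture_scenario(alpha = 1, n_snps = 8000, seed = 7))
  f0 <- block_bootstrap_ci(sim0$matrix, "Target", c("SourceA", "SourceB"),
                           scenario_right_panel(sim0$spec), n_reps = 200,
                           seed = 3)
  expect_lte(f0$ci["SourceB", "lower"], 0.05)
})

test_that("fit tables serialize with weights, CIs and p-value", {
  sim <- get_sim()
  fit <- block_bootstrap_ci(sim$matrix, "Target", c("SourceA", "SourceB"),
                            scenario_right_panel(sim$spec), n_reps = 200,
                            seed = 5)
  tsv <- tempfile(fileext = ".tsv")
  write_admixture_fit(fit, tsv, "tsv")
  tab <- read.delim(tsv)
  expect_identical(tab$source, c("SourceA", "SourceB"))
  expect_equal(tab$weight, unname(fit$weights))
  expect_false(anyNA(tab$ci_low))
})
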