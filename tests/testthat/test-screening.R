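# Shared synthetic score fixture: n samples, K PCs, optional planted group
# shift on chosen components.
make_scores <- function(n_per_pop, pops, K = 10, shift = NULL, seed = 1) {
  set.seed(seed)
  n <- n_per_pop * length(pops)
  scores <- matrix(rnorm(n * K), n, K,
                   dimnames = list(sprintf("s%03d", 1:n), paste0("PC", 1:K)))
  metadata <- data.frame(sample_id = rownames(scores),
                         population = rep(pops, each = n_per_pop))
  if (!is.null(shift)) {
    rows <- metadata$population %in% shift$pops
    scores[rows, shift$pcs] <- scores[rows, shift$pcs] + shift$delta
  }
  list(scores = scores, metadata = metadata)
}

test_that("population PC statistics match an independent group-by oracle", {
  fx <- make_scores(4, c("A", "B", "C"), K = 5, seed = 3)
  stats <- population_pc_stats(fx$scores, fx$metadata)
  for (p in c("A", "B", "C")) {
    rows <- fx$scores[fx$metadata$population == p, ]
    for (k in 1:5) {
      r <- stats[stats$population == p & stats$pc == k, ]
      expect_equal(r$mean, mean(rows[, k]))
      expect_equal(r$sd, sd(rows[, k]))
      expect_equal(r$n, 4)
    }
  }
  # SD undefined for singletons; identical scores give SD 0
  single <- make_scores(1, c("X", "Y", "Z"), K = 2, seed = 4)
  st <- population_pc_stats(single$scores, single$metadata)
  expect_true(all(is.na(st$sd)))
  expect_equal(st$mean[st$population == "X" & st$pc == 1],
               single$scores[1, 1])
  const <- make_scores(3, c("A", "B"), K = 2, seed = 5)
  const$scores[const$metadata$population == "A", 1] <- 7
  stc <- population_pc_stats(const$scores, const$metadata)
  expect_equal(stc$sd[stc$population == "A" & stc$pc == 1], 0)
})

test_that("extreme detection flags a strongly shifted population and only that", {
  # one of eight populations shifted far out on PC6; the shift also inflates
  # the global SD, so the planted z works out to ~2.5 global SDs
  fx <- make_scores(10, LETTERS[1:8], K = 8,
                    shift = list(pops = "C", pcs = 6, delta = 10), seed = 11)
  ext <- detect_extremes(fx$scores, fx$metadata, z_threshold = 2)
  hit <- ext$flagged[ext$flagged$population == "C", ]
  expect_true(6 %in% hit$pc)
  expect_gt(abs(hit$z[hit$pc == 6]), 2)
  # under exchangeability, false flags are rare
  n_flags <- sapply(1:20, function(s) {
    f <- make_scores(10, LETTERS[1:8], K = 8, seed = 100 + s)
    nrow(detect_extremes(f$scores, f$metadata, 2)$flagged)
  })
  expect_lt(mean(n_flags) / (8 * 8), 0.1)  # per-(pop, PC) false-flag rate
  # singletons never flagged, reported separately
  fs <- make_scores(1, c("solo", "grp", "oth"), K = 3, seed = 12)
  fs$metadata$population <- c("solo", "grp", "grp")
  fs2 <- rbind(fs$scores, fs$scores + 0.1)
  rownames(fs2) <- sprintf("s%03d", 1:6)
  md <- data.frame(sample_id = rownames(fs2),
                   population = rep(c("solo", "grp", "grp"), 2))
  ext2 <- detect_extremes(fs2, md, z_threshold = 0.1, min_group_n = 3)
  expect_false("solo" %in% ext2$flagged$population)
  expect_true("solo" %in% ext2$too_small)
  # degenerate PC errors
  degen <- fs2; degen[, 2] <- 1
  expect_error(detect_extremes(degen, md), "zero global SD")
})

test_that("discrimination score is scale-invariant and ceilinged at point masses", {
  fx <- make_scores(6, c("A", "B", "C"), K = 6,
                    shift = list(pops = "A", pcs = 2, delta = 3), seed = 7)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B", g3 = "C"))
  s1 <- discrimination_score(fx$scores, fx$metadata, spec, c(1, 2))
  s2 <- discrimination_score(fx$scores * 2, fx$metadata, spec, c(1, 2))
  expect_equal(s1, s2, tolerance = 1e-12)
  # rotation within the subset leaves the score on standardized
  # coordinates exactly unchanged
  th <- 0.6
  rot_mat <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pre <- scale(fx$scores)
  rot <- pre
  rot[, 1:2] <- pre[, 1:2] %*% rot_mat
  expect_equal(
    discrimination_score(rot, fx$metadata, spec, 1:2, standardize = FALSE),
    discrimination_score(pre, fx$metadata, spec, 1:2, standardize = FALSE),
    tolerance = 1e-9)
  # two point-mass groups at distinct locations: astronomically large score
  pm <- make_scores(3, c("A", "B"), K = 2, seed = 8)
  pm$scores[pm$metadata$population == "A", ] <- 0
  pm$scores[pm$metadata$population == "B", ] <- 1
  spec2 <- discrimination_spec(list(g1 = "A", g2 = "B"))
  expect_gt(discrimination_score(pm$scores, pm$metadata, spec2, 1), 1e10)
  expect_error(discrimination_score(fx$scores, fx$metadata, spec,
                                    integer(0)), "non-empty")
})

test_that("identical groups score near the permutation null, planted shifts above it", {
  fx <- make_scores(12, c("A", "B"), K = 6, seed = 19)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  null_s <- discrimination_score(fx$scores, fx$metadata, spec, 1:3)
  perm <- permutation_null_scores(fx$scores, fx$metadata, spec, 1:3,
                                  n_perm = 199, seed = 5)
  expect_lt(null_s, quantile(perm, 0.999) * 3)   # same order of magnitude
  shifted <- make_scores(12, c("A", "B"), K = 6,
                         shift = list(pops = "A", pcs = 2, delta = 4),
                         seed = 19)
  alt_s <- discrimination_score(shifted$scores, shifted$metadata, spec, 1:3)
  expect_gt(alt_s, max(perm))
})

test_that("screen_all_pcs covers every PC and ranks the planted one first", {
  fx <- make_scores(10, c("A", "B", "C"), K = 12,
                    shift = list(pops = "A", pcs = 7, delta = 3), seed = 23)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  rep <- screen_all_pcs(fx$scores, fx$metadata, spec)
  expect_setequal(rep$discrimination$pc, 1:12)
  expect_equal(rep$discrimination$pc[1], 7)
  expect_equal(nrow(rep$stats), 3 * 12)
})

test_that("combination search is exhaustive, consistent and deterministic", {
  fx <- make_scores(10, c("A", "B"), K = 10,
                    shift = list(pops = "A", pcs = c(4, 9), delta = 2),
                    seed = 29)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  sr <- search_pc_combinations(fx$scores, fx$metadata, spec, arity = 3)
  expect_equal(sr$n_evaluated, choose(10, 3))
  expect_equal(nrow(sr$ranking), choose(10, 3))
  expect_true(all(diff(sr$ranking$score) <= 1e-12))
  expect_true(all(c(4, 9) %in% sr$selected))
  # arity 1 reduces to the single-PC argmax
  sr1 <- search_pc_combinations(fx$scores, fx$metadata, spec, arity = 1)
  rep1 <- screen_all_pcs(fx$scores, fx$metadata, spec)
  expect_equal(sr1$selected, rep1$discrimination$pc[1])
  # K = arity: single candidate
  sr3 <- search_pc_combinations(fx$scores[, 1:3], fx$metadata, spec, arity = 3)
  expect_equal(nrow(sr3$ranking), 1)
  expect_equal(sr3$selected, 1:3)
  expect_error(search_pc_combinations(fx$scores[, 1:2], fx$metadata, spec,
                                      arity = 3), "exceeds")
})

test_that("stronger planted shifts never lower the selected triple's score", {
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  best <- sapply(seq(0, 3, by = 0.5), function(delta) {
    fx <- make_scores(10, c("A", "B"), K = 8,
                      shift = list(pops = "A", pcs = 5, delta = delta),
                      seed = 31)
    search_pc_combinations(fx$scores, fx$metadata, spec,
                           arity = 3)$ranking$score[1]
  })
  expect_true(all(diff(best) >= -1e-9))
})

test_that("with randomized labels the planted triple is selected at chance rate", {
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  n_hit <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    fx <- make_scores(10, c("A", "B"), K = 8, seed = 4000 + s)
    sr <- search_pc_combinations(fx$scores, fx$metadata, spec, arity = 3)
    if (all(sr$selected == c(3, 4, 5))) n_hit <- n_hit + 1  # arbitrary triple
  }
  p_chance <- 1 / choose(8, 3)
  bt <- binom.test(n_hit, n_seeds, p_chance)
  expect_gt(bt$p.value, 0.001)
})

test_that("groups split at random from one population stay within the null", {
  # no PC should beat the label-permutation 95th percentile in most seeds
  exceed <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(7000 + s)
    scores <- matrix(rnorm(24 * 8), 24, 8,
                     dimnames = list(sprintf("s%02d", 1:24),
                                     paste0("PC", 1:8)))
    md <- data.frame(sample_id = rownames(scores),
                     population = sample(rep(c("splitA", "splitB"), 12)))
    spec <- discrimination_spec(list(g1 = "splitA", g2 = "splitB"))
    rep <- screen_all_pcs(scores, md, spec)
    # null of the maximum single-PC score (accounts for selection over PCs)
    null_max <- apply(sapply(1:8, function(k) {
      permutation_null_scores(scores, md, spec, k, n_perm = 99, seed = s)
    }), 1, max)
    if (rep$discrimination$score[1] > quantile(null_max, 0.95)) {
      exceed <- exceed + 1
    }
  }
  expect_lte(exceed, 2)
})

test_that("groups failing min_group_n or overlapping are rejected", {
  expect_error(discrimination_spec(list(g1 = "A")), ">= 2 named groups")
  expect_error(discrimination_spec(list(g1 = "A", g2 = "A")), "disjoint")
  fx <- make_scores(2, c("A", "B"), K = 3, seed = 2)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"), min_group_n = 3)
  expect_error(discrimination_score(fx$scores, fx$metadata, spec, 1),
               "min_group_n")
})

test_that("screening reports serialize to JSON with the selected triple", {
  fx <- make_scores(8, c("A", "B"), K = 6,
                    shift = list(pops = "A", pcs = 4, delta = 3), seed = 3)
  spec <- discrimination_spec(list(g1 = "A", g2 = "B"))
  rep <- pc_screening_report(fx$scores, fx$metadata, spec, arity = 3)
  path <- tempfile(fileext = ".json")
  write_screening_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(unlist(parsed$selected_triple), rep$selected_triple)
  expect_true(4 %in% rep$selected_triple)
})
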