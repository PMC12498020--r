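# Fixtures are generated in code; nothing is stored on disk.

# Small handcrafted matrix: 3 populations, known calls.
tiny_matrix <- function() {
  calls <- rbind(
    c(0L, 1L, 2L, 0L),
    c(1L, 1L, 2L, NA),
    c(2L, 0L, 1L, 1L),
    c(0L, 2L, NA, 2L),
    c(1L, 0L, 0L, 2L),
    c(2L, 2L, 1L, 0L))
  genotype_matrix(
    calls,
    data.frame(sample_id = paste0("s", 1:6),
               population = rep(c("A", "B", "C"), each = 2),
               sex = c("M", "F", "U", "M", "F", "U")),
    data.frame(snp_id = paste0("rs", 1:4), chromosome = "1",
               genetic_pos = c(0, 1e-4, 2e-4, 3e-4),
               physical_pos = c(100L, 200L, 300L, 400L),
               ref_allele = "A", alt_allele = c("C", "G", "T", "G")))
}

# Random matrix with controllable shape and missingness.
random_matrix <- function(n = 5, m = 8, miss = 0.2, n_pops = 2, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n)
  if (miss > 0) calls[matrix(runif(n * m) < miss, n)] <- NA_integer_
  genotype_matrix(
    calls,
    data.frame(sample_id = sprintf("ind%02d", seq_len(n)),
               population = paste0("pop", rep_len(seq_len(n_pops), n))),
    data.frame(snp_id = sprintf("snp%03d", seq_len(m)), chromosome = "1",
               genetic_pos = (seq_len(m) - 1) * 1e-5,
               physical_pos = seq_len(m) * 100L,
               ref_allele = "A", alt_allele = "G"))
}

# Independent oracle: HWE probabilities by direct enumeration with choose().
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- sapply(hets, function(h) {
    choose(n, (nA - h) / 2) * choose(n - (nA - h) / 2, h) * 2^h /
      choose(2 * n, nA)
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# Independent oracle: naive two-pass f4 with its own frequency counting.
naive_f4 <- function(matrix, A, B, C, D) {
  freq_of <- function(pop) {
    g <- matrix$calls[matrix$samples$population == pop, , drop = FALSE]
    colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
  }
  d <- (freq_of(A) - freq_of(B)) * (freq_of(C) - freq_of(D))
  mean(d[is.finite(d)])
}

# Independent oracle: Hudson-type Fst estimator from allele frequencies.
hudson_fst <- function(matrix, pop1, pop2) {
  fr <- pop_allele_freqs(matrix, c(pop1, pop2))
  p1 <- fr$freq[1, ]; p2 <- fr$freq[2, ]
  n1 <- fr$n_chrom[1, ]; n2 <- fr$n_chrom[2, ]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den)
  mean(num[ok]) / mean(den[ok])
}

# Identify the PC that actually carries a planted two-group signature:
# strongest absolute correlation with the true group indicator.
planted_pc <- function(scores, populations, group_a, group_b) {
  members <- populations %in% c(group_a, group_b)
  ind <- as.numeric(populations[members] == group_a)
  which.max(abs(suppressWarnings(stats::cor(scores[members, ], ind))))
}
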