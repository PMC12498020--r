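#' Quality-control thresholds for the filtering cascade
#'
#' Defaults follow standard ancient-DNA practice: sites are kept with minor
#' allele frequency >= 0.01, Hardy-Weinberg exact p > 1e-6 and missingness
#' <= 0.80; linkage-disequilibrium pruning uses an r^2 threshold of 0.25 in
#' 200-SNP windows advanced by 50 SNPs; samples need >= 50,000 covered SNPs
#' and missingness <= 0.80; pairs with PI_HAT > 0.25 (first-degree
#' relatives) lose one member.
#'
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min sites are removed when the Hardy-Weinberg exact p-value
#'   is not above this.
#' @param snp_missing_max maximum per-SNP missingness rate.
#' @param ld_r2_max r-squared above which one SNP of a pair is pruned.
#' @param ld_window,ld_step sliding-window size and step, in SNPs.
#' @param sample_min_snps minimum covered (non-missing) SNPs per sample.
#' @param sample_missing_max maximum per-sample missingness rate.
#' @param pi_hat_max kinship threshold (proportion of genome shared IBD).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_p_min = 1e-6,
                          snp_missing_max = 0.80, ld_r2_max = 0.25,
                          ld_window = 200, ld_step = 50,
                          sample_min_snps = 50000, sample_missing_max = 0.80,
                          pi_hat_max = 0.25) {
  th <- list(maf_min = maf_min, hwe_p_min = hwe_p_min,
             snp_missing_max = snp_missing_max, ld_r2_max = ld_r2_max,
             ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
             sample_min_snps = as.integer(sample_min_snps),
             sample_missing_max = sample_missing_max, pi_hat_max = pi_hat_max)
  rates <- c(th$maf_min, th$hwe_p_min, th$snp_missing_max,
             th$sample_missing_max, th$pi_hat_max)
  if (any(rates < 0 | rates > 1)) stop("rates/frequencies must lie in [0, 1]")
  if (th$ld_step < 1 || th$ld_window < th$ld_step) {
    stop("need ld_window >= ld_step >= 1")
  }
  structure(th, class = "qc_thresholds")
}

#' Minor allele frequency at one site
#'
#' `min(p, 1 - p)` where `p` is the alternate-allele frequency among
#' non-missing calls. A site with no non-missing call returns `NA`
#' (undefined), which fails any positive MAF filter.
#'
#' @param matrix a [genotype_matrix()].
#' @param snp_index column index or `snp_id`.
#' @return A frequency in `[0, 0.5]`, or `NA` for an all-missing site.
#' @export
compute_maf <- function(matrix, snp_index) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (is.character(snp_index)) {
    snp_index <- match(snp_index, matrix$snps$snp_id)
    if (anyNA(snp_index)) stop("unknown snp_id")
  }
  g <- matrix$calls[, snp_index]
  if (all(is.na(g))) return(NA_real_)
  p <- mean(g, na.rm = TRUE) / 2
  min(p, 1 - p)
}

# Vectorized per-SNP alt-allele frequency / MAF / missingness.
.snp_freqs <- function(calls) {
  n_obs <- colSums(!is.na(calls))
  tot <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n_obs > 0, tot / (2 * n_obs), NA_real_)
  list(p = p, maf = pmin(p, 1 - p), n_obs = n_obs,
       missing = 1 - n_obs / nrow(calls))
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact two-sided test conditioning on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (probability-ordering convention). Monomorphic sites return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectors recycle elementwise).
#' @return P-values in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, n); n_Aa <- rep_len(n_Aa, n); n_aa <- rep_len(n_aa, n)
  vapply(seq_len(n), function(i) {
    .hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

.hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Prune SNPs in linkage disequilibrium
#'
#' Sliding-window greedy pruning: within each window of `window` SNPs
#' (advanced by `step`, per chromosome) any retained pair with genotype
#' dosage correlation `r^2 > r2_max` loses its later member. r^2 uses
#' pairwise-complete observations; pairs with fewer than 20 complete
#' observations are skipped (ancient-DNA missingness makes such estimates
#' worthless). Output is deterministic.
#'
#' @param matrix a [genotype_matrix()] with SNPs sorted by
#'   (chromosome, physical_pos).
#' @param window,step window length and step in SNPs.
#' @param r2_max pruning threshold.
#' @param min_pair_obs minimum complete observations to evaluate a pair.
#' @return Character vector of retained `snp_id`s, in input order.
#' @export
ld_prune <- function(matrix, window = 200, step = 50, r2_max = 0.25,
                     min_pair_obs = 20) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  s <- matrix$snps
  o <- order(s$chromosome, s$physical_pos)
  if (!identical(o, seq_len(nrow(s)))) {
    stop("SNPs must be sorted by (chromosome, physical_pos); sort the matrix first")
  }
  keep <- rep(TRUE, nrow(s))
  for (chr in unique(s$chromosome)) {
    idx <- which(s$chromosome == chr)
    if (length(idx) < 2) next
    starts <- seq(1, length(idx), by = step)
    for (st in starts) {
      win <- idx[st:min(st + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      g <- matrix$calls[, win, drop = FALSE]
      obs <- !is.na(g)
      n_pair <- crossprod(obs)
      suppressWarnings(r <- stats::cor(g, use = "pairwise.complete.obs"))
      r2 <- r^2
      r2[is.na(r2)] <- 0
      r2[n_pair < min_pair_obs] <- 0
      m <- length(win)
      alive <- rep(TRUE, m)
      for (a in seq_len(m - 1)) {
        if (!alive[a]) next
        hits <- which(alive & r2[a, ] > r2_max)
        hits <- hits[hits > a]
        alive[hits] <- FALSE
      }
      keep[win[!alive]] <- FALSE
    }
  }
  matrix$snps$snp_id[keep]
}

#' Pairwise identity-by-descent estimates (PI_HAT)
#'
#' Method-of-moments IBD estimation from identity-by-state counts, as used
#' for relatedness screening: per pair, the observed numbers of IBS 0/1/2
#' sites over pairwise-complete sites are compared with their expectations
#' under the sample allele frequencies to estimate P(IBD = 0, 1, 2);
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`, clipped to `[0, 1]`. Pairs with fewer
#' than `min_pair_sites` complete sites are marked unevaluable (`NA`).
#' Estimates should be computed on an LD-pruned site set.
#'
#' @param matrix a [genotype_matrix()] with >= 2 samples.
#' @param snp_ids optional site subset (e.g. from [ld_prune()]).
#' @param min_pair_sites minimum complete sites per pair.
#' @return data.frame with `sample_1`, `sample_2`, `n_sites`, `pi_hat`.
#' @export
estimate_pi_hat <- function(matrix, snp_ids = NULL, min_pair_sites = 100) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$calls) < 2) stop("need at least 2 samples")
  if (!is.null(snp_ids)) matrix <- subset_genotypes(matrix, snp_ids = snp_ids)
  g <- matrix$calls
  fr <- .snp_freqs(g)
  use <- which(!is.na(fr$p) & fr$maf > 0)
  g <- g[, use, drop = FALSE]
  p <- fr$p[use]
  q <- 1 - p
  G0 <- (!is.na(g)) & g == 0L
  G1 <- (!is.na(g)) & g == 1L
  G2 <- (!is.na(g)) & g == 2L
  M <- G0 | G1 | G2
  storage.mode(G0) <- storage.mode(G1) <- storage.mode(G2) <- "double"
  storage.mode(M) <- "double"
  ibs0 <- tcrossprod(G0, G2); ibs0 <- ibs0 + t(ibs0)
  ibs2 <- tcrossprod(G0) + tcrossprod(G1) + tcrossprod(G2)
  n_pair <- tcrossprod(M)
  ibs1 <- n_pair - ibs0 - ibs2
  # per-pair expectations: sum over complete sites of f(p)
  esum <- function(v) {
    tmp <- tcrossprod(M * rep(v, each = nrow(M)), M)
    (tmp + t(tmp)) / 2
  }
  E0_0 <- esum(2 * p^2 * q^2)
  E1_0 <- esum(4 * p^3 * q + 4 * p * q^3)
  E2_0 <- esum(p^4 + q^4 + 4 * p^2 * q^2)
  E1_1 <- esum(2 * p^2 * q + 2 * p * q^2)
  E2_1 <- esum(p^3 + q^3 + p^2 * q + p * q^2)
  n <- nrow(g)
  pairs <- which(upper.tri(n_pair), arr.ind = TRUE)
  z0 <- ifelse(E0_0[pairs] > 0, ibs0[pairs] / E0_0[pairs], 0)
  z1 <- ifelse(E1_1[pairs] > 0,
               (ibs1[pairs] - z0 * E1_0[pairs]) / E1_1[pairs], 0)
  z2 <- (ibs2[pairs] - z0 * E2_0[pairs] - z1 * E2_1[pairs]) / n_pair[pairs]
  z0 <- pmax(z0, 0); z1 <- pmax(z1, 0); z2 <- pmax(z2, 0)
  tot <- z0 + z1 + z2
  tot[tot == 0] <- 1
  pi_hat <- pmin(1, pmax(0, (z2 + z1 / 2) / tot))
  pi_hat[n_pair[pairs] < min_pair_sites] <- NA_real_
  ids <- matrix$samples$sample_id
  data.frame(sample_1 = ids[pairs[, 1]], sample_2 = ids[pairs[, 2]],
             n_sites = as.integer(n_pair[pairs]), pi_hat = pi_hat,
             stringsAsFactors = FALSE)
}

#' Apply the full quality-control cascade
#'
#' Stages run in a fixed order: SNP filters first (MAF, Hardy-Weinberg,
#' missingness, LD pruning), then sample filters (coverage, missingness,
#' sex-consistency check, kinship). Kinship runs last, on the LD-pruned
#' QC-passing site set; for each pair above `pi_hat_max` the sample with
#' fewer covered SNPs is removed (ties: the lexicographically later
#' `sample_id`). The Hardy-Weinberg filter is computed on the pooled
#' dataset — as is conventional for a global SNP filter — even though
#' population structure deflates its p-values; treat it as a genotyping
#' artefact screen, not a population test. The sex check only compares
#' recorded metadata against `declared_sex` (no sex-chromosome data is
#' modelled): mismatches warn, and are removed only when `strict_sex` is
#' set.
#'
#' @param matrix a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @param declared_sex optional named character vector (`sample_id` ->
#'   `"M"/"F"/"U"`) of externally determined sex.
#' @param strict_sex remove (rather than warn about) sex mismatches.
#' @return list with `matrix` (filtered) and `report` (a `qc_report`).
#' @export
apply_qc_pipeline <- function(matrix, thresholds = qc_thresholds(),
                              declared_sex = NULL, strict_sex = FALSE) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  th <- thresholds
  stages <- list()
  note_stage <- function(stage, level, n_in, n_removed, threshold) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, level = level, n_in = n_in, n_removed = n_removed,
      threshold = threshold, stringsAsFactors = FALSE)
  }
  check_nonempty <- function(m, stage) {
    if (nrow(m$calls) == 0 || ncol(m$calls) == 0) {
      stop("QC stage '", stage, "' removed everything; nothing left to analyze")
    }
    m
  }

  # --- SNP level -----------------------------------------------------------
  fr <- .snp_freqs(matrix$calls)
  drop <- if (th$maf_min > 0) is.na(fr$maf) | fr$maf < th$maf_min
          else !is.na(fr$maf) & fr$maf < th$maf_min
  note_stage("maf", "snp", ncol(matrix$calls), sum(drop), th$maf_min)
  matrix <- check_nonempty(.drop_snps(matrix, drop), "maf")

  counts <- .genotype_counts(matrix$calls)
  p_hwe <- rep(1, ncol(matrix$calls))
  has_data <- counts$n > 0
  p_hwe[has_data] <- hwe_exact_p(counts$n_AA[has_data], counts$n_Aa[has_data],
                                 counts$n_aa[has_data])
  drop <- !(p_hwe > th$hwe_p_min)
  note_stage("hwe", "snp", ncol(matrix$calls), sum(drop), th$hwe_p_min)
  matrix <- check_nonempty(.drop_snps(matrix, drop), "hwe")

  fr <- .snp_freqs(matrix$calls)
  drop <- fr$missing > th$snp_missing_max
  note_stage("snp_missingness", "snp", ncol(matrix$calls), sum(drop),
             th$snp_missing_max)
  matrix <- check_nonempty(.drop_snps(matrix, drop), "snp_missingness")

  if (th$ld_r2_max < 1) {
    kept_ids <- ld_prune(matrix, window = th$ld_window, step = th$ld_step,
                         r2_max = th$ld_r2_max)
    drop <- !(matrix$snps$snp_id %in% kept_ids)
  } else {
    drop <- rep(FALSE, ncol(matrix$calls))
  }
  note_stage("ld_prune", "snp", ncol(matrix$calls), sum(drop), th$ld_r2_max)
  matrix <- check_nonempty(.drop_snps(matrix, drop), "ld_prune")

  # --- sample level --------------------------------------------------------
  covered <- rowSums(!is.na(matrix$calls))
  drop <- covered < th$sample_min_snps
  note_stage("sample_coverage", "sample", nrow(matrix$calls), sum(drop),
             th$sample_min_snps)
  matrix <- check_nonempty(.drop_samples(matrix, drop), "sample_coverage")

  miss <- 1 - rowSums(!is.na(matrix$calls)) / ncol(matrix$calls)
  drop <- miss > th$sample_missing_max
  note_stage("sample_missingness", "sample", nrow(matrix$calls), sum(drop),
             th$sample_missing_max)
  matrix <- check_nonempty(.drop_samples(matrix, drop), "sample_missingness")

  drop <- rep(FALSE, nrow(matrix$calls))
  if (!is.null(declared_sex)) {
    idx <- match(matrix$samples$sample_id, names(declared_sex))
    mism <- !is.na(idx) & declared_sex[idx] != "U" &
      matrix$samples$sex != "U" & declared_sex[idx] != matrix$samples$sex
    if (any(mism)) {
      warning("sex mismatch for: ",
              paste(matrix$samples$sample_id[mism], collapse = ", "))
      if (strict_sex) drop <- mism
    }
  }
  note_stage("sex_check", "sample", nrow(matrix$calls), sum(drop),
             as.numeric(strict_sex))
  matrix <- check_nonempty(.drop_samples(matrix, drop), "sex_check")

  drop_ids <- character(0)
  if (th$pi_hat_max < 1 && nrow(matrix$calls) >= 2) {
    kin <- estimate_pi_hat(matrix)
    kin <- kin[!is.na(kin$pi_hat) & kin$pi_hat > th$pi_hat_max, , drop = FALSE]
    if (nrow(kin) > 0) {
      kin <- kin[order(-kin$pi_hat, kin$sample_1, kin$sample_2), , drop = FALSE]
      covered <- rowSums(!is.na(matrix$calls))
      names(covered) <- matrix$samples$sample_id
      for (i in seq_len(nrow(kin))) {
        a <- kin$sample_1[i]; b <- kin$sample_2[i]
        if (a %in% drop_ids || b %in% drop_ids) next
        victim <- if (covered[a] < covered[b]) a
                  else if (covered[b] < covered[a]) b
                  else max(a, b)  # tie: lexicographically later id
        drop_ids <- c(drop_ids, victim)
      }
    }
  }
  drop <- matrix$samples$sample_id %in% drop_ids
  note_stage("kinship", "sample", nrow(matrix$calls), sum(drop), th$pi_hat_max)
  matrix <- check_nonempty(.drop_samples(matrix, drop), "kinship")

  report <- structure(list(stages = do.call(rbind, stages),
                           n_samples_final = nrow(matrix$calls),
                           n_snps_final = ncol(matrix$calls),
                           thresholds = th),
                      class = "qc_report")
  list(matrix = matrix, report = report)
}

.drop_snps <- function(matrix, drop) {
  if (!any(drop)) return(matrix)
  genotype_matrix(matrix$calls[, !drop, drop = FALSE], matrix$samples,
                  matrix$snps[!drop, , drop = FALSE])
}

.drop_samples <- function(matrix, drop) {
  if (!any(drop)) return(matrix)
  genotype_matrix(matrix$calls[!drop, , drop = FALSE],
                  matrix$samples[!drop, , drop = FALSE], matrix$snps)
}

.genotype_counts <- function(calls) {
  list(n_AA = colSums(calls == 0L, na.rm = TRUE),
       n_Aa = colSums(calls == 1L, na.rm = TRUE),
       n_aa = colSums(calls == 2L, na.rm = TRUE),
       n = colSums(!is.na(calls)))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final: %d samples x %d SNPs\n",
              x$n_samples_final, x$n_snps_final))
  invisible(x)
}

#' Serialize a QC report
#'
#' @param report a `qc_report` from [apply_qc_pipeline()].
#' @param path output file.
#' @param format `"tsv"` (stage table) or `"json"` (full report).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report$stages, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(stages = report$stages,
                              n_samples_final = report$n_samples_final,
                              n_snps_final = report$n_snps_final,
                              thresholds = unclass(report$thresholds)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
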