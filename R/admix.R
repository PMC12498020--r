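#' Population allele frequencies
#'
#' Alternate-allele frequency per (population, SNP) from non-missing calls.
#' Sites with zero calls in a population get `NA` there; joint statistics
#' mask any site that is `NA` in any population they use.
#'
#' @param matrix a [genotype_matrix()].
#' @param populations character vector of population labels.
#' @return list with `freq` (pops x SNPs matrix, rownames = populations)
#'   and `n_chrom` (non-missing allele counts, same shape).
#' @export
pop_allele_freqs <- function(matrix, populations) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (length(populations) == 0) stop("populations must be non-empty")
  unknown <- setdiff(populations, matrix$samples$population)
  if (length(unknown) > 0) {
    stop("unknown populations: ", paste(unknown, collapse = ", "))
  }
  m <- ncol(matrix$calls)
  freq <- matrix(NA_real_, nrow = length(populations), ncol = m,
                 dimnames = list(populations, matrix$snps$snp_id))
  n_chrom <- matrix(0, nrow = length(populations), ncol = m,
                    dimnames = dimnames(freq))
  for (p in populations) {
    g <- matrix$calls[matrix$samples$population == p, , drop = FALSE]
    n_obs <- colSums(!is.na(g))
    tot <- colSums(g, na.rm = TRUE)
    freq[p, ] <- ifelse(n_obs > 0, tot / (2 * n_obs), NA_real_)
    n_chrom[p, ] <- 2 * n_obs
  }
  list(freq = freq, n_chrom = n_chrom)
}

# Block id per SNP: fixed-size windows of consecutive SNPs.
.make_blocks <- function(n_snps, block_size) {
  if (block_size < 1) stop("block_size must be >= 1")
  as.integer(ceiling(seq_len(n_snps) / block_size))
}

# Per-block sums of per-SNP statistics sharing one validity mask.
# stats_snp: n_snps x n_stats matrix (NA outside mask).
.block_sums <- function(stats_snp, valid, block_ids) {
  keep <- which(valid)
  if (length(keep) == 0) stop("no usable SNPs (all masked)")
  s <- rowsum(stats_snp[keep, , drop = FALSE], block_ids[keep])
  n <- rowsum(rep(1, length(keep)), block_ids[keep])[, 1]
  list(sums = s, counts = n)
}

# Delete-one block jackknife for a vector-valued mean statistic.
# Returns estimate, delete-one estimates, SE vector and covariance.
.block_jackknife <- function(sums, counts) {
  m <- nrow(sums)
  if (m < 2) stop("fewer than 2 usable blocks; lower block_size or add SNPs")
  tot <- colSums(sums)
  n <- sum(counts)
  est <- tot / n
  loo <- sweep(-sums, 2, tot, "+") / (n - counts)  # theta_(b)
  ctr <- sweep(loo, 2, colMeans(loo))
  cov <- (m - 1) / m * crossprod(ctr)
  list(est = est, loo = loo, se = sqrt(diag(cov)), cov = cov, n_blocks = m,
       n_snps = n)
}

#' f-statistics with block-jackknife standard errors
#'
#' `f4(A, B; C, D)` is the mean over SNPs of `(p_A - p_B)(p_C - p_D)`:
#' zero when the unrooted quartet is tree-like, nonzero under gene flow.
#' `f2(A, B)` is the mean of `(p_A - p_B)^2` minus the binomial sampling
#' terms `p(1-p)/(n_chrom - 1)` for each population (the unbiased
#' estimator). Standard errors come from a delete-one jackknife over
#' blocks of `block_size_snps` consecutive SNPs, which absorbs linkage
#' between nearby sites.
#'
#' @param matrix a [genotype_matrix()].
#' @param A,B,C,D population labels.
#' @param block_size_snps SNPs per jackknife block (default 500).
#' @return An `f_stat_result`: `type`, `pops`, `value`, `se`, `z`,
#'   `n_blocks`, `n_snps`.
#' @export
f4 <- function(matrix, A, B, C, D, block_size_snps = 500) {
  fr <- pop_allele_freqs(matrix, unique(c(A, B, C, D)))$freq
  d_snp <- (fr[A, ] - fr[B, ]) * (fr[C, ] - fr[D, ])
  valid <- !is.na(d_snp)
  blocks <- .make_blocks(ncol(fr), block_size_snps)
  bs <- .block_sums(cbind(d_snp), valid, blocks)
  jk <- .block_jackknife(bs$sums, bs$counts)
  .f_stat_result("f4", c(A, B, C, D), jk)
}

#' @rdname f4
#' @export
f2 <- function(matrix, A, B, block_size_snps = 500) {
  fr <- pop_allele_freqs(matrix, unique(c(A, B)))
  f <- fr$freq
  n <- fr$n_chrom
  corr_A <- f[A, ] * (1 - f[A, ]) / pmax(n[A, ] - 1, 1)
  corr_B <- f[B, ] * (1 - f[B, ]) / pmax(n[B, ] - 1, 1)
  d_snp <- (f[A, ] - f[B, ])^2 - corr_A - corr_B
  valid <- !is.na(d_snp) & n[A, ] >= 2 & n[B, ] >= 2
  blocks <- .make_blocks(ncol(f), block_size_snps)
  bs <- .block_sums(cbind(d_snp), valid, blocks)
  jk <- .block_jackknife(bs$sums, bs$counts)
  .f_stat_result("f2", c(A, B), jk)
}

.f_stat_result <- function(type, pops, jk) {
  value <- unname(jk$est[1])
  se <- unname(jk$se[1])
  structure(list(type = type, pops = pops, value = value, se = se,
                 z = if (se > 0) value / se else NA_real_,
                 n_blocks = jk$n_blocks, n_snps = jk$n_snps),
            class = "f_stat_result")
}

#' @export
print.f_stat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f  (%d SNPs, %d blocks)\n",
              x$type, paste(x$pops, collapse = ", "), x$value, x$se, x$z,
              x$n_snps, x$n_blocks))
  invisible(x)
}

# Shared machinery for the f4 systems used by the rank test and the
# weight fit: per-block sums of every needed f4, all computed on the
# intersection mask (sites defined in every involved population), so the
# statistic vector has a single jackknife covariance.
.f4_system <- function(matrix, pops, quartets, block_size) {
  fr <- pop_allele_freqs(matrix, pops)$freq
  valid <- colSums(is.na(fr)) == 0
  if (!any(valid)) stop("no SNPs covered in all populations")
  stats_snp <- vapply(quartets, function(q) {
    (fr[q[1], ] - fr[q[2], ]) * (fr[q[3], ] - fr[q[4], ])
  }, numeric(ncol(fr)))
  blocks <- .make_blocks(ncol(fr), block_size)
  bs <- .block_sums(stats_snp, valid, blocks)
  jk <- .block_jackknife(bs$sums, bs$counts)
  c(jk, list(sums = bs$sums, counts = bs$counts))
}

.solve_psd <- function(Q, b) {
  # ridge-regularize if numerically singular
  tries <- c(0, 1e-10, 1e-8, 1e-6)
  for (eps in tries) {
    Qr <- Q + diag(eps * mean(diag(Q)) + (eps > 0) * 1e-300, nrow(Q))
    ans <- tryCatch(solve(Qr, b), error = function(e) NULL)
    if (!is.null(ans)) {
      if (eps > 0) warning("singular covariance; ridge-regularized")
      return(ans)
    }
  }
  stop("jackknife covariance is singular beyond repair")
}

#' Rank test for the number of independent ancestry streams
#'
#' Tests whether the matrix of `f4(left_i, left_1; right_j, right_1)`
#' statistics has the stated rank — rank r means the left populations
#' descend from r + 1 independent ancestry streams relative to the right
#' panel. The statistic is a generalized least-squares distance between
#' the observed f4 matrix and its best rank-`rank` approximation, using
#' the block-jackknife covariance, referred to a chi-square with
#' `(L - 1 - rank)(R - 1 - rank)` degrees of freedom.
#'
#' @param matrix a [genotype_matrix()].
#' @param left_pops character vector (length >= rank + 2).
#' @param right_pops character vector (length >= rank + 2).
#' @param rank rank under the null (0 = all left pops form one stream).
#' @param block_size_snps SNPs per jackknife block.
#' @return list with `p_value`, `chi_sq`, `df`, `rank`, `n_blocks`.
#' @export
qpwave_rank_test <- function(matrix, left_pops, right_pops, rank = 0,
                             block_size_snps = 500) {
  L <- length(left_pops); R <- length(right_pops)
  if (L < rank + 2 || R < rank + 2) {
    stop("need at least rank + 2 populations on each side")
  }
  # column-major order (i fast, j slow) so matrix(f, L-1, R-1) is F[i, j]
  quartets <- list()
  for (j in 2:R) for (i in 2:L) {
    quartets[[length(quartets) + 1]] <-
      c(left_pops[i], left_pops[1], right_pops[j], right_pops[1])
  }
  sys <- .f4_system(matrix, unique(c(left_pops, right_pops)), quartets,
                    block_size_snps)
  f <- sys$est
  Q <- sys$cov
  df <- (L - 1 - rank) * (R - 1 - rank)
  if (rank == 0) {
    chi_sq <- drop(f %*% .solve_psd(Q, f))
  } else {
    Fm <- matrix(f, nrow = L - 1, ncol = R - 1)
    sv <- svd(Fm)
    A <- sv$u[, seq_len(rank), drop = FALSE] %*%
      diag(sv$d[seq_len(rank)], rank)
    B <- sv$v[, seq_len(rank), drop = FALSE]
    Qi_chol <- chol(Q + diag(1e-12 * mean(diag(Q)), nrow(Q)))
    obj <- function(A, B) {
      r <- f - as.vector(A %*% t(B))
      drop(r %*% .solve_psd(Q, r))
    }
    last <- obj(A, B)
    for (it in seq_len(100)) {
      # given B, vec(AB') is linear in vec(A); GLS update, then swap
      XB <- kronecker(B, diag(L - 1))
      QiXB <- apply(XB, 2, function(col) .solve_psd(Q, col))
      a <- solve(t(XB) %*% QiXB, t(QiXB) %*% f)
      A <- matrix(a, nrow = L - 1)
      XA <- kronecker(diag(R - 1), A)
      QiXA <- apply(XA, 2, function(col) .solve_psd(Q, col))
      b <- solve(t(XA) %*% QiXA, t(QiXA) %*% f)
      B <- t(matrix(b, nrow = rank))
      cur <- obj(A, B)
      if (abs(last - cur) < 1e-12 * max(1, abs(cur))) break
      last <- cur
    }
    chi_sq <- last
  }
  list(p_value = stats::pchisq(chi_sq, df, lower.tail = FALSE),
       chi_sq = chi_sq, df = df, rank = rank, n_blocks = sys$n_blocks)
}

# Build the y / X f4 system for a target + sources + right panel.
# y_j   = f4(T,  S1; R1, Rj)    j = 2..r
# X_js  = f4(Ss, S1; R1, Rj)    s = 2..k
# so that y = X beta with beta = alpha[2..k] and alpha_1 = 1 - sum(beta).
.qpadm_system <- function(matrix, target, sources, right_pops, block_size) {
  k <- length(sources); r <- length(right_pops)
  quartets <- list()
  for (j in 2:r) {
    quartets[[length(quartets) + 1]] <-
      c(target, sources[1], right_pops[1], right_pops[j])
  }
  if (k >= 2) {
    for (s in 2:k) for (j in 2:r) {
      quartets[[length(quartets) + 1]] <-
        c(sources[s], sources[1], right_pops[1], right_pops[j])
    }
  }
  sys <- .f4_system(matrix, unique(c(target, sources, right_pops)), quartets,
                    block_size)
  ny <- r - 1
  sys$y_idx <- seq_len(ny)
  sys$x_idx <- if (k >= 2) matrix(ny + seq_len((k - 1) * ny), nrow = ny)
               else matrix(integer(0), nrow = ny, ncol = 0)
  sys
}

# GLS solve of the admixture system from stat vector est and weight Qe.
.qpadm_solve <- function(est, y_idx, x_idx, Qe) {
  y <- est[y_idx]
  X <- matrix(est[x_idx], nrow = length(y_idx))
  if (ncol(X) == 0) return(numeric(0))
  QiX <- apply(X, 2, function(col) .solve_psd(Qe, col))
  QiX <- matrix(QiX, nrow = length(y))
  solve(t(X) %*% QiX, t(QiX) %*% y)[, 1]
}

#' Estimate admixture proportions from an f4 system
#'
#' Models the target's allele frequencies as a mixture
#' `p_T = sum_s alpha_s p_Ss` with `sum alpha = 1`, estimated by
#' generalized least squares on the system of f4 statistics relating
#' target and sources to a panel of right (outgroup) populations, with
#' the block-jackknife covariance as weight. The fit p-value is the
#' chi-square tail of the weighted residual with `r - k` degrees of
#' freedom (r right populations, k sources): small p means the source set
#' cannot explain the target. Infeasible fits (weights outside `[0, 1]`)
#' are flagged, not truncated. This is a self-contained simplified
#' estimator of the qpAdm type, not a port of AdmixTools; numerical
#' agreement with that software on real data is not promised.
#'
#' @param matrix a [genotype_matrix()].
#' @param target population label being modelled.
#' @param sources 2 to 5 source population labels.
#' @param right_pops at least `length(sources) + 1` outgroup labels.
#' @param block_size_snps SNPs per jackknife block.
#' @return An `admixture_fit`: `weights` (named, summing to 1), `se`,
#'   `p_value`, `feasible`, `df`, `n_blocks`.
#' @export
qpadm_fit <- function(matrix, target, sources, right_pops,
                      block_size_snps = 500) {
  k <- length(sources); r <- length(right_pops)
  if (k < 2 || k > 5) stop("need between 2 and 5 sources")
  if (r < k + 1) stop("need at least length(sources) + 1 right populations")
  if (anyDuplicated(c(target, sources, right_pops))) {
    stop("target, sources and right populations must be distinct")
  }
  sys <- .qpadm_system(matrix, target, sources, right_pops, block_size_snps)
  X <- matrix(sys$est[sys$x_idx], nrow = r - 1)
  # an ~zero column means source s is indistinguishable from the pivot
  # source in the right-population f4 space
  se_x <- matrix(sqrt(diag(sys$cov))[as.vector(sys$x_idx)], nrow = r - 1)
  tiny <- colSums(abs(X) > 5 * se_x) == 0 & colSums(abs(X)) < 1e-4
  if (any(tiny)) {
    stop("near-collinear sources: ", sources[1], " and ",
         sources[which(tiny)[1] + 1])
  }
  if (ncol(X) >= 2) {
    cx <- suppressWarnings(stats::cor(X))
    cx[!is.finite(cx)] <- 1
    diag(cx) <- 0
    if (max(abs(cx)) > 0.999) {
      worst <- which(abs(cx) == max(abs(cx)), arr.ind = TRUE)[1, ]
      stop("near-collinear sources: ", sources[worst[1] + 1], " and ",
           sources[worst[2] + 1])
    }
  }

  # step 1: GLS with the covariance of y alone
  Qy <- sys$cov[sys$y_idx, sys$y_idx, drop = FALSE]
  beta <- .qpadm_solve(sys$est, sys$y_idx, sys$x_idx, Qy)
  # step 2: re-weight with the covariance of the fitted residual
  # statistic (absorbs noise in X), then refit
  for (it in 1:2) {
    res_sums <- sys$sums[, sys$y_idx, drop = FALSE] -
      matrix(sys$sums[, sys$x_idx], nrow = nrow(sys$sums)) %*%
        kronecker(beta, diag(r - 1))
    jk_res <- .block_jackknife(res_sums, sys$counts)
    Qe <- jk_res$cov
    beta <- .qpadm_solve(sys$est, sys$y_idx, sys$x_idx, Qe)
  }
  alpha <- c(1 - sum(beta), beta)
  names(alpha) <- sources

  # jackknife SEs for the weights: refit on delete-one-block systems
  loo_alpha <- t(vapply(seq_len(nrow(sys$sums)), function(b) {
    est_b <- sys$loo[b, ]
    beta_b <- .qpadm_solve(est_b, sys$y_idx, sys$x_idx, Qe)
    c(1 - sum(beta_b), beta_b)
  }, numeric(k)))
  m <- nrow(loo_alpha)
  se <- sqrt((m - 1) / m *
               colSums(sweep(loo_alpha, 2, colMeans(loo_alpha))^2))
  names(se) <- sources

  y <- sys$est[sys$y_idx]
  Xhat <- matrix(sys$est[sys$x_idx], nrow = r - 1)
  resid <- y - if (ncol(Xhat) > 0) drop(Xhat %*% beta) else 0
  chi_sq <- drop(resid %*% .solve_psd(Qe, resid))
  df <- r - k
  structure(list(target = target, sources = sources, right_pops = right_pops,
                 weights = alpha, se = se,
                 p_value = stats::pchisq(chi_sq, df, lower.tail = FALSE),
                 chi_sq = chi_sq, df = df,
                 feasible = all(alpha >= 0 & alpha <= 1),
                 n_blocks = sys$n_blocks, block_size = block_size_snps),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: %s from %d sources (p = %.3g%s)\n", x$target,
              length(x$sources), x$p_value,
              if (x$feasible) "" else ", INFEASIBLE"))
  for (s in x$sources) {
    ci <- if (!is.null(x$ci)) sprintf("  [%.3f, %.3f]", x$ci[s, 1], x$ci[s, 2])
          else ""
    cat(sprintf("  %-24s %6.3f +/- %.3f%s\n", s, x$weights[s], x$se[s], ci))
  }
  invisible(x)
}

#' Scan source-population models of increasing complexity
#'
#' Fits every subset of `candidate_sources` of size `min_k` to `max_k`
#' with [qpadm_fit()]. A model is accepted when it is feasible (all
#' weights in `[0, 1]`) and its fit p-value exceeds `p_threshold`; the
#' selected model is the accepted one with the fewest sources, ties broken
#' by higher p-value and then lexicographically by source labels. If
#' nothing is accepted the selection is empty and the diagnostic ranking
#' is still returned.
#'
#' @param matrix a [genotype_matrix()].
#' @param target population being modelled.
#' @param candidate_sources pool of candidate source labels.
#' @param right_pops outgroup panel.
#' @param p_threshold acceptance gate on the fit p-value (default 0.05).
#' @param min_k,max_k model sizes to scan (defaults 2 and 5).
#' @param block_size_snps SNPs per jackknife block.
#' @return A `model_scan_result`: `models` (data.frame with sources, k,
#'   p_value, feasible, accepted), `fits` (list of `admixture_fit`),
#'   `selected` (index into `models`, or `NA`).
#' @export
model_scan <- function(matrix, target, candidate_sources, right_pops,
                       p_threshold = 0.05, min_k = 2, max_k = 5,
                       block_size_snps = 500) {
  if (length(candidate_sources) < min_k) {
    stop("need at least min_k candidate sources")
  }
  sizes <- seq(min_k, min(max_k, length(candidate_sources)))
  fits <- list()
  rows <- list()
  for (k in sizes) {
    combos <- utils::combn(sort(candidate_sources), k, simplify = FALSE)
    for (src in combos) {
      fit <- tryCatch(
        qpadm_fit(matrix, target, src, right_pops,
                  block_size_snps = block_size_snps),
        error = function(e) e)
      i <- length(fits) + 1
      if (inherits(fit, "error")) {
        fits[[i]] <- NULL
        rows[[i]] <- data.frame(
          model = paste(src, collapse = "+"), k = k, p_value = NA_real_,
          feasible = FALSE, accepted = FALSE,
          error = conditionMessage(fit), stringsAsFactors = FALSE)
      } else {
        fits[[i]] <- fit
        rows[[i]] <- data.frame(
          model = paste(src, collapse = "+"), k = k, p_value = fit$p_value,
          feasible = fit$feasible,
          accepted = fit$feasible && fit$p_value > p_threshold,
          error = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  models <- do.call(rbind, rows)
  acc <- which(models$accepted)
  selected <- NA_integer_
  if (length(acc) > 0) {
    ord <- acc[order(models$k[acc], -models$p_value[acc], models$model[acc])]
    selected <- ord[1]
  }
  structure(list(models = models, fits = fits, selected = selected,
                 p_threshold = p_threshold, target = target),
            class = "model_scan_result")
}

#' @export
print.model_scan_result <- function(x, ...) {
  cat(sprintf("model_scan for %s: %d models, %d accepted (p > %g)\n",
              x$target, nrow(x$models), sum(x$models$accepted), x$p_threshold))
  if (!is.na(x$selected)) {
    cat("selected:", x$models$model[x$selected],
        sprintf("(p = %.3g)\n", x$models$p_value[x$selected]))
  } else {
    cat("selected: none\n")
    print(utils::head(x$models[order(-x$models$p_value), ], 5),
          row.names = FALSE)
  }
  invisible(x)
}

#' Block-bootstrap confidence intervals for admixture weights
#'
#' Resamples jackknife blocks (consecutive-SNP windows) with replacement,
#' refits the weight system on each replicate with the original
#' generalized-least-squares weighting, and reports percentile 95%
#' intervals. Reproducible given `seed`.
#'
#' @inheritParams qpadm_fit
#' @param n_reps bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return The `admixture_fit` with an added `ci` matrix (`lower`,
#'   `upper` per source) and `boot_weights` replicate matrix.
#' @export
block_bootstrap_ci <- function(matrix, target, sources, right_pops,
                               n_reps = 1000, block_size_snps = 500,
                               seed = 1) {
  if (n_reps < 100) warning("fewer than 100 bootstrap replicates")
  fit <- qpadm_fit(matrix, target, sources, right_pops,
                   block_size_snps = block_size_snps)
  sys <- .qpadm_system(matrix, target, sources, right_pops, block_size_snps)
  m <- nrow(sys$sums)
  if (m < 10) stop("need at least 10 blocks for the bootstrap")
  r <- length(right_pops)
  beta0 <- fit$weights[-1]
  res_sums <- sys$sums[, sys$y_idx, drop = FALSE] -
    matrix(sys$sums[, sys$x_idx], nrow = m) %*%
      kronecker(beta0, diag(r - 1))
  Qe <- .block_jackknife(res_sums, sys$counts)$cov
  k <- length(sources)
  boot <- with_substream(seed, "block-bootstrap", {
    t(vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(m, m, replace = TRUE)
      est <- colSums(sys$sums[idx, , drop = FALSE]) / sum(sys$counts[idx])
      beta <- .qpadm_solve(est, sys$y_idx, sys$x_idx, Qe)
      c(1 - sum(beta), beta)
    }, numeric(k)))
  })
  colnames(boot) <- sources
  ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  fit$ci <- ci
  fit$boot_weights <- boot
  fit$n_reps <- n_reps
  fit
}

#' Serialize an admixture fit
#'
#' @param fit an `admixture_fit`.
#' @param path output file.
#' @param format `"tsv"` (per-source table) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_admixture_fit <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- data.frame(source = fit$sources,
                    weight = unname(fit$weights),
                    se = unname(fit$se),
                    ci_low = if (!is.null(fit$ci)) fit$ci[, "lower"] else NA,
                    ci_high = if (!is.null(fit$ci)) fit$ci[, "upper"] else NA,
                    p_fit = fit$p_value, stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(target = fit$target, fit = tab,
                              feasible = fit$feasible, df = fit$df,
                              n_blocks = fit$n_blocks),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
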