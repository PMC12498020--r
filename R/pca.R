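#' Standardize a genotype matrix for PCA
#'
#' Per SNP, missing calls are replaced by the site mean, values are
#' centered by the site mean and scaled by `sqrt(p(1-p))` where `p` is the
#' shrunk allele-frequency estimate `(1 + sum g) / (2 + 2 n_obs)`
#' (Patterson scaling, the drift-variance normalization standard in
#' population-structure PCA). Mean-imputed cells are therefore exactly 0.
#'
#' @param matrix a [genotype_matrix()]; every SNP needs >= 2 non-missing
#'   calls and a positive minor allele frequency (run QC first).
#' @return list with `z` (n_samples x n_snps numeric matrix), `site_means`,
#'   `site_scales` and `snp_ids`, for use when projecting held-out samples.
#' @export
standardize_genotypes <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  g <- matrix$calls
  fr <- .snp_freqs(g)
  bad <- fr$n_obs < 2 | is.na(fr$maf) | fr$maf == 0
  if (any(bad)) {
    stop("monomorphic or near-empty sites present (e.g. ",
         paste(utils::head(matrix$snps$snp_id[bad], 3), collapse = ", "),
         "); run QC with a positive MAF filter first")
  }
  mu <- colMeans(g, na.rm = TRUE)
  p_shrunk <- (1 + colSums(g, na.rm = TRUE)) / (2 + 2 * fr$n_obs)
  sc <- sqrt(p_shrunk * (1 - p_shrunk))
  z <- sweep(g, 2, mu, "-")
  z[is.na(z)] <- 0
  z <- sweep(z, 2, sc, "/")
  rownames(z) <- matrix$samples$sample_id
  list(z = z, site_means = mu, site_scales = sc, snp_ids = matrix$snps$snp_id)
}

#' Principal components of a genotype matrix
#'
#' Eigen-decomposition of the sample-by-sample covariance of the
#' standardized genotype matrix. Score columns are the unit-norm
#' eigenvectors (the convention of common genotype-PCA tools), so absolute
#' score magnitudes depend on sample size and are not comparable across
#' datasets. Because eigenvector signs are arbitrary, each component is
#' oriented so that the mean score of the `sign_anchor_population` (default
#' the alphabetically first population label) is >= 0, making downstream
#' extreme-value reports deterministic.
#'
#' @param matrix a [genotype_matrix()] with at least `K + 1` samples.
#' @param K number of components to keep (default 20).
#' @param sign_anchor_population population label used to orient signs.
#' @return A `pc_result`: `scores` (n x K), `eigenvalues` (non-increasing),
#'   `variance_explained`, `snp_weights` (n_snps x K, for projection),
#'   `sign_anchor`, `projected` flags, and the standardization constants.
#' @export
compute_pcs <- function(matrix, K = 20, sign_anchor_population = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  n <- nrow(matrix$calls)
  if (K > n - 1) {
    stop(sprintf("K = %d exceeds n_samples - 1 = %d", K, n - 1))
  }
  std <- standardize_genotypes(matrix)
  z <- std$z
  m <- ncol(z)
  cov_ss <- tcrossprod(z) / m
  eig <- eigen(cov_ss, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(K), drop = FALSE]
  lambda <- vals[seq_len(K)]

  pops <- matrix$samples$population
  anchor <- if (is.null(sign_anchor_population)) sort(unique(pops))[1]
            else sign_anchor_population
  if (!anchor %in% pops) stop("sign anchor population not present: ", anchor)
  anchor_rows <- pops == anchor
  for (k in seq_len(K)) {
    if (mean(scores[anchor_rows, k]) < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- matrix$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(K))

  w <- crossprod(z, scores)
  pos <- lambda > .Machine$double.eps * max(lambda, 1)
  w[, pos] <- sweep(w[, pos, drop = FALSE], 2, m * lambda[pos], "/")
  w[, !pos] <- 0

  structure(list(scores = scores, eigenvalues = lambda,
                 variance_explained = lambda / sum(vals),
                 snp_weights = w, sign_anchor = anchor,
                 projected = stats::setNames(rep(FALSE, n), rownames(scores)),
                 populations = stats::setNames(pops, rownames(scores)),
                 site_means = std$site_means, site_scales = std$site_scales,
                 snp_ids = std$snp_ids, n_snps = m),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("pc_result: %d samples x %d components (%d projected)\n",
              nrow(x$scores), ncol(x$scores), sum(x$projected)))
  ve <- utils::head(round(100 * x$variance_explained, 2), 5)
  cat("variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$variance_explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' Project held-out samples onto fitted principal axes
#'
#' Least-squares projection through the stored SNP weights, using each
#' sample's non-missing sites only (the partial inner product is rescaled
#' by the fraction of fit SNPs observed). Samples to project must not have
#' been part of the fit.
#'
#' @param pc_result a fitted `pc_result`.
#' @param matrix a [genotype_matrix()] holding the samples to project.
#' @param sample_ids ids within `matrix` to project.
#' @return A `pc_result` containing only the projected samples (scores,
#'   `projected` flags set); eigenvalues and weights are inherited.
#' @export
project_samples <- function(pc_result, matrix, sample_ids) {
  stopifnot(inherits(pc_result, "pc_result"),
            inherits(matrix, "genotype_matrix"))
  overlap_fit <- intersect(sample_ids, names(pc_result$projected))
  if (length(overlap_fit) > 0) {
    stop("samples already in the fit set: ",
         paste(overlap_fit, collapse = ", "))
  }
  K <- ncol(pc_result$scores)
  res <- pc_result
  res$scores <- matrix(numeric(0), nrow = 0, ncol = K,
                       dimnames = list(NULL, colnames(pc_result$scores)))
  res$projected <- stats::setNames(logical(0), character(0))
  res$populations <- stats::setNames(character(0), character(0))
  if (length(sample_ids) == 0) return(res)

  sub <- subset_genotypes(matrix, sample_ids = sample_ids)
  idx <- match(pc_result$snp_ids, sub$snps$snp_id)
  have <- !is.na(idx)
  if (!any(have)) stop("no overlapping SNPs between fit and projection data")
  g <- sub$calls[, idx[have], drop = FALSE]
  mu <- pc_result$site_means[have]
  sc <- pc_result$site_scales[have]
  w <- pc_result$snp_weights[have, , drop = FALSE]
  m_fit <- pc_result$n_snps

  z <- sweep(g, 2, mu, "-")
  obs <- !is.na(z)
  z[!obs] <- 0
  z <- sweep(z, 2, sc, "/")
  raw <- z %*% w
  m_obs <- rowSums(obs)
  if (any(m_obs == 0)) {
    stop("no overlapping SNPs for sample(s): ",
         paste(rownames(g)[m_obs == 0], collapse = ", "))
  }
  scores <- sweep(raw, 1, m_fit / m_obs, "*")
  rownames(scores) <- sub$samples$sample_id
  colnames(scores) <- colnames(pc_result$scores)
  res$scores <- scores
  res$projected <- stats::setNames(rep(TRUE, nrow(scores)), rownames(scores))
  res$populations <- stats::setNames(sub$samples$population, rownames(scores))
  res
}

#' Write PC scores as a TSV interchange table
#'
#' Columns: `sample_id`, `population`, `PC1..PCK` — the format consumed by
#' the screening and distance modules.
#'
#' @param pc_result a `pc_result`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_pc_scores <- function(pc_result, path) {
  tab <- data.frame(sample_id = rownames(pc_result$scores),
                    population = unname(pc_result$populations),
                    pc_result$scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
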