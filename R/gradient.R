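#' Euclidean distance between two samples in a PC subspace
#'
#' `d(i, j) = sqrt(sum_k (PC_ki - PC_kj)^2)` over the chosen components —
#' by default the triple selected by the screening step, since that is the
#' subspace in which cryptic structure is visible.
#'
#' @param scores_i,scores_j numeric score vectors (named by PC) or single
#'   rows of a score matrix.
#' @param pc_subset integer indices of the components to use.
#' @return A non-negative distance.
#' @export
pc_distance <- function(scores_i, scores_j, pc_subset) {
  scores_i <- as.numeric(scores_i)[pc_subset]
  scores_j <- as.numeric(scores_j)[pc_subset]
  if (anyNA(scores_i) || anyNA(scores_j)) {
    stop("missing score component in pc_subset")
  }
  sqrt(sum((scores_i - scores_j)^2))
}

# All-pairs distance matrix in the subspace.
.pc_distance_matrix <- function(scores, pc_subset) {
  x <- scores[, pc_subset, drop = FALSE]
  if (anyNA(x)) stop("missing score component in pc_subset")
  as.matrix(stats::dist(x))
}

#' Per-sample distance to the nearest member of each reference set
#'
#' For every sample, the minimum subspace distance to each named reference
#' set (a set of population labels). A reference sample's distance to its
#' own set is computed excluding itself, so reference individuals do not
#' trivially sit at zero. Plotting one reference distance against another
#' exposes admixture gradients between the two ancestries.
#'
#' @param scores n x K score matrix.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param reference_sets named list of character vectors of population
#'   labels; each must resolve to at least one sample.
#' @param pc_subset integer indices of the components to use.
#' @return data.frame with `sample_id`, `population`, and per reference
#'   set `dist_<name>` and `nearest_<name>` (the neighbor's id), plus the
#'   subset used as an attribute `pc_subset`.
#' @export
nearest_reference_distances <- function(scores, metadata, reference_sets,
                                        pc_subset) {
  if (length(reference_sets) == 0 || is.null(names(reference_sets))) {
    stop("reference_sets must be a named list")
  }
  pops <- .match_populations(scores, metadata)
  d <- .pc_distance_matrix(scores, pc_subset)
  diag(d) <- Inf  # self never its own nearest neighbor
  out <- data.frame(sample_id = rownames(scores), population = pops,
                    stringsAsFactors = FALSE)
  for (nm in names(reference_sets)) {
    ref_rows <- which(pops %in% reference_sets[[nm]])
    if (length(ref_rows) == 0) {
      stop("empty reference set: ", nm)
    }
    sub <- d[, ref_rows, drop = FALSE]
    j <- apply(sub, 1, which.min)
    out[[paste0("dist_", nm)]] <- sub[cbind(seq_len(nrow(sub)), j)]
    out[[paste0("nearest_", nm)]] <- rownames(scores)[ref_rows[j]]
  }
  attr(out, "pc_subset") <- pc_subset
  out
}

#' Population-mean reference distances
#'
#' Averages the per-sample nearest-reference distances of
#' [nearest_reference_distances()] by population — the summary used for
#' gradient plots and heat maps (both per-sample and population-mean views
#' are kept because either may be wanted downstream).
#'
#' @param gradient_table output of [nearest_reference_distances()].
#' @return data.frame keyed by population with mean `dist_*` columns.
#' @export
population_mean_distances <- function(gradient_table) {
  dist_cols <- grep("^dist_", names(gradient_table), value = TRUE)
  agg <- stats::aggregate(gradient_table[dist_cols],
                          by = list(population = gradient_table$population),
                          FUN = mean)
  agg[order(agg$population), , drop = FALSE]
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Ward linkage in its squared-distance (ward.D2) form, the variant whose
#' objective matches Euclidean-space variance minimization. Merge heights
#' are non-decreasing.
#'
#' @param distance_matrix square symmetric matrix with zero diagonal.
#' @return An [stats::hclust] tree.
#' @export
ward_clustering <- function(distance_matrix) {
  d <- .check_distance_matrix(distance_matrix)
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

.check_distance_matrix <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be >= 0")
  d
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centering of squared distances followed by the top-eigenvector
#' embedding. For a Euclidean-realizable matrix the embedded pairwise
#' distances reproduce the input (up to numerical tolerance). If fewer
#' positive eigenvalues exist than `dims`, a warning is issued and the
#' embedding is truncated.
#'
#' @param distance_matrix square symmetric matrix with zero diagonal.
#' @param dims target dimensionality (default 2).
#' @return n x d coordinate matrix (d <= dims).
#' @export
classical_mds <- function(distance_matrix, dims = 2) {
  d <- .check_distance_matrix(distance_matrix)
  n <- nrow(d)
  if (n == 1) {
    return(matrix(0, 1, 1, dimnames = list(rownames(d), "MDS1")))
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dims, n - 1), eig = TRUE)
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-9)
  if (n_pos < dims) {
    warning(sprintf("only %d positive eigenvalue(s); embedding truncated", n_pos))
  }
  coords <- fit$points[, seq_len(min(dims, max(n_pos, 1))), drop = FALSE]
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  rownames(coords) <- rownames(d)
  coords
}

#' Export a Ward tree as Newick with branch lengths
#'
#' @param tree an [stats::hclust] tree (e.g. from [ward_clustering()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
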