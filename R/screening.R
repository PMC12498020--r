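#' Define the groups whose discrimination is being screened for
#'
#' Named, disjoint sets of population labels (e.g. an early-Slavic set vs.
#' a Germanic set vs. a Baltic set). Groups that resolve to fewer than
#' `min_group_n` samples are rejected: with n = 1 a within-group standard
#' deviation does not exist and a singleton can never drive selection.
#'
#' @param groups named list of character vectors of population labels.
#' @param min_group_n minimum samples per group (default 3).
#' @return A `discrimination_spec`.
#' @export
discrimination_spec <- function(groups, min_group_n = 3) {
  if (length(groups) < 2 || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    stop("need >= 2 named groups")
  }
  all_pops <- unlist(groups)
  if (anyDuplicated(all_pops)) {
    stop("groups must be disjoint; duplicated: ",
         paste(unique(all_pops[duplicated(all_pops)]), collapse = ", "))
  }
  structure(list(groups = groups, min_group_n = as.integer(min_group_n)),
            class = "discrimination_spec")
}

# Map each sample to its group (NA when in no group); checks group sizes.
.resolve_groups <- function(populations, spec) {
  g <- rep(NA_character_, length(populations))
  for (nm in names(spec$groups)) {
    g[populations %in% spec$groups[[nm]]] <- nm
  }
  sizes <- table(factor(g, levels = names(spec$groups)))
  small <- sizes < spec$min_group_n
  if (any(small)) {
    stop("groups below min_group_n = ", spec$min_group_n, ": ",
         paste(names(sizes)[small], collapse = ", "))
  }
  g
}

#' Per-population summary statistics on every PC
#'
#' @param scores n x K score matrix (e.g. `pc_result$scores`).
#' @param metadata data.frame with `sample_id` and `population`, aligned to
#'   the score rows by `sample_id`.
#' @return data.frame with one row per (population, PC): `mean`, `sd`
#'   (`NA` for n = 1) and `n`.
#' @export
population_pc_stats <- function(scores, metadata) {
  pops <- .match_populations(scores, metadata)
  K <- ncol(scores)
  out <- lapply(sort(unique(pops)), function(p) {
    rows <- scores[pops == p, , drop = FALSE]
    data.frame(population = p, pc = seq_len(K),
               mean = colMeans(rows),
               sd = if (nrow(rows) > 1) apply(rows, 2, stats::sd) else NA_real_,
               n = nrow(rows), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.match_populations <- function(scores, metadata) {
  idx <- match(rownames(scores), metadata$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing samples: ",
         paste(rownames(scores)[is.na(idx)], collapse = ", "))
  }
  pops <- metadata$population[idx]
  if (anyNA(pops) || any(!nzchar(pops))) stop("every sample needs a population")
  pops
}

#' Flag populations with extreme mean scores on any PC
#'
#' A population is flagged on a PC when its mean score lies more than
#' `z_threshold` global standard deviations from the global mean, where the
#' global moments are taken over all sample scores on that PC (robust to
#' uneven population sizes). Populations smaller than `min_group_n` are
#' excluded from flagging and reported separately.
#'
#' @param scores n x K score matrix.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param z_threshold flagging threshold in global SDs (default 2).
#' @param min_group_n smallest population eligible for flagging.
#' @return list with `flagged` (population, pc, z, pop_mean) and
#'   `too_small` (populations excluded by size).
#' @export
detect_extremes <- function(scores, metadata, z_threshold = 2.0,
                            min_group_n = 3) {
  pops <- .match_populations(scores, metadata)
  gm <- colMeans(scores)
  gsd <- apply(scores, 2, stats::sd)
  if (any(gsd <= 0)) {
    stop("degenerate PC with zero global SD: ",
         paste(colnames(scores)[gsd <= 0], collapse = ", "))
  }
  sizes <- table(pops)
  eligible <- names(sizes)[sizes >= min_group_n]
  rows <- list()
  for (p in sort(eligible)) {
    pm <- colMeans(scores[pops == p, , drop = FALSE])
    z <- (pm - gm) / gsd
    hit <- which(abs(z) > z_threshold)
    for (k in hit) {
      rows[[length(rows) + 1]] <- data.frame(
        population = p, pc = k, z = z[k], pop_mean = pm[k],
        stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(rows) > 0) do.call(rbind, rows)
             else data.frame(population = character(0), pc = integer(0),
                             z = numeric(0), pop_mean = numeric(0))
  list(flagged = flagged,
       too_small = sort(names(sizes)[sizes < min_group_n]))
}

#' Group-discrimination score of a PC subset
#'
#' A multi-group variance-ratio (F-type) score on globally standardized
#' scores: `(trace(B)/(g-1)) / (trace(W)/(N-g))` with between- and
#' within-group scatter `B` and `W` accumulated over the subset
#' dimensions. Traces are invariant to rotation within the subset, the
#' ratio is invariant to rescaling all scores, and higher means better
#' separation. Under exchangeable labels the score hovers around 1; use
#' [permutation_null_scores()] for calibration. A subset in which every
#' group is a point mass gets the variance floor `1e-12` in the
#' denominator.
#'
#' @param scores n x K score matrix.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param spec a [discrimination_spec()].
#' @param pc_subset integer vector of PC indices (non-empty).
#' @param standardize z-score each component over the group members first
#'   (default). Disable only when the scores are already on a common scale
#'   — the score is then exactly invariant to rotations within the subset.
#' @return A non-negative score.
#' @export
discrimination_score <- function(scores, metadata, spec, pc_subset,
                                 standardize = TRUE) {
  if (length(pc_subset) == 0) stop("pc_subset must be non-empty")
  parts <- .discrimination_parts(scores, metadata, spec,
                                 standardize = standardize)
  .score_from_parts(parts, pc_subset)
}

# Per-PC between/within sums of squares for group members, on globally
# z-scored columns; computing them once makes the exhaustive subset search
# a table lookup.
.discrimination_parts <- function(scores, metadata, spec, standardize = TRUE) {
  pops <- .match_populations(scores, metadata)
  grp <- .resolve_groups(pops, spec)
  keep <- !is.na(grp)
  x <- scores[keep, , drop = FALSE]
  grp <- grp[keep]
  if (standardize) x <- .zscale(x)  # global standardization over group members
  gm <- colMeans(x)
  between <- numeric(ncol(x))
  within <- numeric(ncol(x))
  for (g in unique(grp)) {
    rows <- x[grp == g, , drop = FALSE]
    mu <- colMeans(rows)
    between <- between + nrow(rows) * (mu - gm)^2
    within <- within + colSums(sweep(rows, 2, mu)^2)
  }
  list(between = between, within = within,
       n = nrow(x), g = length(unique(grp)))
}

# z-score columns; constant columns are centered only (they then
# contribute nothing to either scatter term).
.zscale <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-300] <- 1
  sweep(sweep(x, 2, mu), 2, sds, "/")
}

.score_from_parts <- function(parts, pc_subset) {
  b <- sum(parts$between[pc_subset])
  w <- sum(parts$within[pc_subset])
  df1 <- parts$g - 1
  df2 <- parts$n - parts$g
  (b / df1) / (max(w, 1e-12) / df2)
}

#' Null distribution of discrimination scores by label permutation
#'
#' Recomputes the subset score after randomly permuting group labels among
#' group members; used to calibrate observed scores.
#'
#' @inheritParams discrimination_score
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Numeric vector of `n_perm` null scores.
#' @export
permutation_null_scores <- function(scores, metadata, spec, pc_subset,
                                    n_perm = 200, seed = 1) {
  pops <- .match_populations(scores, metadata)
  grp <- .resolve_groups(pops, spec)
  keep <- !is.na(grp)
  x <- .zscale(scores[keep, , drop = FALSE])
  grp <- grp[keep]
  with_substream(seed, "perm-null", {
    vapply(seq_len(n_perm), function(i) {
      gperm <- sample(grp)
      parts <- .parts_from_groups(x, gperm)
      .score_from_parts(parts, pc_subset)
    }, numeric(1))
  })
}

.parts_from_groups <- function(x, grp) {
  gm <- colMeans(x)
  between <- numeric(ncol(x))
  within <- numeric(ncol(x))
  for (g in unique(grp)) {
    rows <- x[grp == g, , drop = FALSE]
    mu <- colMeans(rows)
    between <- between + nrow(rows) * (mu - gm)^2
    within <- within + colSums(sweep(rows, 2, mu)^2)
  }
  list(between = between, within = within, n = nrow(x),
       g = length(unique(grp)))
}

#' Screen every principal component for group signal
#'
#' The single-PC stage of the systematic screening protocol: for each of
#' the K components it tabulates per-population statistics, flags
#' population extremes, and computes the single-PC discrimination score
#' for the requested groups.
#'
#' @param scores n x K score matrix.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param spec a [discrimination_spec()].
#' @param z_threshold extreme-value threshold in global SDs.
#' @return A `pc_screening_report`: `stats`, `extremes`, `too_small`,
#'   `discrimination` (pc, score, ranked), and the spec used.
#' @export
screen_all_pcs <- function(scores, metadata, spec, z_threshold = 2.0) {
  stats_tab <- population_pc_stats(scores, metadata)
  ext <- detect_extremes(scores, metadata, z_threshold = z_threshold,
                         min_group_n = spec$min_group_n)
  parts <- .discrimination_parts(scores, metadata, spec)
  disc <- data.frame(pc = seq_len(ncol(scores)),
                     score = vapply(seq_len(ncol(scores)), function(k) {
                       .score_from_parts(parts, k)
                     }, numeric(1)))
  disc <- disc[order(-disc$score, disc$pc), ]
  rownames(disc) <- NULL
  structure(list(stats = stats_tab, extremes = ext$flagged,
                 too_small = ext$too_small, discrimination = disc,
                 spec = spec, z_threshold = z_threshold),
            class = "pc_screening_report")
}

#' @export
print.pc_screening_report <- function(x, ...) {
  cat("pc_screening_report\n")
  cat(sprintf("  %d populations, %d PCs screened\n",
              length(unique(x$stats$population)), max(x$stats$pc)))
  cat(sprintf("  %d extreme (population, PC) flags at |z| > %.2f\n",
              nrow(x$extremes), x$z_threshold))
  top <- utils::head(x$discrimination, 3)
  cat("  top single-PC discrimination: ",
      paste(sprintf("PC%d (%.2f)", top$pc, top$score), collapse = ", "), "\n")
  if (!is.null(x$triples)) {
    cat("  selected triple: PC",
        paste(x$selected_triple, collapse = ", PC"), "\n", sep = "")
  }
  invisible(x)
}

#' Exhaustive search over PC subsets for maximum group discrimination
#'
#' Evaluates the discrimination score on every size-`arity` subset of the
#' K components (all C(K, 3) = 1,140 triples for K = 20) and returns the
#' full ranking. Ties break to the lexicographically smallest index tuple,
#' so the selection is deterministic.
#'
#' @inheritParams discrimination_score
#' @param arity subset size (default 3).
#' @return list with `ranking` (data.frame of subsets and scores, ranked
#'   non-increasing) and `selected` (integer vector, the argmax subset).
#' @export
search_pc_combinations <- function(scores, metadata, spec, arity = 3) {
  K <- ncol(scores)
  if (arity > K) stop(sprintf("arity = %d exceeds K = %d", arity, K))
  parts <- .discrimination_parts(scores, metadata, spec)
  combos <- utils::combn(K, arity)
  score <- vapply(seq_len(ncol(combos)), function(i) {
    .score_from_parts(parts, combos[, i])
  }, numeric(1))
  ranking <- data.frame(t(combos))
  names(ranking) <- paste0("pc_", seq_len(arity))
  ranking$score <- score
  ord <- do.call(order, c(list(-ranking$score),
                          unname(ranking[paste0("pc_", seq_len(arity))])))
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  selected <- as.integer(ranking[1, seq_len(arity)])
  list(ranking = ranking, selected = selected, n_evaluated = ncol(combos))
}

#' Full screening report: single-PC stage plus subset search
#'
#' Convenience wrapper combining [screen_all_pcs()] and
#' [search_pc_combinations()].
#'
#' @inheritParams search_pc_combinations
#' @param z_threshold extreme-value threshold in global SDs.
#' @return A `pc_screening_report` with `triples` and `selected_triple`.
#' @export
pc_screening_report <- function(scores, metadata, spec, arity = 3,
                                z_threshold = 2.0) {
  rep1 <- screen_all_pcs(scores, metadata, spec, z_threshold = z_threshold)
  sr <- search_pc_combinations(scores, metadata, spec, arity = arity)
  rep1$triples <- sr$ranking
  rep1$selected_triple <- sr$selected
  rep1
}

#' Serialize a screening report
#'
#' @param report a `pc_screening_report`.
#' @param path output file.
#' @param format `"json"` (full report) or `"tsv"` (discrimination table).
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- list(stats = report$stats, extremes = report$extremes,
                too_small = report$too_small,
                discrimination = report$discrimination,
                z_threshold = report$z_threshold)
    if (!is.null(report$triples)) {
      out$triples <- utils::head(report$triples, 50)
      out$selected_triple <- report$selected_triple
    }
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(report$discrimination, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
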