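#' Construct a genotype matrix object
#'
#' The central data container of the package: diploid (or pseudo-haploid)
#' genotype calls for a set of samples at a set of biallelic autosomal SNPs,
#' together with per-SNP and per-sample records. Calls count copies of the
#' alternate allele, so each entry is 0, 1, 2 or `NA` (missing).
#' Pseudo-haploid data, common in low-coverage ancient DNA, is simply a
#' matrix whose non-missing entries are all 0 or 2; no special flag is kept.
#'
#' @param calls integer matrix, samples in rows and SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `sample_id`, `population`, and
#'   optionally `sex` (`"M"`, `"F"` or `"U"`), `date_start`, `date_end`
#'   (integer years, negative = BCE) and `role` (one of `"source"`,
#'   `"target"`, `"reference"`, `"outgroup"`, `"unknown"`).
#' @param snps data.frame with columns `snp_id`, `chromosome`,
#'   `genetic_pos` (morgans, >= 0), `physical_pos` (1-based bp),
#'   `ref_allele`, `alt_allele`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- .complete_sample_records(samples)
  snps <- .complete_snp_records(snps)

  if (nrow(samples) != nrow(calls) || nrow(snps) != ncol(calls)) {
    stop(sprintf(
      "call matrix is %d x %d but there are %d sample records and %d SNP records",
      nrow(calls), ncol(calls), nrow(samples), nrow(snps)
    ))
  }
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0) {
    stop("invalid genotype codes (must be 0, 1, 2 or NA): ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  if (any(!nzchar(samples$population)) || anyNA(samples$population)) {
    stop("every sample needs a non-empty population label")
  }
  if (any(snps$physical_pos < 1)) stop("physical_pos must be >= 1")
  same <- snps$ref_allele == snps$alt_allele
  if (any(same)) {
    stop("ref_allele must differ from alt_allele at: ",
         paste(utils::head(snps$snp_id[same], 5), collapse = ", "))
  }
  bad_range <- !is.na(samples$date_start) & !is.na(samples$date_end) &
    samples$date_start > samples$date_end
  if (any(bad_range)) {
    stop("date_start > date_end for: ",
         paste(samples$sample_id[bad_range], collapse = ", "))
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_matrix")
}

.complete_sample_records <- function(samples) {
  if (is.null(samples$sample_id)) stop("sample table needs a sample_id column")
  if (is.null(samples$population)) stop("sample table needs a population column")
  if (is.null(samples$sex)) samples$sex <- "U"
  if (is.null(samples$date_start)) samples$date_start <- NA_integer_
  if (is.null(samples$date_end)) samples$date_end <- NA_integer_
  if (is.null(samples$role)) samples$role <- "unknown"
  if (!all(samples$sex %in% c("M", "F", "U"))) {
    stop("sex must be one of M, F, U")
  }
  roles <- c("source", "target", "reference", "outgroup", "unknown")
  if (!all(samples$role %in% roles)) {
    stop("role must be one of ", paste(roles, collapse = ", "))
  }
  samples[c("sample_id", "population", "sex", "date_start", "date_end", "role")]
}

.complete_snp_records <- function(snps) {
  if (is.null(snps$snp_id)) stop("SNP table needs a snp_id column")
  if (is.null(snps$chromosome)) snps$chromosome <- "1"
  if (is.null(snps$genetic_pos)) snps$genetic_pos <- 0
  if (is.null(snps$physical_pos)) snps$physical_pos <- seq_len(nrow(snps))
  if (is.null(snps$ref_allele)) snps$ref_allele <- "A"
  if (is.null(snps$alt_allele)) snps$alt_allele <- "G"
  snps$chromosome <- as.character(snps$chromosome)
  if (any(snps$genetic_pos < 0)) stop("genetic_pos must be >= 0 (morgans)")
  snps[c("snp_id", "chromosome", "genetic_pos", "physical_pos",
         "ref_allele", "alt_allele")]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  tab <- sort(table(x$samples$population), decreasing = TRUE)
  cat(sprintf("populations (%d): %s\n", length(tab),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("missingness: %.1f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample ids, SNP ids, or population labels
#'
#' Retained rows and columns keep their original order; sample and SNP
#' records are subset consistently with the call matrix. Unknown identifiers
#' are an error (all missing ids are listed).
#'
#' @param matrix a [genotype_matrix()].
#' @param sample_ids optional character vector of samples to keep.
#' @param snp_ids optional character vector of SNPs to keep.
#' @param populations optional character vector of population labels to keep
#'   (intersected with `sample_ids` if both given).
#' @return A `genotype_matrix` restricted to the requested samples/SNPs.
#' @export
subset_genotypes <- function(matrix, sample_ids = NULL, snp_ids = NULL,
                             populations = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  keep_s <- rep(TRUE, nrow(matrix$calls))
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, matrix$samples$sample_id)
    if (length(missing_ids) > 0) {
      stop("unknown sample ids: ", paste(missing_ids, collapse = ", "))
    }
    keep_s <- keep_s & matrix$samples$sample_id %in% sample_ids
  }
  if (!is.null(populations)) {
    missing_pops <- setdiff(populations, matrix$samples$population)
    if (length(missing_pops) > 0) {
      stop("unknown populations: ", paste(missing_pops, collapse = ", "))
    }
    keep_s <- keep_s & matrix$samples$population %in% populations
  }
  keep_v <- rep(TRUE, ncol(matrix$calls))
  if (!is.null(snp_ids)) {
    missing_ids <- setdiff(snp_ids, matrix$snps$snp_id)
    if (length(missing_ids) > 0) {
      stop("unknown snp ids: ", paste(missing_ids, collapse = ", "))
    }
    keep_v <- matrix$snps$snp_id %in% snp_ids
  }
  genotype_matrix(matrix$calls[keep_s, keep_v, drop = FALSE],
                  matrix$samples[keep_s, , drop = FALSE],
                  matrix$snps[keep_v, , drop = FALSE])
}
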