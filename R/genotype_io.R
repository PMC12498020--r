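#' Read a genotype matrix from EIGENSTRAT or PLINK-text files
#'
#' EIGENSTRAT is the three-file convention standard in ancient-DNA work: a
#' `.geno` digit matrix (one line per SNP, one character per sample, `9` =
#' missing), a `.snp` map and a `.ind` sample list. The PLINK-text dialect
#' accepted here is the `.traw` numeric table (tab-separated, one row per
#' SNP with columns CHR, SNP, (C)M, POS, COUNTED, ALT followed by one dosage
#' column per sample), with the `.ind`-style sample list supplying
#' population labels. Only biallelic autosomal-style sites are modelled;
#' calls always count alternate-allele copies.
#'
#' @param geno_path path to the `.geno` (or `.traw`) file.
#' @param snp_path path to the `.snp` file (ignored for `plink_text`, whose
#'   table embeds the map; may be `NULL` then).
#' @param ind_path path to the `.ind` file (`sample_id sex population`).
#' @param format `"eigenstrat"` or `"plink_text"`.
#' @return A [genotype_matrix()]. Sample and SNP order follow the files.
#' @seealso [write_genotypes()], [read_sample_metadata()]
#' @export
read_genotypes <- function(geno_path, snp_path = NULL, ind_path,
                           format = c("eigenstrat", "plink_text")) {
  format <- match.arg(format)
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample_id", "sex", "population"))
  samples <- data.frame(sample_id = ind$sample_id, population = ind$population,
                        sex = ind$sex, stringsAsFactors = FALSE)
  if (format == "eigenstrat") {
    if (is.null(snp_path)) stop("eigenstrat format needs a .snp file")
    snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(snp) < 6) {
      stop("parse error in ", snp_path,
           ": expected 6 columns (snp_id chrom genetic_pos physical_pos ref alt)")
    }
    names(snp)[1:6] <- c("snp_id", "chromosome", "genetic_pos", "physical_pos",
                         "ref_allele", "alt_allele")
    lines <- readLines(geno_path)
    if (length(lines) != nrow(snp)) {
      stop(sprintf("dimension mismatch: %s has %d lines but %s lists %d SNPs",
                   geno_path, length(lines), snp_path, nrow(snp)))
    }
    n <- nrow(samples)
    calls <- matrix(NA_integer_, nrow = n, ncol = length(lines))
    for (j in seq_along(lines)) {
      row <- .parse_geno_line(lines[j], n, geno_path, j)
      calls[, j] <- row
    }
    genotype_matrix(calls, samples, snp[1:6])
  } else {
    tab <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = "NA")
    fixed <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
    if (!all(fixed %in% names(tab))) {
      stop("parse error in ", geno_path, ": expected .traw header columns ",
           paste(fixed, collapse = " "))
    }
    sample_cols <- setdiff(names(tab), fixed)
    if (length(sample_cols) != nrow(samples)) {
      stop(sprintf("dimension mismatch: %s has %d sample columns but %s lists %d samples",
                   geno_path, length(sample_cols), ind_path, nrow(samples)))
    }
    if (!identical(sample_cols, samples$sample_id)) {
      stop("sample columns in ", geno_path, " do not match ", ind_path)
    }
    snps <- data.frame(snp_id = tab$SNP, chromosome = as.character(tab$CHR),
                       genetic_pos = tab$`(C)M` / 100, physical_pos = tab$POS,
                       ref_allele = tab$ALT, alt_allele = tab$COUNTED,
                       stringsAsFactors = FALSE)
    calls <- t(as.matrix(tab[sample_cols]))
    bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
    if (length(bad) > 0) {
      stop("parse error in ", geno_path, ": unknown dosage code ",
           paste(utils::head(unique(bad), 3), collapse = ", "))
    }
    genotype_matrix(calls, samples, snps)
  }
}

.parse_geno_line <- function(line, n_samples, path, line_no) {
  if (nchar(line) != n_samples) {
    stop(sprintf("dimension mismatch in %s line %d: %d characters for %d samples",
                 path, line_no, nchar(line), n_samples))
  }
  codes <- strtoi(strsplit(line, "", fixed = TRUE)[[1]])
  if (anyNA(codes) || any(!(codes %in% c(0L, 1L, 2L, 9L)))) {
    stop(sprintf("parse error in %s line %d: unknown genotype code", path, line_no))
  }
  codes[codes == 9L] <- NA_integer_
  codes
}

#' Write a genotype matrix to EIGENSTRAT or PLINK-text files
#'
#' Output is byte-stable for identical input (no timestamps), so files can
#' be hashed for provenance tracking.
#'
#' @param matrix a [genotype_matrix()].
#' @param prefix output path prefix; `.geno`/`.snp`/`.ind` (or
#'   `.traw`/`.ind`) are appended.
#' @param format `"eigenstrat"` or `"plink_text"`.
#' @return Invisibly, the named character vector of files written.
#' @export
write_genotypes <- function(matrix, prefix,
                            format = c("eigenstrat", "plink_text")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (nrow(matrix$calls) == 0) stop("no samples to write")
  if (ncol(matrix$calls) == 0) stop("no SNPs to write")
  ind_path <- paste0(prefix, ".ind")
  writeLines(paste(matrix$samples$sample_id, matrix$samples$sex,
                   matrix$samples$population, sep = "\t"), ind_path)
  if (format == "eigenstrat") {
    geno_path <- paste0(prefix, ".geno")
    snp_path <- paste0(prefix, ".snp")
    calls <- matrix$calls
    calls[is.na(calls)] <- 9L
    lines <- apply(calls, 2, paste, collapse = "")
    writeLines(lines, geno_path)
    s <- matrix$snps
    writeLines(paste(s$snp_id, s$chromosome, format(s$genetic_pos, digits = 10,
                                                    scientific = FALSE, trim = TRUE),
                     s$physical_pos, s$ref_allele, s$alt_allele, sep = "\t"),
               snp_path)
    invisible(c(geno = geno_path, snp = snp_path, ind = ind_path))
  } else {
    traw_path <- paste0(prefix, ".traw")
    s <- matrix$snps
    tab <- data.frame(CHR = s$chromosome, SNP = s$snp_id,
                      CM = s$genetic_pos * 100, POS = s$physical_pos,
                      COUNTED = s$alt_allele, ALT = s$ref_allele,
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(tab)[3] <- "(C)M"
    geno <- t(matrix$calls)
    colnames(geno) <- matrix$samples$sample_id
    tab <- cbind(tab, as.data.frame(geno, check.names = FALSE))
    utils::write.table(tab, traw_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(c(traw = traw_path, ind = ind_path))
  }
}

#' Read or write a sample metadata table
#'
#' Tab-separated with header `sample_id population sex date_start date_end
#' role`; dates are integer years with negative values meaning BCE.
#' [attach_sample_metadata()] merges such a table into an existing matrix
#' by `sample_id`.
#'
#' @param path TSV path.
#' @return `read_sample_metadata`: a data.frame of sample records.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "sex", "date_start", "date_end", "role")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("metadata ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  .complete_sample_records(tab[need])
}

#' @rdname read_sample_metadata
#' @param metadata data.frame of sample records.
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- .complete_sample_records(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_sample_metadata
#' @param matrix a [genotype_matrix()].
#' @export
attach_sample_metadata <- function(matrix, metadata) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  metadata <- .complete_sample_records(metadata)
  idx <- match(matrix$samples$sample_id, metadata$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing samples: ",
         paste(matrix$samples$sample_id[is.na(idx)], collapse = ", "))
  }
  genotype_matrix(matrix$calls, metadata[idx, , drop = FALSE], matrix$snps)
}
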