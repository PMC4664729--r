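# Readers and writers for the tabular formats the pipeline touches.
#
# Conventions: genomic intervals are BED-style 0-based half-open everywhere
# inside the package; SNP positions in the allele-count table are 1-based
# (VCF convention). Strand is ignored throughout. Readers validate and
# reject malformed input rather than coercing it; every accepted file
# round-trips through the paired writer.

ALLELE_COUNT_COLS <- c("snp_id", "chrom", "pos", "gene_id", "family",
                       "sample_type", "library_id", "count_E", "count_A")
EXPRESSION_COLS <- c("gene_id", "family", "sample_type", "library_id", "count")

#' Read a per-SNP allele count table
#'
#' Reads the tab-separated allele-count format: one row per SNP x family x
#' library with read counts supporting the European-lineage (`count_E`) and
#' Africanized-lineage (`count_A`) allele. Validates the closed `family` and
#' `sample_type` vocabularies, non-negative integer counts and uniqueness of
#' `(snp_id, family, library_id)`, reporting offending line numbers.
#'
#' @param path Path to a TSV file with header columns `snp_id`, `chrom`,
#'   `pos` (1-based), `gene_id`, `family`, `sample_type`, `library_id`,
#'   `count_E`, `count_A`.
#' @return A validated data frame of allele count records.
#' @export
read_allele_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(ALLELE_COUNT_COLS, names(x))
  if (length(missing_cols)) {
    stop("allele count file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, ALLELE_COUNT_COLS]
  lines <- seq_len(nrow(x)) + 1L  # header is line 1
  check_vocab(x$family, FAMILIES, "family", lines)
  check_vocab(x$sample_type, SAMPLE_TYPES, "sample_type", lines)
  for (col in c("pos", "count_E", "count_A")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad)) {
      stop(sprintf("invalid %s at line %s", col,
                   paste(utils::head(lines[bad], 5), collapse = ", ")),
           call. = FALSE)
    }
    x[[col]] <- as.integer(v)
  }
  key <- paste(x$snp_id, x$family, x$library_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (snp_id, family, library_id) at line ",
         paste(utils::head(lines[dup], 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_allele_counts
#' @param x A data frame of allele count records.
#' @export
write_allele_counts <- function(x, path) {
  utils::write.table(x[, ALLELE_COUNT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a gene-level expression count table
#'
#' @param path Path to a TSV with columns `gene_id`, `family`,
#'   `sample_type`, `library_id`, `count`.
#' @return A validated data frame.
#' @export
read_expression_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(EXPRESSION_COLS, names(x))
  if (length(missing_cols)) {
    stop("expression file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, EXPRESSION_COLS]
  lines <- seq_len(nrow(x)) + 1L
  check_vocab(x$family, FAMILIES, "family", lines)
  check_vocab(x$sample_type, SAMPLE_TYPES, "sample_type", lines)
  v <- suppressWarnings(as.numeric(x$count))
  bad <- is.na(v) | v < 0 | v != round(v)
  if (any(bad)) {
    stop("invalid count at line ",
         paste(utils::head(lines[bad], 5), collapse = ", "), call. = FALSE)
  }
  x$count <- as.integer(v)
  x
}

#' @rdname read_expression_counts
#' @param x A data frame of expression records.
#' @export
write_expression_counts <- function(x, path) {
  utils::write.table(x[, EXPRESSION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_bed <- function(path, cols, what) {
  x <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) {
      data.frame(matrix(character(0), ncol = length(cols)))
    }
  )
  if (nrow(x) == 0) {
    out <- as.data.frame(matrix(character(0), ncol = length(cols)),
                         stringsAsFactors = FALSE)
    names(out) <- cols
    out$start <- numeric(0); out$end <- numeric(0)
    return(out[, cols])
  }
  if (ncol(x) < length(cols)) {
    stop(what, " file needs ", length(cols), " columns: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, seq_along(cols)]
  names(x) <- cols
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (any(is.na(v))) {
      stop("non-numeric ", col, " at line ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           call. = FALSE)
    }
    x[[col]] <- v
  }
  bad <- x$start >= x$end
  if (any(bad)) {
    stop("start >= end at line ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' Read gene or QTL intervals from BED files
#'
#' Gene BED columns: `chrom`, `start`, `end`, `gene_id`. QTL BED columns:
#' `chrom`, `start`, `end`, `qtl_id`, `trait_class` (one of `defense`,
#' `reproduction`, `foraging`). Coordinates are 0-based half-open; files
#' have no header; empty files yield empty tables.
#'
#' @param path Path to a BED file.
#' @return A data frame of intervals.
#' @export
read_gene_bed <- function(path) {
  x <- read_bed(path, c("chrom", "start", "end", "gene_id"), "gene BED")
  x[, c("gene_id", "chrom", "start", "end")]
}

#' @rdname read_gene_bed
#' @export
read_qtl_bed <- function(path) {
  x <- read_bed(path, c("chrom", "start", "end", "qtl_id", "trait_class"),
                "QTL BED")
  if (nrow(x)) check_vocab(x$trait_class, TRAIT_CLASSES, "trait_class",
                           seq_len(nrow(x)))
  x[, c("qtl_id", "chrom", "start", "end", "trait_class")]
}

#' @rdname read_gene_bed
#' @param x A data frame of intervals.
#' @export
write_gene_bed <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), x$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_gene_bed
#' @export
write_qtl_bed <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), x$qtl_id,
               x$trait_class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene set from a plain-text file
#'
#' One gene identifier per line; `#` starts a comment; blank lines are
#' skipped. Duplicate identifiers are dropped with a warning; an empty file
#' yields an empty set with a warning.
#'
#' @param path Path to the gene-set file.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) {
    warning("gene set file is empty: ", path, call. = FALSE)
    return(character(0))
  }
  if (anyDuplicated(x)) {
    warning(sum(duplicated(x)), " duplicate gene ids dropped from ", path,
            call. = FALSE)
    x <- unique(x)
  }
  x
}

#' @rdname read_gene_set
#' @param ids Character vector of gene identifiers.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Select diagnostic SNPs from parental genotypes
#'
#' Keeps VCF sites where both parents of a cross are homozygous for
#' different alleles, so that every F1 offspring is heterozygous with known
#' allele parentage, and records which allele belongs to the European and
#' which to the Africanized lineage. Sites with a heterozygous or missing
#' parent genotype, identical parental alleles, or more than two alleles
#' among the two parents are excluded; exclusions are counted and reported
#' via [message()].
#'
#' @param vcf_path Path to a VCF 4.x file holding the two parental samples.
#' @param european_sample,africanized_sample Sample names of the
#'   European-lineage and Africanized-lineage parent.
#' @return Data frame `snp_id`, `chrom`, `pos` (1-based), `allele_E`,
#'   `allele_A`, with an `excluded` attribute giving per-reason counts.
#' @export
select_diagnostic_snps <- function(vcf_path, european_sample,
                                   africanized_sample) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  for (s in c(european_sample, africanized_sample)) {
    if (!s %in% colnames(gt)) {
      stop("sample not in VCF: ", s, call. = FALSE)
    }
  }
  fix <- vcfR::getFIX(vcf)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  parse_gt <- function(g) {
    # returns the single allele index for a homozygote, NA otherwise
    if (is.na(g)) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2 || any(parts == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(parts))
    if (anyNA(a) || a[1] != a[2]) return(NA_integer_)
    a[1]
  }
  e_idx <- vapply(gt[, european_sample], parse_gt, integer(1))
  a_idx <- vapply(gt[, africanized_sample], parse_gt, integer(1))

  alleles <- function(i) c(fix$REF[i], strsplit(fix$ALT[i], ",")[[1]])
  n <- nrow(fix)
  keep <- logical(n)
  allele_E <- allele_A <- rep(NA_character_, n)
  n_het <- n_same <- n_multi <- 0L
  for (i in seq_len(n)) {
    if (is.na(e_idx[i]) || is.na(a_idx[i])) { n_het <- n_het + 1L; next }
    if (e_idx[i] == a_idx[i]) { n_same <- n_same + 1L; next }
    al <- alleles(i)
    # two homozygous parents carry at most two alleles; guard against
    # malformed indices beyond the ALT list
    if (e_idx[i] + 1L > length(al) || a_idx[i] + 1L > length(al)) {
      n_multi <- n_multi + 1L; next
    }
    keep[i] <- TRUE
    allele_E[i] <- al[e_idx[i] + 1L]
    allele_A[i] <- al[a_idx[i] + 1L]
  }
  excluded <- c(het_or_missing = n_het, identical_homozygous = n_same,
                bad_allele_index = n_multi)
  message(sum(keep), " diagnostic SNPs kept; excluded: ",
          paste(names(excluded), excluded, sep = "=", collapse = ", "))
  out <- data.frame(
    snp_id = if (!is.null(fix$ID) && !all(is.na(fix$ID))) fix$ID[keep]
             else sprintf("%s_%s", fix$CHROM[keep], fix$POS[keep]),
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    allele_E = allele_E[keep],
    allele_A = allele_A[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory holding `allele_counts.tsv`, `expression_counts.tsv`,
#'   `genes.bed` and `qtl.bed`.
#' @return List with `counts`, `expression`, `genes`, `qtl`.
#' @export
read_cross_dataset <- function(dir) {
  list(
    counts = read_allele_counts(file.path(dir, "allele_counts.tsv")),
    expression = read_expression_counts(file.path(dir, "expression_counts.tsv")),
    genes = read_gene_bed(file.path(dir, "genes.bed")),
    qtl = read_qtl_bed(file.path(dir, "qtl.bed"))
  )
}
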