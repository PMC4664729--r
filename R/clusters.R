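# Detection of genomic clusters of maternally biased genes.
#
# The motivating observation is runs of neighbouring genes that are all
# extremely biased toward the maternal allele in one family (e.g. >90
# percent maternal across a few hundred kilobases). The scan is explicit
# and parameterised: a cluster is a maximal run of consecutive tested genes
# on one chromosome, each reaching the fraction threshold in at least one
# sample type, with bounded gaps between neighbours.

#' Scan for clusters of highly biased genes
#'
#' Orders the tested genes of each chromosome by start position and emits
#' every maximal run of at least `min_cluster_size` consecutive tested
#' genes whose maternal fraction in `family` reaches `fraction_threshold`
#' in at least one sample type, allowing at most `max_gap_bp` between the
#' end of one member and the start of the next. Untested genes are ignored,
#' so calls are invariant to adding genes without usable counts.
#'
#' @param psge A `psge_result` table from [run_psge()].
#' @param genes Gene locus table (`gene_id`, `chrom`, `start`, `end`).
#' @param family Family whose maternal fraction is scanned (`"EA"` or
#'   `"AE"`).
#' @param fraction_threshold Minimum maternal fraction (default 0.9).
#' @param max_gap_bp Maximum gap between consecutive members in basepairs.
#' @param min_cluster_size Minimum number of member genes.
#' @return Data frame: `chrom`, `start`, `end`, `family`, `n_genes`,
#'   `min_fraction`, `gene_ids` (comma-joined, ordered by position).
#' @export
scan_clusters <- function(psge, genes, family = "EA",
                          fraction_threshold = 0.9, max_gap_bp = 250000,
                          min_cluster_size = 8L) {
  check_vocab(family, FAMILIES, "family")
  stopifnot(fraction_threshold > 0.5, fraction_threshold <= 1,
            max_gap_bp >= 0, min_cluster_size >= 1)
  p <- psge[psge$family == family & psge$testable &
              !is.na(psge$maternal_fraction), , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), family = character(),
                      n_genes = integer(), min_fraction = numeric(),
                      gene_ids = character(), stringsAsFactors = FALSE)
  if (!nrow(p)) return(empty)
  # per gene: the largest maternal fraction over tested sample types
  frac <- tapply(p$maternal_fraction, p$gene_id, max)
  loc <- genes[genes$gene_id %in% names(frac), , drop = FALSE]
  loc$fraction <- as.numeric(frac[loc$gene_id])
  loc <- loc[order(loc$chrom, loc$start), , drop = FALSE]

  out <- list()
  for (chrom in unique(loc$chrom)) {
    g <- loc[loc$chrom == chrom, , drop = FALSE]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_cluster_size) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = chrom, start = min(g$start[run]), end = max(g$end[run]),
          family = family, n_genes = length(run),
          min_fraction = min(g$fraction[run]),
          gene_ids = paste(g$gene_id[run], collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_len(nrow(g))) {
      qualifies <- g$fraction[i] >= fraction_threshold
      if (!qualifies) { flush(run); run <- integer(0); next }
      if (length(run) && g$start[i] - g$end[run[length(run)]] > max_gap_bp) {
        flush(run); run <- integer(0)
      }
      run <- c(run, i)
    }
    flush(run)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
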