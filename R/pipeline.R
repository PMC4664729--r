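# End-to-end orchestration: allelic-bias testing, classification, DGE,
# enrichment and cluster scanning, with TSV/JSON artifact export. The
# pipeline itself is deterministic: identical inputs and configuration
# yield byte-identical artifacts.

#' Run the full reciprocal-cross bias analysis
#'
#' Executes the stages in order: per-gene allelic-bias tests
#' ([run_psge()]), nine-way classification at the first cutoff plus the
#' cutoff-robustness table ([classify_bias()], [cutoff_robustness()]),
#' differential expression ([run_dge()], when expression counts are given),
#' QTL and gene-set enrichment ([qtl_enrichment()],
#' [set_overlap_enrichment()], when loci/QTL are given), cluster scanning
#' ([scan_clusters()]), and the biased-vs-DE overlap test
#' ([biased_de_overlap()]). Every exclusion (untestable combinations,
#' MULTI genes) is counted in the report.
#'
#' @param counts Allele count table.
#' @param expression Optional expression count table.
#' @param genes Optional gene locus table.
#' @param qtl Optional QTL interval table.
#' @param gene_sets Optional named list of gene-id vectors; each set is
#'   tested against every biased category cohort.
#' @param bias_cutoffs Bias cutoffs; the first is the primary cutoff.
#' @param fdr_level FDR level for bias and DGE gates.
#' @param min_total_reads Testability threshold of [run_psge()].
#' @param cluster_family,fraction_threshold,max_gap_bp,min_cluster_size
#'   Parameters of [scan_clusters()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSV plus a `run_report.json` summary.
#' @return Object of class `cross_report`.
#' @export
run_pipeline <- function(counts, expression = NULL, genes = NULL, qtl = NULL,
                         gene_sets = list(), bias_cutoffs = c(0.6, 0.7),
                         fdr_level = 0.05, min_total_reads = 20,
                         cluster_family = "EA", fraction_threshold = 0.9,
                         max_gap_bp = 250000, min_cluster_size = 8L,
                         out_dir = NULL) {
  stopifnot(fdr_level > 0, fdr_level < 1)
  if (!length(bias_cutoffs) || any(bias_cutoffs <= 0.5 | bias_cutoffs > 1)) {
    stop("bias_cutoffs must lie in (0.5, 1]", call. = FALSE)
  }

  psge <- run_psge(counts, min_total_reads = min_total_reads,
                   fdr_level = fdr_level)
  message("psge: ", sum(psge$testable), " testable of ", nrow(psge),
          " gene x family x sample-type combinations")

  tau <- bias_cutoffs[1]
  classified <- classify_bias(psge, tau = tau, fdr_level = fdr_level)
  robustness <- cutoff_robustness(psge, cutoffs = bias_cutoffs,
                                  fdr_level = fdr_level)
  n_multi <- sum(classified$consolidated == MULTI, na.rm = TRUE)
  message("classification: ", sum(!is.na(classified$consolidated)),
          " genes classified at tau=", tau, "; ", n_multi,
          " MULTI genes excluded from enrichment cohorts")

  dge <- NULL
  if (!is.null(expression) && nrow(expression)) {
    dge <- run_dge(expression, fdr_level = fdr_level)
    message("dge: ", dge$summary$n_significant_unique,
            " unique significant genes")
  }

  enrichment <- NULL
  clusters <- NULL
  if (!is.null(genes) && nrow(genes)) {
    if (!is.null(qtl) && nrow(qtl)) {
      enrichment <- qtl_enrichment(classified, genes, qtl)
    }
    clusters <- scan_clusters(psge, genes, family = cluster_family,
                              fraction_threshold = fraction_threshold,
                              max_gap_bp = max_gap_bp,
                              min_cluster_size = min_cluster_size)
  }

  set_enrichment <- NULL
  if (length(gene_sets)) {
    universe <- unique(classified$gene_id)
    cohorts <- split(classified$gene_id, classified$consolidated)
    cohorts <- cohorts[setdiff(names(cohorts), c("unbiased", MULTI))]
    biased <- unlist(cohorts, use.names = FALSE)
    cohorts[["any_biased"]] <- biased
    rows <- list()
    for (set_id in names(gene_sets)) {
      for (cohort_id in names(cohorts)) {
        r <- set_overlap_enrichment(cohorts[[cohort_id]],
                                    gene_sets[[set_id]], universe)
        r$cohort_id <- cohort_id; r$target_id <- set_id
        rows[[length(rows) + 1L]] <- r
      }
    }
    set_enrichment <- do.call(rbind, rows)
    p_main <- ifelse(is.na(set_enrichment$p_2cell),
                     set_enrichment$p_1cell, set_enrichment$p_2cell)
    set_enrichment$n_tests <- nrow(set_enrichment)
    set_enrichment$p_bonferroni <- pmin(1, p_main * nrow(set_enrichment))
    set_enrichment <- set_enrichment[
      , c("cohort_id", "target_id", "observed", "expected",
          "chi_square_1cell", "chi_square_2cell", "p_1cell", "p_2cell",
          "p_bonferroni", "n_tests")]
  }

  biased_de <- NULL
  if (!is.null(dge)) {
    biased_de <- biased_de_overlap(classified, dge$table)
  }

  lev <- c(BIAS_CATEGORIES, MULTI)
  report <- structure(list(
    psge = psge,
    classified = classified,
    robustness = robustness,
    category_counts = table(factor(classified$consolidated, levels = lev)),
    dge = dge,
    qtl_enrichment = enrichment,
    set_enrichment = set_enrichment,
    clusters = clusters,
    biased_de_overlap = biased_de,
    stage_counts = list(
      n_count_records = nrow(counts),
      n_combinations = nrow(psge),
      n_testable = sum(psge$testable),
      n_classified = sum(!is.na(classified$consolidated)),
      n_multi = n_multi,
      n_biased = sum(!classified$consolidated %in% c("unbiased", MULTI) &
                       !is.na(classified$consolidated))
    ),
    config = list(bias_cutoffs = bias_cutoffs, fdr_level = fdr_level,
                  min_total_reads = min_total_reads,
                  cluster_family = cluster_family,
                  fraction_threshold = fraction_threshold,
                  max_gap_bp = max_gap_bp,
                  min_cluster_size = min_cluster_size),
    version = as.character(utils::packageVersion("crossbias"))
  ), class = "cross_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Overlap between biased and differentially expressed genes
#'
#' Treats the biased genes (any non-unbiased, non-MULTI consolidated
#' category) as the cohort and the significant DGE genes as the target set
#' over the universe of classified genes, via [set_overlap_enrichment()].
#'
#' @param classified A `bias_classification` table.
#' @param dge_table The `table` component of a `dge_result`.
#' @param universe Optional universe of gene ids (defaults to all genes in
#'   `classified`).
#' @return One-row enrichment data frame.
#' @export
biased_de_overlap <- function(classified, dge_table, universe = NULL) {
  if (is.null(universe)) universe <- unique(classified$gene_id)
  biased <- classified$gene_id[
    !is.na(classified$consolidated) &
      !classified$consolidated %in% c("unbiased", MULTI)]
  de <- unique(dge_table$gene_id[dge_table$significant])
  set_overlap_enrichment(intersect(biased, universe), de, universe)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, name) {
    if (is.null(x) || !nrow(x)) return(invisible(NULL))
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$psge, "psge_results.tsv")
  wt(report$classified, "categories.tsv")
  wt(report$robustness, "robustness.tsv")
  if (!is.null(report$dge)) wt(report$dge$table, "dge_results.tsv")
  wt(report$qtl_enrichment, "enrichment.tsv")
  wt(report$set_enrichment, "set_enrichment.tsv")
  wt(report$clusters, "clusters.tsv")

  json <- list(
    version = report$version,
    config = report$config,
    stage_counts = report$stage_counts,
    category_counts = as.list(report$category_counts),
    dge_summary = if (!is.null(report$dge)) report$dge$summary,
    biased_de_overlap = if (!is.null(report$biased_de_overlap))
      as.list(report$biased_de_overlap)
  )
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.cross_report <- function(x, ...) {
  sc <- x$stage_counts
  cat("Reciprocal-cross allelic bias analysis\n")
  cat(sprintf("  %d testable of %d gene x family x sample-type combinations\n",
              sc$n_testable, sc$n_combinations))
  cat(sprintf("  %d genes classified; %d biased, %d MULTI (tau = %g, FDR <= %g)\n",
              sc$n_classified, sc$n_biased, sc$n_multi,
              x$config$bias_cutoffs[1], x$config$fdr_level))
  cc <- x$category_counts
  cc <- cc[cc > 0]
  for (nm in names(cc)) cat(sprintf("    %-20s %d\n", nm, cc[nm]))
  if (!is.null(x$dge)) {
    cat(sprintf("  DGE: %d unique significant genes, %d over twofold\n",
                x$dge$summary$n_significant_unique,
                x$dge$summary$n_over_twofold))
  }
  if (!is.null(x$clusters) && nrow(x$clusters)) {
    cat(sprintf("  clusters: %d (sizes %s)\n", nrow(x$clusters),
                paste(x$clusters$n_genes, collapse = ", ")))
  }
  if (!is.null(x$qtl_enrichment) && nrow(x$qtl_enrichment)) {
    sig <- x$qtl_enrichment[x$qtl_enrichment$p_bonferroni <= 0.05, ]
    cat(sprintf("  QTL enrichment: %d of %d tests Bonferroni-significant\n",
                nrow(sig), nrow(x$qtl_enrichment)))
  }
  invisible(x)
}

#' @export
summary.cross_report <- function(object, ...) {
  print(object)
  if (!is.null(object$qtl_enrichment) && nrow(object$qtl_enrichment)) {
    cat("\nQTL enrichment tests:\n")
    print(object$qtl_enrichment, digits = 4)
  }
  invisible(object)
}
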