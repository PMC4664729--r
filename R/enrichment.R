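# Goodness-of-fit enrichment of bias categories in QTL intervals and gene
# sets. Expected counts come from the proportion of the gene universe that
# falls in the target (QTL trait class or gene set); the statistic is the
# chi-square goodness of fit with one degree of freedom, reported both in
# the two-cell form (in/out of the target) and the one-cell form
# (O - E)^2 / E used with directly supplied expectations.

#' Half-open interval overlap
#'
#' TRUE iff both intervals sit on the same chromosome and their 0-based
#' half-open ranges share at least one basepair (abutting intervals do not
#' overlap).
#'
#' @param chrom1,start1,end1 First interval (vectorised).
#' @param chrom2,start2,end2 Second interval.
#' @return Logical vector.
#' @export
interval_overlap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  chrom1 == chrom2 & start1 < end2 & start2 < end1
}

#' Gene x QTL trait-class overlap matrix
#'
#' Uses `GenomicRanges::findOverlaps()` to flag, for every gene locus,
#' whether it overlaps at least one QTL of each trait class.
#'
#' @param genes Gene locus table (`gene_id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param qtl QTL table (`qtl_id`, `chrom`, `start`, `end`, `trait_class`).
#' @return Logical matrix, rows named by gene, one column per trait class
#'   present in `qtl`.
#' @export
gene_qtl_overlap <- function(genes, qtl) {
  classes <- unique(qtl$trait_class)
  ov <- matrix(FALSE, nrow(genes), length(classes),
               dimnames = list(genes$gene_id, classes))
  if (!nrow(genes) || !nrow(qtl)) return(ov)
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end))
  gr_q <- GenomicRanges::GRanges(
    qtl$chrom, IRanges::IRanges(start = qtl$start + 1, end = qtl$end))
  # differing chromosome sets between genes and QTL are legitimate input;
  # silence the seqlevel-mismatch note findOverlaps emits for them
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_g, gr_q))
  gi <- S4Vectors::queryHits(hits)
  qi <- S4Vectors::subjectHits(hits)
  for (cl in classes) {
    sel <- qtl$trait_class[qi] == cl
    ov[unique(gi[sel]), cl] <- TRUE
  }
  ov
}

#' Chi-square goodness-of-fit enrichment test
#'
#' Compares an observed membership count against its expectation under
#' proportional allocation. The expectation is either supplied directly or
#' computed as `cohort_n * target_m / universe_n`. The one-cell statistic
#' `(O - E)^2 / E` is always reported; the two-cell statistic adds the
#' complementary cell `(O - E)^2 / (n - E)` and is reported whenever the
#' cohort size is known. Upper-tail p-values use one degree of freedom.
#'
#' @param observed Observed count `O`.
#' @param cohort_n Cohort size `n` (needed for the two-cell form).
#' @param expected Directly supplied expectation `E` (overrides the
#'   proportional computation).
#' @param target_m,universe_n Target and universe sizes used to compute `E`
#'   when `expected` is `NULL`.
#' @param n_tests Number of tests in the family (Bonferroni).
#' @return One-row data frame: `observed`, `expected`, `chi_square_1cell`,
#'   `chi_square_2cell`, `p_1cell`, `p_2cell`, `p_bonferroni`, `n_tests`.
#' @export
gof_enrichment_test <- function(observed, cohort_n = NULL, expected = NULL,
                                target_m = NULL, universe_n = NULL,
                                n_tests = 1L) {
  if (is.null(expected)) {
    stopifnot(!is.null(target_m), !is.null(universe_n), universe_n > 0)
    expected <- cohort_n * target_m / universe_n
  }
  if (expected <= 0) {
    stop("expected count is zero: goodness-of-fit statistic undefined",
         call. = FALSE)
  }
  if (!is.null(cohort_n) && observed > cohort_n) {
    stop("observed exceeds cohort size", call. = FALSE)
  }
  chi1 <- (observed - expected)^2 / expected
  p1 <- stats::pchisq(chi1, df = 1, lower.tail = FALSE)
  if (!is.null(cohort_n) && cohort_n > expected) {
    chi2 <- chi1 + (observed - expected)^2 / (cohort_n - expected)
    p2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_; p2 <- NA_real_
  }
  p_main <- if (is.na(p2)) p1 else p2
  data.frame(
    observed = observed, expected = expected,
    chi_square_1cell = chi1, chi_square_2cell = chi2,
    p_1cell = p1, p_2cell = p2,
    p_bonferroni = min(1, p_main * n_tests), n_tests = as.integer(n_tests)
  )
}

#' Bonferroni-adjusted p-values
#'
#' Family-wise error correction `min(1, p * m)` over the tests actually
#' performed (a thin wrapper over [stats::p.adjust()]).
#'
#' @param p Vector of p-values.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "bonferroni")
}

#' QTL enrichment of bias categories
#'
#' For every (bias category x QTL trait class) with a non-empty target,
#' counts the cohort genes overlapping at least one QTL of that class,
#' computes the expectation from the proportion of the gene universe (the
#' supplied locus table) overlapping the class, runs
#' [gof_enrichment_test()], and Bonferroni-corrects over the tests emitted.
#' `MULTI` and unclassified genes are excluded from cohorts. Following
#' Cochran's validity rule for the chi-square approximation, combinations
#' whose expected count falls below `min_expected` are tabulated in the
#' count matrix but not tested (set `min_expected = 0` to test everything).
#'
#' @param classified A `bias_classification` table.
#' @param genes Gene locus table defining the universe.
#' @param qtl QTL interval table.
#' @param min_expected Smallest expected count for which a chi-square test
#'   is emitted (default 5).
#' @return Data frame of enrichment results (one row per emitted test) with
#'   an `"overlap_counts"` attribute holding the per-category x class
#'   observed count matrix.
#' @export
qtl_enrichment <- function(classified, genes, qtl, min_expected = 5) {
  ov <- gene_qtl_overlap(genes, qtl)
  classes <- colnames(ov)
  n_universe <- nrow(genes)
  cl <- classified[!is.na(classified$consolidated) &
                     !classified$consolidated %in% c("unbiased", MULTI), ,
                   drop = FALSE]
  missing_loci <- !cl$gene_id %in% genes$gene_id
  if (nrow(cl) && mean(missing_loci) > 0.10) {
    warning(sum(missing_loci), " of ", nrow(cl),
            " cohort genes have no locus", call. = FALSE)
  }
  cats <- intersect(BIAS_CATEGORIES, unique(cl$consolidated))
  counts <- matrix(0L, length(cats), length(classes),
                   dimnames = list(cats, classes))
  rows <- list()
  for (cat in cats) {
    ids <- cl$gene_id[cl$consolidated == cat]
    ids <- ids[ids %in% rownames(ov)]
    for (tc in classes) {
      m_target <- sum(ov[, tc])
      o <- sum(ov[ids, tc])
      counts[cat, tc] <- o
      if (m_target == 0 || !length(ids)) next
      if (length(ids) * m_target / n_universe < min_expected) next
      r <- gof_enrichment_test(o, cohort_n = length(ids),
                               target_m = m_target, universe_n = n_universe)
      r$cohort_id <- cat; r$target_id <- tc
      rows[[length(rows) + 1L]] <- r
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    gof_enrichment_test(0, 1, expected = 1)[0, ]
  if (nrow(res)) {
    res$n_tests <- nrow(res)
    p_main <- ifelse(is.na(res$p_2cell), res$p_1cell, res$p_2cell)
    res$p_bonferroni <- pmin(1, p_main * nrow(res))
    res <- res[, c("cohort_id", "target_id", "observed", "expected",
                   "chi_square_1cell", "chi_square_2cell", "p_1cell",
                   "p_2cell", "p_bonferroni", "n_tests")]
  }
  rownames(res) <- NULL
  attr(res, "overlap_counts") <- counts
  res
}

#' Gene-set overlap enrichment
#'
#' Tests whether a cohort of genes over-represents a target gene set,
#' expecting `|cohort| * |target in universe| / |universe|` members under
#' proportional allocation.
#'
#' @param cohort Character vector of cohort gene ids (must be a subset of
#'   the universe).
#' @param target Character vector of target-set gene ids.
#' @param universe Character vector of universe gene ids.
#' @param n_tests Number of tests in the family (Bonferroni).
#' @return One-row enrichment data frame as in [gof_enrichment_test()].
#' @export
set_overlap_enrichment <- function(cohort, target, universe, n_tests = 1L) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  cohort <- unique(cohort)
  if (!all(cohort %in% universe)) {
    stop("cohort must be a subset of the universe", call. = FALSE)
  }
  target_u <- intersect(unique(target), universe)
  o <- length(intersect(cohort, target_u))
  e <- length(cohort) * length(target_u) / length(universe)
  gof_enrichment_test(o, cohort_n = length(cohort), expected = e,
                      n_tests = n_tests)
}

#' Permutation null of the QTL enrichment scan
#'
#' Shuffles consolidated category labels over the classified genes and
#' re-runs [qtl_enrichment()], recording for each permutation whether any
#' test reaches Bonferroni significance. Under the label-permutation null
#' the family-wise rate should not exceed `alpha`.
#'
#' @param classified A `bias_classification` table.
#' @param genes,qtl Locus and QTL tables.
#' @param n_perm Number of permutations.
#' @param alpha Family-wise level.
#' @param seed Optional RNG seed.
#' @param min_expected Expected-count floor as in [qtl_enrichment()].
#' @return List with `rate` (fraction of permutations with a
#'   Bonferroni-significant call) and `n_perm`.
#' @export
enrichment_permutation_null <- function(classified, genes, qtl,
                                        n_perm = 1000L, alpha = 0.05,
                                        seed = NULL, min_expected = 5) {
  if (!is.null(seed)) set.seed(seed)
  ov <- gene_qtl_overlap(genes, qtl)
  keep <- !is.na(classified$consolidated)
  ids <- classified$gene_id[keep]
  labels <- classified$consolidated[keep]
  in_universe <- ids %in% rownames(ov)
  ov_sub <- ov[ids[in_universe], , drop = FALSE]
  m_target <- colSums(ov)
  n_universe <- nrow(genes)
  cohort_cats <- setdiff(unique(labels), c("unbiased", MULTI))
  hits <- logical(n_perm)
  for (b in seq_len(n_perm)) {
    lab <- sample(labels)
    lab_u <- lab[in_universe]
    any_sig <- FALSE
    pvals <- c()
    for (cat in cohort_cats) {
      sel <- lab_u == cat
      n_cohort <- sum(lab == cat)
      if (!n_cohort) next
      for (tc in colnames(ov)) {
        if (m_target[tc] == 0) next
        o <- sum(ov_sub[sel, tc])
        e <- sum(sel) * m_target[tc] / n_universe
        if (e <= 0 || e < min_expected) next
        chi <- (o - e)^2 / e
        if (sum(sel) > e) chi <- chi + (o - e)^2 / (sum(sel) - e)
        pvals <- c(pvals, stats::pchisq(chi, 1, lower.tail = FALSE))
      }
    }
    if (length(pvals)) {
      any_sig <- any(pmin(1, pvals * length(pvals)) <= alpha)
    }
    hits[b] <- any_sig
  }
  list(rate = mean(hits), n_perm = n_perm)
}
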