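# Nine-way bias classification over the two reciprocal families.
#
# Per family and sample type a gene is Maternally biased (M), Paternally
# biased (P) or Not biased (N); the (state_EA, state_AE) pair maps
# bijectively onto nine categories that separate parent-of-origin effects
# (maternal/paternal in both families, or in one family only) from
# allele-of-origin effects (the same lineage's allele preferred in both
# families, which appears maternal in one family and paternal in the other).

STATE_PAIR_CATEGORY <- c(
  "M|M" = "maternal_both",
  "P|P" = "paternal_both",
  "M|N" = "ea_maternal_only",
  "N|M" = "ae_maternal_only",
  "P|N" = "ea_paternal_only",
  "N|P" = "ae_paternal_only",
  "M|P" = "european_allele",
  "P|M" = "africanized_allele",
  "N|N" = "unbiased"
)

#' Per-family bias state
#'
#' A family's call is `M` (maternal) when the FDR gate and the magnitude
#' gate both pass (`q <= fdr_level` and maternal fraction `b >= tau`,
#' inclusive), `P` when `q <= fdr_level` and `b <= 1 - tau`, and `N`
#' otherwise. Untestable entries yield `NA`.
#'
#' @param b Maternal fraction (vectorised).
#' @param q BH-adjusted p-value.
#' @param tau Bias cutoff in `(0.5, 1]` (default 0.6: biased means at least
#'   60 percent of reads from one parent).
#' @param fdr_level FDR gate (default 0.05).
#' @return Character vector of `"M"`, `"P"`, `"N"` (or `NA`).
#' @export
family_state <- function(b, q, tau = 0.6, fdr_level = 0.05) {
  stopifnot(tau > 0.5, tau <= 1, fdr_level > 0, fdr_level < 1)
  out <- rep(NA_character_, length(b))
  ok <- !is.na(b) & !is.na(q)
  out[ok] <- "N"
  out[ok & q <= fdr_level & b >= tau] <- "M"
  out[ok & q <= fdr_level & b <= 1 - tau] <- "P"
  out
}

#' Bias category from the pair of family states
#'
#' @param state_EA,state_AE Bias states (`"M"`, `"P"`, `"N"`) of the EA and
#'   AE family for one sample type (vectorised). A missing state yields `NA`
#'   (the gene cannot be classified for that sample type).
#' @return One of the nine bias categories.
#' @export
classify_gene <- function(state_EA, state_AE) {
  out <- STATE_PAIR_CATEGORY[paste(state_EA, state_AE, sep = "|")]
  out[is.na(state_EA) | is.na(state_AE)] <- NA_character_
  unname(out)
}

#' Consolidate per-sample-type categories for one gene
#'
#' A confident call in one sample type dominates unbiased calls in the
#' others; two or more distinct non-unbiased categories make the gene
#' `MULTI` (excluded from enrichment cohorts downstream).
#'
#' @param categories Character vector of per-sample-type categories
#'   (`NA` entries, i.e. unclassifiable sample types, are dropped).
#' @return A single category, `"MULTI"`, or `NA` when nothing was
#'   classifiable.
#' @export
reconcile_samples <- function(categories) {
  cats <- categories[!is.na(categories)]
  if (!length(cats)) return(NA_character_)
  nb <- setdiff(unique(cats), "unbiased")
  if (length(nb) == 0) return("unbiased")
  if (length(nb) == 1) return(nb)
  MULTI
}

#' Classify every gene into the nine-way bias category system
#'
#' For each gene and sample type with both families testable, derives the
#' family states at cutoff `tau`, maps the pair to a category, and
#' consolidates across sample types via [reconcile_samples()]. A gene
#' testable in only one family is not classified for that sample type.
#'
#' @param psge A `psge_result` table from [run_psge()].
#' @param tau Bias cutoff in `(0.5, 1]`.
#' @param fdr_level FDR gate.
#' @return Data frame of class `bias_classification`: `gene_id`, one
#'   category column per sample type, `consolidated`,
#'   `n_sample_types_tested`.
#' @export
classify_bias <- function(psge, tau = 0.6, fdr_level = 0.05) {
  stopifnot(tau > 0.5, tau <= 1)
  p <- psge[psge$testable, , drop = FALSE]
  p$state <- family_state(p$maternal_fraction, p$q_value, tau, fdr_level)
  key <- function(g, st) paste(g, st, sep = "\t")
  ea <- p[p$family == "EA", ]
  ae <- p[p$family == "AE", ]
  genes <- sort(unique(psge$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  sts <- intersect(SAMPLE_TYPES, unique(psge$sample_type))
  for (st in sts) {
    s_ea <- ea$state[match(key(genes, st), key(ea$gene_id, ea$sample_type))]
    s_ae <- ae$state[match(key(genes, st), key(ae$gene_id, ae$sample_type))]
    out[[st]] <- classify_gene(s_ea, s_ae)
  }
  cat_mat <- as.matrix(out[, sts, drop = FALSE])
  out$consolidated <- apply(cat_mat, 1, reconcile_samples)
  out$n_sample_types_tested <- rowSums(!is.na(cat_mat))
  attr(out, "tau") <- tau
  attr(out, "fdr_level") <- fdr_level
  class(out) <- c("bias_classification", "data.frame")
  out
}

#' Category counts across a range of bias cutoffs
#'
#' Re-runs the classification at each cutoff and tabulates consolidated
#' category counts (including `MULTI`). Because the per-family gate is
#' monotone in the cutoff, biased-category membership can only shrink (or
#' migrate out of `MULTI`) as the cutoff grows.
#'
#' @param psge A `psge_result` table.
#' @param cutoffs Vector of cutoffs, each in `(0.5, 1]`.
#' @param fdr_level FDR gate.
#' @return Long data frame: `cutoff`, `category`, `n_genes`.
#' @export
cutoff_robustness <- function(psge, cutoffs = c(0.6, 0.7), fdr_level = 0.05) {
  if (!length(cutoffs) || any(cutoffs <= 0.5 | cutoffs > 1)) {
    stop("cutoffs must lie in (0.5, 1]", call. = FALSE)
  }
  rows <- lapply(cutoffs, function(tau) {
    cl <- classify_bias(psge, tau = tau, fdr_level = fdr_level)
    lev <- c(BIAS_CATEGORIES, MULTI)
    tab <- table(factor(cl$consolidated, levels = lev))
    data.frame(cutoff = tau, category = lev, n_genes = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
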