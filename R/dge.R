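# Negative-binomial exact-test differential expression between families.
#
# A desk-scale, fully specified variant of the Robinson-Smyth conditional
# exact test for count data: effective library sizes from a median-of-ratios
# composition factor, a method-of-moments common dispersion, quantile
# adjustment of counts to a common library size, and a two-sided conditional
# p-value that sums the probabilities of all splits of the pseudo-count
# total as or less likely than the observed one.

#' Effective library sizes by median-of-ratios
#'
#' For each library, the median over genes of the ratio between its
#' depth-normalised count and the gene's geometric mean across libraries
#' (genes with a zero in any library are skipped). The factors are scaled
#' to geometric mean one and multiplied by the raw totals.
#'
#' @param mat Gene x library count matrix with library column names.
#' @return List with `scale_factors` and `effective_sizes` (both named by
#'   library).
#' @export
normalize_libsizes <- function(mat) {
  mat <- as.matrix(mat)
  totals <- colSums(mat)
  if (any(totals == 0)) {
    stop("library has all-zero counts: ",
         paste(colnames(mat)[totals == 0], collapse = ", "), call. = FALSE)
  }
  prop <- sweep(mat, 2, totals, "/")
  pos <- rowSums(prop > 0) == ncol(prop)
  if (!any(pos)) {
    warning("no gene observed in every library; scale factors set to 1",
            call. = FALSE)
    s <- rep(1, ncol(mat))
  } else {
    ref <- exp(rowMeans(log(prop[pos, , drop = FALSE])))
    s <- apply(prop[pos, , drop = FALSE] / ref, 2, stats::median)
    s <- s / geometric_mean(s)
  }
  names(s) <- colnames(mat)
  list(scale_factors = s, effective_sizes = s * totals)
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Counts are scaled to the mean effective library size; within each group
#' with replication the residual variance in excess of the (scaled) Poisson
#' component is pooled over genes against the squared means:
#' `phi = sum(v - k * m) / sum(m^2)`, floored at zero, where `k` is the
#' group's mean scaling factor.
#'
#' @param mat Gene x library count matrix.
#' @param groups Factor/character of group labels per library (families).
#' @param effective_sizes Effective sizes from [normalize_libsizes()].
#' @return Non-negative common dispersion estimate.
#' @export
estimate_common_dispersion <- function(mat, groups, effective_sizes) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat),
            length(effective_sizes) == ncol(mat))
  if (!any(table(groups) >= 2)) {
    stop("no replicated group: supply a dispersion estimate explicitly",
         call. = FALSE)
  }
  nbar <- mean(effective_sizes)
  k <- nbar / effective_sizes
  y <- sweep(mat, 2, k, "*")
  num <- 0; den <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    if (sum(sel) < 2) next
    yg <- y[, sel, drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1, stats::var)
    kbar <- mean(k[sel])
    use <- m > 0
    num <- num + sum(v[use] - kbar * m[use])
    den <- den + sum(m[use]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

# Quantile map a count from NB(mean_in, phi) to NB(mean_out, phi) via the
# mid-probability of the observed value; the map is the identity when the
# means agree. phi = 0 uses the Poisson limit.
q2q_count <- function(y, mean_in, mean_out, phi) {
  if (mean_in == mean_out) return(y)
  if (mean_in <= 0) return(0)
  if (phi == 0) {
    u <- stats::ppois(y - 1, mean_in) + 0.5 * stats::dpois(y, mean_in)
    return(stats::qpois(pmin(u, 1 - 1e-12), mean_out))
  }
  size <- 1 / phi
  u <- stats::pnbinom(y - 1, size = size, mu = mean_in) +
    0.5 * stats::dnbinom(y, size = size, mu = mean_in)
  stats::qnbinom(pmin(u, 1 - 1e-12), size = size, mu = mean_out)
}

#' Conditional exact test for a difference in negative-binomial means
#'
#' Counts of each library are quantile-adjusted to the geometric-mean
#' effective size, summed within groups, and the two-sided p-value is the
#' sum of the conditional probabilities (given the pseudo-count total) of
#' every split as or less likely than the observed one. At `phi = 0` the
#' conditional distribution is binomial and, with equal library sizes, the
#' test reduces to the exact binomial enumeration.
#'
#' @param y1,y2 Counts of the gene in the libraries of group 1 / group 2.
#' @param size1,size2 Effective library sizes.
#' @param phi Common negative-binomial dispersion (`>= 0`).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(y1, y2, size1, size2, phi) {
  stopifnot(length(y1) == length(size1), length(y2) == length(size2),
            all(size1 > 0), all(size2 > 0))
  if (phi < 0) stop("dispersion phi must be >= 0", call. = FALSE)
  if (sum(y1) + sum(y2) == 0) return(1)
  n1 <- length(y1); n2 <- length(y2)
  lambda <- (sum(y1) + sum(y2)) / (sum(size1) + sum(size2))
  nstar <- geometric_mean(c(size1, size2))
  p1 <- vapply(seq_len(n1), function(i) {
    q2q_count(y1[i], lambda * size1[i], lambda * nstar, phi)
  }, numeric(1))
  p2 <- vapply(seq_len(n2), function(i) {
    q2q_count(y2[i], lambda * size2[i], lambda * nstar, phi)
  }, numeric(1))
  s1 <- round(sum(p1)); s2 <- round(sum(p2))
  total <- s1 + s2
  if (total == 0) return(1)
  k <- 0:total
  if (phi == 0) {
    lp <- stats::dbinom(k, total, n1 / (n1 + n2), log = TRUE)
  } else {
    # conditional split distribution: free of the common mean because both
    # group sums share the NB probability parameter
    lp <- stats::dnbinom(k, size = n1 / phi, mu = n1, log = TRUE) +
      stats::dnbinom(total - k, size = n2 / phi, mu = n2, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[s1 + 1] * (1 + 1e-8)]))
}

#' Differential expression between the reciprocal families
#'
#' Per sample type: normalises library sizes, estimates the common
#' dispersion, applies [nb_exact_test()] to every gene (EA vs AE), adjusts
#' p-values by Benjamini-Hochberg across genes, and flags `q <= fdr_level`.
#' Also assembles the cross-sample-type summary: unique significant genes,
#' pairwise overlap between sample types, and the number of significant
#' genes exceeding a twofold change.
#'
#' @param expression Long expression table (`gene_id`, `family`,
#'   `sample_type`, `library_id`, `count`).
#' @param fdr_level Significance level on the adjusted p-value.
#' @return List of class `dge_result`: `table` (gene x sample type results),
#'   `summary`, `dispersions`.
#' @export
run_dge <- function(expression, fdr_level = 0.05) {
  stopifnot(all(EXPRESSION_COLS %in% names(expression)))
  out <- list()
  disp <- c()
  for (st in intersect(SAMPLE_TYPES, unique(expression$sample_type))) {
    e <- expression[expression$sample_type == st, , drop = FALSE]
    mat <- tapply(e$count, list(e$gene_id, e$library_id), sum)
    mat[is.na(mat)] <- 0
    lib_fam <- e$family[match(colnames(mat), e$library_id)]
    norm <- normalize_libsizes(mat)
    eff <- norm$effective_sizes
    phi <- estimate_common_dispersion(mat, lib_fam, eff)
    disp[st] <- phi
    sel1 <- lib_fam == "EA"; sel2 <- lib_fam == "AE"
    nbar <- mean(eff)
    pvals <- vapply(seq_len(nrow(mat)), function(i) {
      nb_exact_test(mat[i, sel1], mat[i, sel2], eff[sel1], eff[sel2], phi)
    }, numeric(1))
    mean_ea <- rowMeans(sweep(mat[, sel1, drop = FALSE], 2, eff[sel1], "/")) * nbar
    mean_ae <- rowMeans(sweep(mat[, sel2, drop = FALSE], 2, eff[sel2], "/")) * nbar
    q <- bh_fdr(pvals)
    out[[st]] <- data.frame(
      gene_id = rownames(mat), sample_type = st,
      mean_EA = mean_ea, mean_AE = mean_ae,
      log2fc = log2((mean_ea + 0.5) / (mean_ae + 0.5)),
      p_value = pvals, q_value = q, significant = q <= fdr_level,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL

  sig <- tab[tab$significant, , drop = FALSE]
  sts <- unique(tab$sample_type)
  overlap <- list()
  if (length(sts) > 1) {
    for (i in seq_len(length(sts) - 1)) {
      for (j in seq(i + 1, length(sts))) {
        a <- sig$gene_id[sig$sample_type == sts[i]]
        b <- sig$gene_id[sig$sample_type == sts[j]]
        overlap[[paste(sts[i], sts[j], sep = "-")]] <- length(intersect(a, b))
      }
    }
  }
  max_lfc <- tapply(abs(sig$log2fc), sig$gene_id, max)
  summary <- list(
    n_significant_unique = length(unique(sig$gene_id)),
    overlap_between_sample_types = unlist(overlap),
    n_over_twofold = sum(max_lfc > 1)
  )
  structure(list(table = tab, summary = summary, dispersions = disp,
                 fdr_level = fdr_level),
            class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat("Negative-binomial exact-test differential expression\n")
  cat(sprintf("  %d gene x sample-type tests; %d unique significant genes (q <= %g)\n",
              nrow(x$table), x$summary$n_significant_unique, x$fdr_level))
  cat(sprintf("  %d significant genes with |log2 fold change| > 1\n",
              x$summary$n_over_twofold))
  cat("  common dispersion per sample type:",
      paste(sprintf("%s=%.3g", names(x$dispersions), x$dispersions),
            collapse = ", "), "\n")
  invisible(x)
}
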