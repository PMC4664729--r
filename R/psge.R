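# Per-gene allelic-bias testing.
#
# The inferential target is a parent-of-origin effect on allele usage within
# one family and sample type: do the maternal reads deviate from half of the
# total, allowing for extra-binomial variation between replicate libraries?
# The test is a beta-binomial likelihood-ratio test of H0: mu = 0.5 (rho
# free) against H1: mu, rho free, with the intra-class correlation rho
# capturing replicate-level overdispersion. When the fitted (or fixed)
# overdispersion is zero the model is a pooled binomial and the p-value is
# taken from the exact two-sided binomial test instead of the chi-square
# approximation.

#' Maternal read fraction
#'
#' Converts lineage-labelled counts to the maternal scale of a family: in
#' the EA family (European mother) the European-lineage reads are maternal;
#' in the AE family the Africanized-lineage reads are. Zero totals yield
#' `NA` (the caller must mark such entries untestable).
#'
#' @param count_E,count_A Reads supporting the European / Africanized allele.
#' @param family `"EA"` or `"AE"` (vectorised).
#' @return Maternal fraction in `[0, 1]`, `NA` where the total is zero.
#' @export
maternal_fraction <- function(count_E, count_A, family) {
  check_vocab(family, FAMILIES, "family")
  total <- count_E + count_A
  m <- ifelse(family == "EA", count_E, count_A)
  ifelse(total > 0, m / total, NA_real_)
}

# Lean beta-binomial log-likelihood factory: caches the combinatorial term
# once per (m, n) vector; rho = 0 falls back to the binomial kernel.
bb_loglik_fn <- function(m, n) {
  const <- sum(lchoose(n, m))
  M <- sum(m); N <- sum(n)
  function(mu, rho) {
    if (mu <= 0 || mu >= 1) {
      if ((mu <= 0 && M > 0) || (mu >= 1 && M < N)) return(-Inf)
      return(0)
    }
    if (rho == 0) {
      return(const + M * log(mu) + (N - M) * log1p(-mu))
    }
    theta <- (1 - rho) / rho
    a <- mu * theta
    b <- (1 - mu) * theta
    const + sum(lbeta(m + a, n - m + b)) - length(n) * lbeta(a, b)
  }
}

# Profile log-likelihood over mu for fixed rho.
bb_profile_mu <- function(ll, M, N, rho) {
  if (rho == 0) {
    mu_hat <- M / N
    return(list(mu = mu_hat, ll = ll(mu_hat, 0)))
  }
  opt <- stats::optimize(function(mu) ll(mu, rho),
                         interval = c(1e-6, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-5)
  # the boundary MLE can beat the interior optimum when all reads agree
  mu2 <- min(max(M / N, 1e-6), 1 - 1e-6)
  ll2 <- ll(mu2, rho)
  if (ll2 > opt$objective) list(mu = mu2, ll = ll2)
  else list(mu = opt$maximum, ll = opt$objective)
}

RHO_GRID_BODY <- c(1e-3, 4e-3, 0.012, 0.03, 0.07, 0.15, 0.3, 0.55, 0.8)

# Maximise a log-likelihood over rho on [0, max_rho]: coarse grid, then
# local refinement; ties (within 1e-7) broken toward the smallest rho.
bb_maximize_rho <- function(ll_of_rho, max_rho) {
  grid <- c(0, RHO_GRID_BODY[RHO_GRID_BODY < max_rho], max_rho)
  vals <- vapply(grid, ll_of_rho, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  rho_hat <- grid[best]; ll_hat <- vals[best]
  if (hi > lo) {
    opt <- stats::optimize(ll_of_rho, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-4)
    if (opt$objective > ll_hat) {
      rho_hat <- opt$maximum; ll_hat <- opt$objective
    }
  }
  # prefer the boundary rho = 0 under likelihood ties
  ll0 <- vals[1]
  if (ll0 >= ll_hat - 1e-7) {
    rho_hat <- 0; ll_hat <- ll0
  }
  list(rho = rho_hat, ll = ll_hat)
}

#' Beta-binomial likelihood-ratio test of allelic bias
#'
#' Tests H0: maternal fraction mu = 0.5 against H1: mu free, with the
#' beta-binomial intra-class correlation rho profiled out under both
#' hypotheses (bounded to `[0, max_rho]`, likelihood ties broken toward the
#' smaller rho). The statistic is `lrt = 2 * (l1 - l0) >= 0` and the p-value
#' comes from the chi-square distribution with 1 degree of freedom; when
#' both fits sit at the rho = 0 boundary (or `rho = 0` is supplied) the
#' model reduces to a pooled binomial and the exact two-sided binomial
#' p-value (probability-mass ordering) is reported instead.
#'
#' @param m Maternal read counts, one entry per replicate library.
#' @param n Total read counts per library.
#' @param rho Optional fixed intra-class correlation; `NULL` (default)
#'   profiles it out.
#' @param max_rho Upper bound of the rho search.
#' @return Object of class `bias_test`: a list with `lrt`, `p_value`,
#'   `mu_hat`, `rho_hat`, `maternal`, `total`, `n_libraries`, `method`.
#'   All-zero totals yield an untestable result (`NA` statistics).
#' @export
bias_test <- function(m, n, rho = NULL, max_rho = 0.95) {
  stopifnot(length(m) == length(n), all(n >= 0), all(m >= 0), all(m <= n))
  keep <- n > 0
  m <- m[keep]; n <- n[keep]
  out <- list(lrt = NA_real_, p_value = NA_real_, mu_hat = NA_real_,
              rho_hat = NA_real_, maternal = sum(m), total = sum(n),
              n_libraries = length(n), method = "untestable")
  class(out) <- "bias_test"
  if (!length(n)) return(out)
  M <- sum(m); N <- sum(n)
  ll <- bb_loglik_fn(m, n)

  binom_branch <- function() {
    mu_hat <- M / N
    out$lrt <<- max(0, 2 * (ll(mu_hat, 0) - ll(0.5, 0)))
    out$mu_hat <<- mu_hat
    out$rho_hat <<- 0
    out$p_value <<- binom_two_sided_p(M, N)
    out$method <<- "binomial-exact"
  }

  if (!is.null(rho)) {
    stopifnot(rho >= 0, rho < 1)
    if (rho == 0) {
      binom_branch()
      return(out)
    }
    p1 <- bb_profile_mu(ll, M, N, rho)
    out$lrt <- max(0, 2 * (p1$ll - ll(0.5, rho)))
    out$mu_hat <- p1$mu
    out$rho_hat <- rho
    out$p_value <- stats::pchisq(out$lrt, df = 1, lower.tail = FALSE)
    out$method <- "betabinomial-lrt"
    return(out)
  }

  alt <- bb_maximize_rho(function(r) bb_profile_mu(ll, M, N, r)$ll, max_rho)
  null <- bb_maximize_rho(function(r) ll(0.5, r), max_rho)
  if (alt$rho == 0 && null$rho == 0) {
    binom_branch()
    return(out)
  }
  mu_hat <- bb_profile_mu(ll, M, N, alt$rho)$mu
  out$lrt <- max(0, 2 * (alt$ll - null$ll))
  out$mu_hat <- mu_hat
  out$rho_hat <- alt$rho
  out$p_value <- stats::pchisq(out$lrt, df = 1, lower.tail = FALSE)
  out$method <- "betabinomial-lrt"
  out
}

#' @export
print.bias_test <- function(x, ...) {
  if (x$method == "untestable") {
    cat("Allelic bias test: untestable (no reads)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Allelic bias test (%s)\n  maternal %d / %d reads over %d libraries\n  mu_hat = %.4f, rho_hat = %.4f, LRT = %.3f, p = %.4g\n",
    x$method, x$maternal, x$total, x$n_libraries, x$mu_hat, x$rho_hat,
    x$lrt, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper over
#' [stats::p.adjust()] kept as the package's named FDR surface).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, each `>=` its p-value and `<= 1`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Run per-gene allelic-bias tests for every family and sample type
#'
#' Aggregates SNP-level counts to the gene level (summing a gene's
#' diagnostic SNPs within each library — SNPs of one gene share phase
#' through the F1 design), marks combinations whose summed depth falls
#' below `min_total_reads` untestable, runs [bias_test()] on the rest, and
#' applies Benjamini-Hochberg FDR within each family x sample type stratum
#' (each family's bias is tested separately). Genes containing a deeply
#' covered SNP (total >= 20) whose fraction deviates from the gene's by
#' more than 0.3 are flagged as discordant but not down-weighted.
#'
#' @param counts Allele count table as from [read_allele_counts()] or
#'   [simulate_allele_counts()].
#' @param min_total_reads Minimum summed reads per (gene, family,
#'   sample type) for testability.
#' @param fdr_level FDR level recorded in the result (gating happens in
#'   classification).
#' @return Data frame of class `psge_result`: `gene_id`, `family`,
#'   `sample_type`, `maternal_count`, `paternal_count`, `maternal_fraction`,
#'   `lrt_stat`, `p_value`, `q_value`, `testable`, `snp_discordant`.
#' @export
run_psge <- function(counts, min_total_reads = 20, fdr_level = 0.05) {
  stopifnot(all(ALLELE_COUNT_COLS %in% names(counts)))
  stopifnot(min_total_reads >= 0, fdr_level > 0, fdr_level < 1)
  total <- counts$count_E + counts$count_A
  maternal <- ifelse(counts$family == "EA", counts$count_E, counts$count_A)

  # gene-level: sum a gene's SNPs within each library
  sep <- "\t"
  lib_key <- paste(counts$gene_id, counts$family, counts$sample_type,
                   counts$library_id, sep = sep)
  agg <- rowsum(cbind(m = maternal, n = total), lib_key)
  parts <- do.call(rbind, strsplit(rownames(agg), sep, fixed = TRUE))
  lib <- data.frame(gene_id = parts[, 1], family = parts[, 2],
                    sample_type = parts[, 3], m = agg[, "m"], n = agg[, "n"],
                    stringsAsFactors = FALSE)

  grp_key <- paste(lib$gene_id, lib$family, lib$sample_type, sep = sep)
  m_split <- split(lib$m, grp_key)
  n_split <- split(lib$n, grp_key)
  gparts <- do.call(rbind, strsplit(names(m_split), sep, fixed = TRUE))

  # per-SNP discordance within each (gene, family, sample type)
  snp_key <- paste(counts$gene_id, counts$family, counts$sample_type,
                   counts$snp_id, sep = sep)
  snp_agg <- rowsum(cbind(m = maternal, n = total), snp_key)
  sparts <- do.call(rbind, strsplit(rownames(snp_agg), sep, fixed = TRUE))
  snp_grp <- paste(sparts[, 1], sparts[, 2], sparts[, 3], sep = sep)

  res <- data.frame(
    gene_id = gparts[, 1], family = gparts[, 2], sample_type = gparts[, 3],
    maternal_count = vapply(m_split, sum, numeric(1)),
    paternal_count = vapply(n_split, sum, numeric(1)) -
      vapply(m_split, sum, numeric(1)),
    stringsAsFactors = FALSE
  )
  tot <- res$maternal_count + res$paternal_count
  res$maternal_fraction <- ifelse(tot > 0, res$maternal_count / tot, NA_real_)
  res$testable <- tot >= max(min_total_reads, 1)

  res$lrt_stat <- NA_real_
  res$p_value <- NA_real_
  idx <- which(res$testable)
  for (i in idx) {
    bt <- bias_test(m_split[[i]], n_split[[i]])
    res$lrt_stat[i] <- bt$lrt
    res$p_value[i] <- bt$p_value
  }
  res$maternal_fraction[!res$testable & tot == 0] <- NA_real_

  res$q_value <- NA_real_
  for (fam in FAMILIES) {
    for (st in SAMPLE_TYPES) {
      sel <- res$family == fam & res$sample_type == st & res$testable
      if (any(sel)) res$q_value[sel] <- bh_fdr(res$p_value[sel])
    }
  }

  # discordance flag
  gene_frac <- res$maternal_fraction[match(snp_grp, paste(
    res$gene_id, res$family, res$sample_type, sep = sep))]
  snp_frac <- ifelse(snp_agg[, "n"] > 0, snp_agg[, "m"] / snp_agg[, "n"], NA)
  disc <- snp_agg[, "n"] >= 20 & !is.na(gene_frac) &
    abs(snp_frac - gene_frac) > 0.3
  disc_groups <- unique(snp_grp[which(disc)])
  res$snp_discordant <- paste(res$gene_id, res$family, res$sample_type,
                              sep = sep) %in% disc_groups

  res <- res[, c("gene_id", "family", "sample_type", "maternal_count",
                 "paternal_count", "maternal_fraction", "lrt_stat",
                 "p_value", "q_value", "testable", "snp_discordant")]
  rownames(res) <- NULL
  attr(res, "min_total_reads") <- min_total_reads
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("psge_result", "data.frame")
  res
}
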