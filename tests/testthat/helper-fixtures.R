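# Shared fixtures and independent oracles used across test files.

# A small, fast configuration covering all moving parts.
tiny_config <- function(..., seed = 42L) {
  defaults <- list(
    n_genes = 120L, n_chromosomes = 4L, chrom_length = 3e6,
    category_counts = c(ea_maternal_only = 15L, ae_maternal_only = 3L,
                        maternal_both = 3L, paternal_both = 3L,
                        european_allele = 8L, africanized_allele = 3L,
                        ea_paternal_only = 2L, ae_paternal_only = 2L),
    planted_clusters = list(list(
      name = "cl1", chrom = "chr2", start = 5e5, span = 410000L,
      n_genes = 13L, category = "ea_maternal_only")),
    qtl_layout = data.frame(
      qtl_id = c("Q1", "Q2", "Q3"), chrom = c("chr2", "chr3", "chr1"),
      start = c(4e5, 1e5, 2e5), end = c(1.2e6, 9e5, 1.1e6),
      trait_class = c("defense", "foraging", "reproduction"),
      enrich_category = c("ea_maternal_only", "european_allele", NA),
      enrich_odds = c(2, 3, 1), stringsAsFactors = FALSE),
    n_de_genes = 20L, n_de_strong = 12L, seed = seed
  )
  override <- list(...)
  args <- defaults
  args[names(override)] <- override  # full replacement, no nested merging
  do.call(sim_config, args)
}

# Brute-force conditional-split oracle for the exact test at phi = 0 with
# equal library sizes: enumerate every split of the total as Binomial(T, w).
oracle_split_p <- function(s1, total, w = 0.5) {
  d <- stats::dbinom(0:total, total, w)
  sum(d[d <= d[s1 + 1] * (1 + 1e-8)])
}

# Independent grid maximisation of the beta-binomial likelihood, used as the
# oracle for the LRT statistic (coarse but unoptimised-path independent).
oracle_bb_lrt <- function(m, n, max_rho = 0.95) {
  ll <- function(mu, rho) sum(dbetabinom(m, n, mu, rho, log = TRUE))
  mus <- seq(0.001, 0.999, length.out = 401)
  rhos <- c(0, exp(seq(log(1e-4), log(max_rho), length.out = 61)))
  best1 <- -Inf; best0 <- -Inf; rho1 <- NA
  for (r in rhos) {
    v <- vapply(mus, ll, numeric(1), rho = r)
    if (max(v) > best1) { best1 <- max(v); rho1 <- r }
    v0 <- ll(0.5, r)
    if (v0 > best0) best0 <- v0
  }
  list(lrt = max(0, 2 * (best1 - best0)), rho1 = rho1)
}

# Minimal psge-like table builder for classification and cluster tests.
make_psge_rows <- function(gene_id, family, sample_type, b, q,
                           testable = TRUE, total = 1000L) {
  maternal <- round(b * total)
  data.frame(
    gene_id = gene_id, family = family, sample_type = sample_type,
    maternal_count = maternal, paternal_count = total - maternal,
    maternal_fraction = b, lrt_stat = 1, p_value = q, q_value = q,
    testable = testable, snp_discordant = FALSE, stringsAsFactors = FALSE
  )
}

write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tqueen\tdrone",
    "chr1\t100\ts1\tA\tG\t50\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\ts2\tC\tT\t50\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t300\ts3\tG\tA\t50\tPASS\t.\tGT\t0/0\t0/0",
    "chr1\t400\ts4\tT\tC,G\t50\tPASS\t.\tGT\t1/1\t2/2",
    "chr1\t500\ts5\tA\tC\t50\tPASS\t.\tGT\t1|1\t0|0"
  ), path)
  path
}
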