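# Synthetic reciprocal-cross generator: layout, truth planting, count
# sampling and dataset round trips.

test_that("genome layout places genes and planted clusters correctly", {
  cfg <- tiny_config()
  layout <- generate_genome_layout(cfg)
  genes <- layout$genes

  expect_equal(nrow(genes), cfg$n_genes)
  expect_true(all(genes$start < genes$end))
  # non-overlapping within each chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # every gene has at least one SNP strictly inside its interval
  snp_per_gene <- table(layout$snps$gene_id)
  expect_true(all(genes$gene_id %in% names(snp_per_gene)))
  j <- match(layout$snps$gene_id, genes$gene_id)
  expect_true(all(layout$snps$pos > genes$start[j] &
                    layout$snps$pos <= genes$end[j]))

  # planted cluster: 13 consecutive genes within a <= 410 kb span on chr2
  cl <- genes[!is.na(genes$cluster_id), ]
  expect_equal(nrow(cl), 13L)
  expect_true(all(cl$chrom == "chr2"))
  expect_lte(max(cl$end) - min(cl$start), 410000)
  on_chr <- genes[genes$chrom == "chr2", ]
  on_chr <- on_chr[order(on_chr$start), ]
  idx <- which(!is.na(on_chr$cluster_id))
  expect_equal(idx, seq(min(idx), max(idx)))  # consecutive among neighbours

  # determinism and the minimal one-gene case
  layout2 <- generate_genome_layout(cfg)
  expect_identical(layout, layout2)
  solo <- generate_genome_layout(sim_config(
    n_genes = 1L, n_chromosomes = 1L, chrom_length = 1e5,
    category_counts = c(ea_maternal_only = 0L), n_de_genes = 0L,
    n_de_strong = 0L, planted_clusters = list(), seed = 1L))
  expect_equal(nrow(solo$genes), 1L)
  expect_gte(nrow(solo$snps), 1L)
})

test_that("impossible cluster requests fail with the cluster named", {
  cfg <- tiny_config()
  bad <- sim_config(
    n_genes = 50L, n_chromosomes = 2L, chrom_length = 1e6,
    category_counts = c(ea_maternal_only = 30L),
    planted_clusters = list(list(name = "too_big", chrom = "chr1",
                                 start = 9e5, span = 4e5, n_genes = 30L,
                                 category = "ea_maternal_only")),
    n_de_genes = 0L, n_de_strong = 0L, qtl_layout = cfg$qtl_layout,
    seed = 1L)
  expect_error(generate_genome_layout(bad), "too_big")
})

test_that("planted truth maps categories to family fractions exactly", {
  cfg <- tiny_config()
  layout <- generate_genome_layout(cfg)
  truth <- plant_bias_truth(layout, cfg)

  # exactly the requested count per category
  tab <- table(truth$true_category)
  for (cat in names(cfg$category_counts)) {
    expect_equal(unname(tab[cat]), unname(cfg$category_counts[cat]),
                 label = cat)
  }
  expect_equal(unname(tab["unbiased"]),
               cfg$n_genes - sum(cfg$category_counts))

  # category -> (mu_EA, mu_AE): spot examples at mu1 = 0.9
  mu_of <- function(cat) {
    r <- truth[truth$true_category == cat & is.na(truth$cluster_id), ][1, ]
    c(r$true_mu_EA, r$true_mu_AE)
  }
  expect_equal(mu_of("ea_maternal_only"), c(0.9, 0.5))
  expect_equal(mu_of("european_allele"), c(0.9, 0.1))
  expect_equal(mu_of("unbiased"), c(0.5, 0.5))

  # noise-free inversion: the planted fractions classify back to the
  # planted category for every gene
  state_of <- function(mu) ifelse(mu >= 0.6, "M", ifelse(mu <= 0.4, "P", "N"))
  back <- classify_gene(state_of(truth$true_mu_EA), state_of(truth$true_mu_AE))
  expect_identical(back, truth$true_category)

  # cluster genes forced to the cluster category at the cluster fraction
  cl <- truth[!is.na(truth$cluster_id), ]
  expect_true(all(cl$true_category == "ea_maternal_only"))
  expect_true(all(cl$true_mu_EA == cfg$cluster_bias_strength))
})

test_that("beta-binomial sampler has the target moments", {
  set.seed(11)
  n_draw <- 10000L
  size <- 60L
  # rho = 0 reduces to binomial: mean and variance
  x0 <- rbetabinom(n_draw, size, 0.3, 0)
  expect_lt(abs(mean(x0) - size * 0.3), 0.15)
  expect_lt(abs(stats::var(x0) - size * 0.3 * 0.7), 0.7)
  # rho > 0: mean still mu, variance inflated by 1 + (n-1) rho
  rho <- 0.1
  x1 <- rbetabinom(n_draw, size, 0.3, rho)
  expect_lt(abs(mean(x1) / size - 0.3), 0.01)
  vexp <- size * 0.3 * 0.7 * (1 + (size - 1) * rho)
  expect_lt(abs(stats::var(x1) - vexp) / vexp, 0.1)
  # implied ICC recovers rho
  icc <- (stats::var(x1) / (size * 0.3 * 0.7) - 1) / (size - 1)
  expect_lt(abs(icc - rho), 0.02)
})

test_that("simulated allele counts follow the planted fractions", {
  # deep unbiased gene: aggregated maternal fraction within 0.5 +/- 0.002
  cfg <- sim_config(
    n_genes = 1L, n_chromosomes = 1L, chrom_length = 1e5,
    snps_per_gene = c(2L, 2L), library_design = c(larva = 2L),
    depth_mean = 250000, depth_dispersion = 0, allelic_icc = 0,
    category_counts = c(ea_maternal_only = 0L), planted_clusters = list(),
    n_de_genes = 0L, n_de_strong = 0L, seed = 7L)
  ds <- simulate_cross_dataset(cfg)
  ea <- ds$counts[ds$counts$family == "EA", ]
  frac <- sum(ea$count_E) / sum(ea$count_E + ea$count_A)
  expect_lt(abs(frac - 0.5), 0.002)

  # zero depth: all counts zero but the table is still well-formed
  cfg0 <- tiny_config(depth_mean = 0)
  ds0 <- simulate_allele_counts(plant_bias_truth(generate_genome_layout(cfg0), cfg0),
                                generate_genome_layout(cfg0), cfg0)
  expect_true(all(ds0$count_E == 0 & ds0$count_A == 0))
  expect_true(all(c("snp_id", "family", "library_id") %in% names(ds0)))

  # maternal-lineage mapping: a strongly European-allele gene has high
  # count_E in both families
  cfg_e <- tiny_config(allelic_icc = 0, depth_mean = 500)
  ds_e <- simulate_cross_dataset(cfg_e)
  eur <- ds_e$truth$gene_id[ds_e$truth$true_category == "european_allele"]
  sub <- ds_e$counts[ds_e$counts$gene_id %in% eur, ]
  for (fam in c("EA", "AE")) {
    s <- sub[sub$family == fam, ]
    expect_gt(sum(s$count_E) / sum(s$count_E + s$count_A), 0.85)
  }
})

test_that("expression counts carry the planted differential expression", {
  cfg <- tiny_config(expr_dispersion = 0, depth_mean = 100, seed = 99)
  ds <- simulate_cross_dataset(cfg)
  expr <- ds$expression
  truth <- ds$truth

  # truth table has exactly the planted DE composition
  expect_equal(sum(truth$is_de), 20L)
  expect_equal(sum(abs(truth$true_log2fc) > 1), 12L)

  # non-DE genes: EA/AE mean ratio ~ 1 in aggregate
  nd <- truth$gene_id[!truth$is_de]
  e <- expr[expr$gene_id %in% nd, ]
  r <- sum(e$count[e$family == "EA"]) / sum(e$count[e$family == "AE"])
  expect_lt(abs(log2(r)), 0.15)

  # expr_dispersion = 0 limit: after library-size normalisation the
  # residual dispersion is ~ 0, well below an NB run at phi = 0.1
  resid_phi <- function(disp) {
    cfg_p <- sim_config(
      n_genes = 400L, n_chromosomes = 2L, chrom_length = 6e6,
      library_design = c(brain = 3L), expr_dispersion = disp,
      category_counts = c(ea_maternal_only = 0L), planted_clusters = list(),
      n_de_genes = 0L, n_de_strong = 0L, seed = 17L)
    e <- simulate_expression_counts(
      plant_bias_truth(generate_genome_layout(cfg_p), cfg_p), cfg_p)
    mat <- tapply(e$count, list(e$gene_id, e$library_id), sum)
    eff <- normalize_libsizes(mat)$effective_sizes
    estimate_common_dispersion(mat, e$family[match(colnames(mat), e$library_id)],
                               eff)
  }
  expect_lte(resid_phi(0), 0.02)
  expect_gte(resid_phi(0.1), 0.05)
})

test_that("datasets round-trip through the writers and readers", {
  cfg <- tiny_config(n_genes = 40L, category_counts = c(ea_maternal_only = 5L),
                     planted_clusters = list(), n_de_genes = 5L,
                     n_de_strong = 3L)
  ds <- simulate_cross_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_cross_dataset(dir)

  expect_equal(back$counts, ds$counts)
  expect_equal(back$expression, ds$expression)
  expect_equal(back$genes, ds$layout$genes[, c("gene_id", "chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(back$qtl,
               ds$layout$qtl[, c("qtl_id", "chrom", "start", "end", "trait_class")],
               ignore_attr = TRUE)

  # one row per SNP per (2 families x sum(library_design)) libraries
  per_snp <- table(ds$counts$snp_id)
  expect_true(all(per_snp == 2 * sum(cfg$library_design)))

  # byte-identical re-write (generator determinism through files)
  dir2 <- withr::local_tempdir()
  write_dataset(simulate_cross_dataset(cfg), dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
  }

  # zero genes: headers-only files that still read back
  empty <- simulate_cross_dataset(sim_config(
    n_genes = 0L, category_counts = c(ea_maternal_only = 0L),
    planted_clusters = list(), n_de_genes = 0L, n_de_strong = 0L, seed = 3L))
  dir0 <- withr::local_tempdir()
  write_dataset(empty, dir0)
  back0 <- read_cross_dataset(dir0)
  expect_equal(nrow(back0$counts), 0L)
  expect_equal(nrow(back0$expression), 0L)
  expect_equal(nrow(back0$genes), 0L)
})
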