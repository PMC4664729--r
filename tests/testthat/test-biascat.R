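# Nine-way bias classification, consolidation and cutoff robustness.

test_that("family state gates on FDR and magnitude jointly", {
  expect_equal(family_state(0.75, 0.01), "M")
  expect_equal(family_state(0.75, 0.20), "N")   # FDR gate fails
  expect_equal(family_state(0.55, 0.001), "N")  # magnitude gate fails
  expect_equal(family_state(0.60, 0.01), "M")   # cutoff is inclusive
  expect_equal(family_state(0.40, 0.01), "P")
  expect_equal(family_state(0.25, 0.01), "P")
  expect_true(is.na(family_state(NA, 0.01)))
  expect_error(family_state(0.7, 0.01, tau = 0.5), "tau")
})

test_that("the state pair maps bijectively onto the nine categories", {
  pairs <- expand.grid(ea = c("M", "P", "N"), ae = c("M", "P", "N"),
                       stringsAsFactors = FALSE)
  got <- classify_gene(pairs$ea, pairs$ae)
  expect_setequal(got, c("maternal_both", "paternal_both",
                         "ea_maternal_only", "ae_maternal_only",
                         "ea_paternal_only", "ae_paternal_only",
                         "european_allele", "africanized_allele", "unbiased"))
  expect_equal(classify_gene("M", "M"), "maternal_both")
  expect_equal(classify_gene("M", "N"), "ea_maternal_only")
  expect_equal(classify_gene("M", "P"), "european_allele")
  expect_equal(classify_gene("P", "M"), "africanized_allele")
  expect_equal(classify_gene("N", "N"), "unbiased")
  expect_true(is.na(classify_gene("M", NA)))
})

test_that("consolidation lets one confident call dominate unbiased calls", {
  expect_equal(reconcile_samples(c("ea_maternal_only", "ea_maternal_only")),
               "ea_maternal_only")
  expect_equal(reconcile_samples(c("ea_maternal_only", "unbiased")),
               "ea_maternal_only")
  expect_equal(reconcile_samples(c("maternal_both", "ea_maternal_only")),
               "MULTI")
  expect_equal(reconcile_samples(c("unbiased", "unbiased")), "unbiased")
  expect_equal(reconcile_samples(c(NA, "unbiased")), "unbiased")
  expect_true(is.na(reconcile_samples(c(NA_character_, NA_character_))))
})

test_that("classification needs both families and partitions the cohort", {
  psge <- rbind(
    make_psge_rows("g1", "EA", "larva", 0.9, 0.001),
    make_psge_rows("g1", "AE", "larva", 0.5, 0.9),
    make_psge_rows("g1", "EA", "brain", 0.92, 0.002),
    make_psge_rows("g1", "AE", "brain", 0.48, 0.8),
    make_psge_rows("g2", "EA", "larva", 0.95, 0.001),  # AE untestable
    make_psge_rows("g2", "AE", "larva", 0.5, NA, testable = FALSE),
    make_psge_rows("g3", "EA", "larva", 0.7, 0.01),
    make_psge_rows("g3", "AE", "larva", 0.3, 0.01),
    make_psge_rows("g3", "EA", "brain", 0.85, 0.01),
    make_psge_rows("g3", "AE", "brain", 0.86, 0.01)
  )
  cl <- classify_bias(psge, tau = 0.6, fdr_level = 0.05)
  expect_equal(cl$consolidated[cl$gene_id == "g1"], "ea_maternal_only")
  # one family untestable: not classified at all
  expect_true(is.na(cl$consolidated[cl$gene_id == "g2"]))
  expect_equal(cl$n_sample_types_tested[cl$gene_id == "g2"], 0)
  # european in larva, maternal_both in brain: MULTI
  expect_equal(cl$consolidated[cl$gene_id == "g3"], "MULTI")
  # partition: category counts sum to the classified cohort size
  counts <- table(cl$consolidated[!is.na(cl$consolidated)])
  expect_equal(sum(counts), sum(!is.na(cl$consolidated)))
})

test_that("relabeling the families swaps the asymmetric categories", {
  set.seed(9)
  n <- 120
  psge <- rbind(
    make_psge_rows(sprintf("g%03d", 1:n), "EA", "larva",
                   stats::runif(n, 0.05, 0.95), stats::runif(n, 0, 0.2)),
    make_psge_rows(sprintf("g%03d", 1:n), "AE", "larva",
                   stats::runif(n, 0.05, 0.95), stats::runif(n, 0, 0.2))
  )
  cl <- classify_bias(psge)
  swapped <- psge
  swapped$family <- ifelse(psge$family == "EA", "AE", "EA")
  cl_sw <- classify_bias(swapped)
  tab <- function(x) table(factor(x$consolidated,
                                  levels = c("maternal_both", "paternal_both",
                                             "ea_maternal_only", "ae_maternal_only",
                                             "ea_paternal_only", "ae_paternal_only",
                                             "european_allele", "africanized_allele",
                                             "unbiased", "MULTI")))
  a <- tab(cl); b <- tab(cl_sw)
  expect_equal(unname(a["ea_maternal_only"]), unname(b["ae_maternal_only"]))
  expect_equal(unname(a["ae_maternal_only"]), unname(b["ea_maternal_only"]))
  expect_equal(unname(a["ea_paternal_only"]), unname(b["ae_paternal_only"]))
  expect_equal(unname(a["european_allele"]), unname(b["africanized_allele"]))
  expect_equal(unname(a["africanized_allele"]), unname(b["european_allele"]))
  expect_equal(unname(a["maternal_both"]), unname(b["maternal_both"]))
  expect_equal(unname(a["unbiased"]), unname(b["unbiased"]))
})

test_that("cutoff robustness validates input and captures gate crossings", {
  expect_error(cutoff_robustness(make_psge_rows("g", "EA", "larva", 0.7, 0.01),
                                 cutoffs = c(0.4)), "cutoffs")
  psge <- rbind(make_psge_rows("g1", "EA", "larva", 0.65, 1e-6),
                make_psge_rows("g1", "AE", "larva", 0.5, 0.9))
  rob <- cutoff_robustness(psge, cutoffs = c(0.6, 0.7))
  n_of <- function(tau, cat) rob$n_genes[rob$cutoff == tau & rob$category == cat]
  expect_equal(n_of(0.6, "ea_maternal_only"), 1L)
  expect_equal(n_of(0.7, "ea_maternal_only"), 0L)
  expect_equal(n_of(0.7, "unbiased"), 1L)
  # tau = 1 boundary: only an exactly pure gene can be biased
  pure <- rbind(make_psge_rows("g2", "EA", "larva", 1.0, 1e-9),
                make_psge_rows("g2", "AE", "larva", 0.5, 0.9))
  rob2 <- cutoff_robustness(pure, cutoffs = 1.0)
  expect_equal(rob2$n_genes[rob2$category == "ea_maternal_only"], 1L)
})

test_that("strongly planted bias is robust to raising the cutoff", {
  cfg <- tiny_config(n_genes = 400L,
                     category_counts = c(ea_maternal_only = 60L),
                     planted_clusters = list(),
                     n_de_genes = 0L, n_de_strong = 0L, seed = 77L)
  ds <- simulate_cross_dataset(cfg)
  res <- run_psge(ds$counts)
  rob <- cutoff_robustness(res, cutoffs = c(0.6, 0.7))
  n6 <- rob$n_genes[rob$cutoff == 0.6 & rob$category == "ea_maternal_only"]
  n7 <- rob$n_genes[rob$cutoff == 0.7 & rob$category == "ea_maternal_only"]
  # bias planted at 0.9 sits far above both cutoffs: < 5 percent change
  expect_lte(abs(n6 - n7) / n6, 0.05)
  # MULTI can only shrink as the cutoff grows
  m6 <- rob$n_genes[rob$cutoff == 0.6 & rob$category == "MULTI"]
  m7 <- rob$n_genes[rob$cutoff == 0.7 & rob$category == "MULTI"]
  expect_lte(m7, m6)
})

test_that("noise-free synthetic data classifies back to the planted truth", {
  cfg <- sim_config(
    n_genes = 90L, n_chromosomes = 2L, chrom_length = 4e6,
    snps_per_gene = c(2L, 2L), library_design = c(larva = 2L),
    depth_mean = 3000, depth_dispersion = 0, allelic_icc = 0,
    category_counts = c(ea_maternal_only = 10L, ae_maternal_only = 10L,
                        maternal_both = 10L, paternal_both = 10L,
                        european_allele = 10L, africanized_allele = 10L,
                        ea_paternal_only = 10L, ae_paternal_only = 10L),
    planted_clusters = list(), n_de_genes = 0L, n_de_strong = 0L,
    seed = 123L)
  ds <- simulate_cross_dataset(cfg)
  cl <- classify_bias(run_psge(ds$counts))
  merged <- merge(cl[, c("gene_id", "consolidated")],
                  ds$truth[, c("gene_id", "true_category")])
  expect_equal(mean(merged$consolidated == merged$true_category), 1)
})
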