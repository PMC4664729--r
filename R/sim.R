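# Synthetic reciprocal-cross data generator.
#
# Emulates the structure of an allele-specific expression study of two
# reciprocal F1 honeybee hybrid families (EA = European mother x Africanized
# father, AE = the reverse): per-SNP allelic read counts over replicate
# libraries of three sample types, gene-level expression counts, gene and QTL
# intervals, and a truth table recording the planted bias category, allelic
# fractions and differential expression of every gene.

default_planted_clusters <- function() {
  list(
    list(name = "cl_chr3", chrom = "chr3", start = 6.0e6, span = 410000L,
         n_genes = 13L, category = "ea_maternal_only"),
    list(name = "cl_chr12", chrom = "chr12", start = 4.0e6, span = 600000L,
         n_genes = 29L, category = "ea_maternal_only")
  )
}

default_qtl_layout <- function() {
  data.frame(
    qtl_id = c("Sting2", "Iap", "Def1", "Def2", "Def3", "Def4",
               "Rep1", "Rep2", "Rep3", "Rep4",
               "Pln1", "Pln2", "Pln3"),
    chrom = c("chr3", "chr12", "chr1", "chr7", "chr9", "chr14",
              "chr2", "chr6", "chr11", "chr13",
              "chr4", "chr10", "chr16"),
    start = c(5.8e6, 3.8e6, 1.0e6, 2.0e6, 0.5e6, 4.0e6,
              2.0e6, 1.0e6, 5.0e6, 2.0e6,
              3.0e6, 1.0e6, 6.0e6),
    end = c(8.0e6, 5.0e6, 7.0e6, 8.0e6, 6.5e6, 10.0e6,
            8.0e6, 6.0e6, 11.0e6, 6.0e6,
            7.0e6, 4.5e6, 10.0e6),
    trait_class = c(rep("defense", 6), rep("reproduction", 4),
                    rep("foraging", 3)),
    enrich_category = c(rep("ea_maternal_only", 6), rep(NA_character_, 4),
                        rep("european_allele", 3)),
    enrich_odds = c(rep(2.0, 6), rep(1.0, 4), rep(3.0, 3)),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic reciprocal-cross dataset
#'
#' Builds a validated configuration for [simulate_cross_dataset()] and the
#' individual generator stages. Defaults emulate the scale of the motivating
#' study: 2663 testable genes on 16 chromosomes, two reciprocal families each
#' sequenced as 2 larval pools, 2 guard pools and 3 individual brains, with
#' beta-binomial overdispersed allelic counts, planted bias categories
#' (223 EA-maternal-only, 24 AE-maternal-only, 23 + 23 symmetric, plus
#' documented defaults for the lineage and paternal-only classes), two
#' planted maternal clusters (13 genes / 410 kb and 29 genes / 600 kb), QTL
#' intervals with category enrichment odds, and 160 differentially expressed
#' genes of which 101 exceed a twofold change.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in basepairs.
#' @param snps_per_gene Length-2 integer range of diagnostic SNPs per gene.
#' @param library_design Named integer vector, libraries per family for each
#'   sample type.
#' @param depth_mean Mean reads per SNP per library.
#' @param depth_dispersion Negative-binomial dispersion of per-SNP depth.
#' @param allelic_icc Beta-binomial intra-class correlation rho in `[0, 1)`.
#' @param bias_strength True biased-allele fraction mu1 in `(0.5, 1]`.
#' @param cluster_bias_strength Maternal fraction for genes inside planted
#'   clusters (the clusters emulate regions of >90 percent maternal bias).
#' @param category_counts Named integer vector of planted genes per bias
#'   category (excluding `unbiased`, which takes the remainder).
#' @param expr_dispersion Negative-binomial dispersion of expression counts.
#' @param n_de_genes Number of differentially expressed genes.
#' @param n_de_strong How many DE genes exceed the `de_fold_change` fold.
#' @param de_fold_change Fold change separating strong from weak DE genes.
#' @param planted_clusters List of planted clusters, each a list with
#'   `name`, `chrom`, `start`, `span`, `n_genes`, `category`.
#' @param qtl_layout Data frame of QTL intervals (`qtl_id`, `chrom`, `start`,
#'   `end`, `trait_class`, optional `enrich_category`, `enrich_odds`).
#' @param seed Integer seed; every generator stage derives its stream from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2663L,
                       n_chromosomes = 16L,
                       chrom_length = 12e6,
                       snps_per_gene = c(1L, 4L),
                       library_design = c(larva = 2L, guard = 2L, brain = 3L),
                       depth_mean = 100,
                       depth_dispersion = 0.3,
                       allelic_icc = 0.02,
                       bias_strength = 0.9,
                       cluster_bias_strength = 0.95,
                       category_counts = c(
                         ea_maternal_only = 223L,
                         ae_maternal_only = 24L,
                         maternal_both = 23L,
                         paternal_both = 23L,
                         european_allele = 120L,
                         africanized_allele = 30L,
                         ea_paternal_only = 20L,
                         ae_paternal_only = 16L
                       ),
                       expr_dispersion = 0.1,
                       n_de_genes = 160L,
                       n_de_strong = 101L,
                       de_fold_change = 2.0,
                       planted_clusters = default_planted_clusters(),
                       qtl_layout = default_qtl_layout(),
                       seed = 20151201L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, snps_per_gene = as.integer(snps_per_gene),
    library_design = library_design, depth_mean = depth_mean,
    depth_dispersion = depth_dispersion, allelic_icc = allelic_icc,
    bias_strength = bias_strength,
    cluster_bias_strength = cluster_bias_strength,
    category_counts = category_counts, expr_dispersion = expr_dispersion,
    n_de_genes = as.integer(n_de_genes), n_de_strong = as.integer(n_de_strong),
    de_fold_change = de_fold_change, planted_clusters = planted_clusters,
    qtl_layout = qtl_layout, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 0, cfg$n_chromosomes >= 1, cfg$chrom_length > 0,
    length(cfg$snps_per_gene) == 2, cfg$snps_per_gene[1] >= 1,
    cfg$snps_per_gene[2] >= cfg$snps_per_gene[1],
    all(cfg$library_design >= 0), cfg$depth_mean >= 0,
    cfg$depth_dispersion >= 0, cfg$expr_dispersion >= 0,
    cfg$n_de_genes >= 0, cfg$n_de_strong >= 0,
    cfg$n_de_strong <= cfg$n_de_genes, cfg$n_de_genes <= cfg$n_genes,
    cfg$de_fold_change > 1
  )
  if (cfg$allelic_icc < 0 || cfg$allelic_icc >= 1) {
    stop("allelic_icc must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$bias_strength <= 0.5 || cfg$bias_strength > 1) {
    stop("bias_strength must lie in (0.5, 1]", call. = FALSE)
  }
  if (cfg$cluster_bias_strength <= 0.5 || cfg$cluster_bias_strength > 1) {
    stop("cluster_bias_strength must lie in (0.5, 1]", call. = FALSE)
  }
  bad <- setdiff(names(cfg$category_counts), setdiff(BIAS_CATEGORIES, "unbiased"))
  if (length(bad)) {
    stop("unknown bias categories in category_counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$category_counts < 0)) stop("category_counts must be >= 0", call. = FALSE)
  if (sum(cfg$category_counts) > cfg$n_genes) {
    stop("sum of category_counts exceeds n_genes", call. = FALSE)
  }
  for (cl in cfg$planted_clusters) {
    stopifnot(all(c("name", "chrom", "start", "span", "n_genes", "category")
                  %in% names(cl)))
    if (!cl$category %in% BIAS_CATEGORIES) {
      stop("cluster ", cl$name, ": unknown category ", cl$category, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic genome layout
#'
#' Places non-overlapping gene intervals on the configured chromosomes, puts
#' 1-4 diagnostic SNPs inside every gene, lays planted clusters down as
#' consecutive genes within their stated span, and carries the configured QTL
#' intervals through. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cross_layout` with data frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `cluster_id`), `snps`
#'   (`snp_id`, `chrom`, `pos` 1-based, `gene_id`) and `qtl`.
#' @export
generate_genome_layout <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  min_len <- 2000; max_len <- 8000

  cluster_tab <- config$planted_clusters
  for (cl in cluster_tab) {
    if (!cl$chrom %in% chroms ||
        cl$start + cl$span > config$chrom_length ||
        cl$n_genes * (min_len + 100) > cl$span) {
      stop("planted cluster '", cl$name,
           "' exceeds chromosome capacity or span", call. = FALSE)
    }
  }

  n_cluster_genes <- sum(vapply(cluster_tab, `[[`, integer(1), "n_genes"))
  if (n_cluster_genes > config$n_genes) {
    stop("planted clusters request more genes than n_genes", call. = FALSE)
  }
  n_free <- config$n_genes - n_cluster_genes
  # near-even split of free genes across chromosomes
  per_chrom <- rep(n_free %/% config$n_chromosomes, config$n_chromosomes)
  extra <- n_free %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  gene_rows <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    cls <- Filter(function(cl) cl$chrom == chrom, cluster_tab)
    blocked <- do.call(rbind, lapply(cls, function(cl) {
      c(cl$start, cl$start + cl$span)
    }))
    # cluster genes: evenly spaced, consecutive, inside the stated span
    for (cl in cls) {
      spacing <- cl$span / cl$n_genes
      starts <- floor(cl$start + (seq_len(cl$n_genes) - 1) * spacing)
      lens <- pmin(max_len, floor(spacing) - 100L)
      lens <- pmax(min_len, round(stats::runif(cl$n_genes, min_len, lens)))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts, end = starts + lens,
        cluster_id = cl$name, stringsAsFactors = FALSE
      )
    }
    # free genes on the segments left open between clusters
    k <- per_chrom[ci]
    if (k == 0) next
    bounds <- c(0, if (!is.null(blocked)) as.vector(t(blocked)), config$chrom_length)
    segs <- matrix(bounds, ncol = 2, byrow = TRUE)  # open segments
    seg_len <- segs[, 2] - segs[, 1]
    alloc <- round(k * seg_len / sum(seg_len))
    alloc[length(alloc)] <- k - sum(alloc[-length(alloc)])
    for (si in seq_len(nrow(segs))) {
      ks <- alloc[si]
      if (ks <= 0) next
      lens <- round(stats::runif(ks, min_len, max_len))
      if (sum(lens) + ks >= seg_len[si]) {
        stop("chromosome ", chrom, " cannot hold ", ks,
             " genes in a segment of ", seg_len[si], " bp", call. = FALSE)
      }
      slack <- seg_len[si] - sum(lens)
      u <- stats::runif(ks + 1)
      gaps <- floor(slack * u / sum(u))
      starts <- segs[si, 1] + cumsum(gaps[seq_len(ks)]) +
        cumsum(c(0, lens[-ks]))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        chrom = chrom, start = starts, end = starts + lens,
        cluster_id = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes)) {
    genes <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), cluster_id = character())
  }
  ord <- order(match(genes$chrom, chroms), genes$start)
  genes <- genes[ord, , drop = FALSE]
  genes$gene_id <- sprintf("GB%05d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end", "cluster_id")]
  rownames(genes) <- NULL

  # diagnostic SNPs: 1-based positions inside each gene's half-open interval
  n_snps <- if (nrow(genes)) {
    sample(config$snps_per_gene[1]:config$snps_per_gene[2],
           nrow(genes), replace = TRUE)
  } else integer(0)
  snp_gene <- rep(seq_len(nrow(genes)), n_snps)
  offs <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    len <- genes$end[i] - genes$start[i]
    sort(sample.int(len, n_snps[i]))
  }))
  snps <- data.frame(
    snp_id = sprintf("snp%06d", seq_along(snp_gene)),
    chrom = genes$chrom[snp_gene],
    pos = genes$start[snp_gene] + offs,  # 1-based: start is 0-based
    gene_id = genes$gene_id[snp_gene],
    stringsAsFactors = FALSE
  )

  qtl <- config$qtl_layout
  structure(list(genes = genes, snps = snps, qtl = qtl),
            class = "cross_layout")
}

# (mu_EA, mu_AE) maternal fractions implied by each category; exact inverse
# of classify_gene() in the noise-free limit.
category_mu <- function(category, mu1) {
  switch(category,
    maternal_both      = c(mu1, mu1),
    paternal_both      = c(1 - mu1, 1 - mu1),
    ea_maternal_only   = c(mu1, 0.5),
    ae_maternal_only   = c(0.5, mu1),
    ea_paternal_only   = c(1 - mu1, 0.5),
    ae_paternal_only   = c(0.5, 1 - mu1),
    european_allele    = c(mu1, 1 - mu1),
    africanized_allele = c(1 - mu1, mu1),
    unbiased           = c(0.5, 0.5),
    stop("unknown category: ", category)
  )
}

#' Plant the per-gene truth of a synthetic dataset
#'
#' Assigns every gene a bias category (cluster genes are forced to their
#' cluster's category; the remaining planted counts are drawn with sampling
#' weights respecting the QTL enrichment odds in expectation), the implied
#' maternal fractions in both families, and the differential-expression truth.
#'
#' @param layout A `cross_layout` from [generate_genome_layout()].
#' @param config The [sim_config()] used to build the layout.
#' @return A data frame of class `cross_truth`: `gene_id`, `true_category`,
#'   `true_mu_EA`, `true_mu_AE`, `is_de`, `true_log2fc`, `de_sample_type`,
#'   `cluster_id`.
#' @export
plant_bias_truth <- function(layout, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genes <- layout$genes
  n <- nrow(genes)
  category <- rep("unbiased", n)
  mu1 <- config$bias_strength

  in_cluster <- !is.na(genes$cluster_id)
  for (cl in config$planted_clusters) {
    category[genes$cluster_id %in% cl$name] <- cl$category
  }

  counts <- config$category_counts
  # cluster-forced genes count toward their category's planted total
  for (cat in names(counts)) {
    counts[cat] <- counts[cat] - sum(category == cat & in_cluster)
  }
  if (any(counts < 0)) {
    stop("cluster genes exceed the planted count of their category", call. = FALSE)
  }

  # QTL enrichment odds: per-category sampling weights over free genes
  qtl <- config$qtl_layout
  weight_for <- function(cat) {
    w <- rep(1, n)
    rows <- which(!is.na(qtl$enrich_category) & qtl$enrich_category == cat &
                    qtl$enrich_odds != 1)
    for (r in rows) {
      hit <- genes$chrom == qtl$chrom[r] &
        genes$start < qtl$end[r] & qtl$start[r] < genes$end
      w[hit] <- pmax(w[hit], qtl$enrich_odds[r])
    }
    w
  }
  free <- which(!in_cluster)
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k == 0) next
    w <- weight_for(cat)[free]
    pick <- free[sample.int(length(free), k, prob = w)]
    category[pick] <- cat
    free <- setdiff(free, pick)
  }

  mus <- vapply(seq_len(n), function(i) {
    m <- if (in_cluster[i]) config$cluster_bias_strength else mu1
    category_mu(category[i], m)
  }, numeric(2))

  # differential expression truth
  is_de <- rep(FALSE, n)
  lfc <- rep(0, n)
  de_st <- rep(NA_character_, n)
  if (config$n_de_genes > 0) {
    de_idx <- sample.int(n, config$n_de_genes)
    is_de[de_idx] <- TRUE
    thr <- log2(config$de_fold_change)
    n_strong <- config$n_de_strong
    mag <- c(stats::runif(n_strong, thr * 1.1, thr * 2),
             stats::runif(config$n_de_genes - n_strong, thr * 0.4, thr * 0.9))
    lfc[de_idx] <- mag * sample(c(-1, 1), config$n_de_genes, replace = TRUE)
    de_st[de_idx] <- sample(names(config$library_design),
                            config$n_de_genes, replace = TRUE)
  }

  truth <- data.frame(
    gene_id = genes$gene_id,
    true_category = category,
    true_mu_EA = mus[1, ],
    true_mu_AE = mus[2, ],
    is_de = is_de,
    true_log2fc = lfc,
    de_sample_type = de_st,
    cluster_id = genes$cluster_id,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("cross_truth", "data.frame")
  truth
}

#' Beta-binomial random draws
#'
#' One draw per element of `size`; `rho = 0` short-circuits to binomial
#' sampling. This is the sampler behind [simulate_allele_counts()].
#'
#' @param n_draws Number of draws.
#' @param size Number of trials (recycled).
#' @param mu Mean success fraction.
#' @param rho Intra-class correlation in `[0, 1)`.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n_draws, size, mu, rho) {
  if (rho == 0) return(stats::rbinom(n_draws, size, mu))
  theta <- (1 - rho) / rho
  p <- stats::rbeta(n_draws, mu * theta, (1 - mu) * theta)
  # degenerate mu = 0/1 gives NaN from rbeta
  p[mu == 0] <- 0; p[mu == 1] <- 1
  stats::rbinom(n_draws, size, p)
}

library_ids <- function(design) {
  unlist(lapply(FAMILIES, function(fam) {
    unlist(lapply(names(design), function(st) {
      if (design[[st]] == 0) return(character(0))
      sprintf("%s_%s_%d", fam, st, seq_len(design[[st]]))
    }))
  }), use.names = FALSE)
}

#' Simulate per-SNP allelic read counts
#'
#' For every SNP x library, draws the total depth from a negative binomial
#' and the maternal read count from a beta-binomial with the gene's planted
#' maternal fraction and the configured intra-class correlation, then reports
#' counts on the European/Africanized lineage scale via the family's
#' maternal-lineage mapping (EA: maternal = European allele; AE: maternal =
#' Africanized allele).
#'
#' @param truth A `cross_truth` table.
#' @param layout The matching `cross_layout`.
#' @param config The [sim_config()].
#' @return Data frame with columns `snp_id`, `chrom`, `pos`, `gene_id`,
#'   `family`, `sample_type`, `library_id`, `count_E`, `count_A`.
#' @export
simulate_allele_counts <- function(truth, layout, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  snps <- layout$snps
  design <- config$library_design
  libs <- expand.grid(
    lib = seq_len(max(1, max(design))), sample_type = names(design),
    family = FAMILIES, stringsAsFactors = FALSE
  )
  libs <- libs[libs$lib <= design[libs$sample_type], , drop = FALSE]
  libs$library_id <- sprintf("%s_%s_%d", libs$family, libs$sample_type, libs$lib)

  idx_snp <- rep(seq_len(nrow(snps)), times = nrow(libs))
  idx_lib <- rep(seq_len(nrow(libs)), each = nrow(snps))
  fam <- libs$family[idx_lib]
  gene_row <- match(snps$gene_id[idx_snp], truth$gene_id)
  mu <- ifelse(fam == "EA", truth$true_mu_EA[gene_row], truth$true_mu_AE[gene_row])

  n_obs <- length(idx_snp)
  depth <- if (config$depth_mean == 0) {
    integer(n_obs)
  } else if (config$depth_dispersion == 0) {
    stats::rpois(n_obs, config$depth_mean)
  } else {
    stats::rnbinom(n_obs, mu = config$depth_mean,
                   size = 1 / config$depth_dispersion)
  }
  rho <- config$allelic_icc
  maternal <- if (rho == 0) {
    stats::rbinom(n_obs, depth, mu)
  } else {
    theta <- (1 - rho) / rho
    p <- stats::rbeta(n_obs, mu * theta, (1 - mu) * theta)
    p[mu == 0] <- 0; p[mu == 1] <- 1
    stats::rbinom(n_obs, depth, p)
  }
  count_E <- ifelse(fam == "EA", maternal, depth - maternal)
  count_A <- depth - count_E

  data.frame(
    snp_id = snps$snp_id[idx_snp],
    chrom = snps$chrom[idx_snp],
    pos = snps$pos[idx_snp],
    gene_id = snps$gene_id[idx_snp],
    family = fam,
    sample_type = libs$sample_type[idx_lib],
    library_id = libs$library_id[idx_lib],
    count_E = as.integer(count_E),
    count_A = as.integer(count_A),
    stringsAsFactors = FALSE
  )
}

#' Simulate gene-level expression counts
#'
#' Draws negative-binomial expression counts per gene x library around a
#' log-normal baseline mean, with library-specific scale factors within a
#' twofold range of each other and the planted fold change applied between
#' families in each DE gene's affected sample type.
#'
#' @param truth A `cross_truth` table.
#' @param config The [sim_config()].
#' @return Long data frame: `gene_id`, `family`, `sample_type`, `library_id`,
#'   `count`.
#' @export
simulate_expression_counts <- function(truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  design <- config$library_design
  lib_ids <- library_ids(design)
  if (!length(lib_ids) || !nrow(truth)) {
    return(data.frame(gene_id = character(), family = character(),
                      sample_type = character(), library_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lib_ids, "_"))
  lib_fam <- parts[, 1]; lib_st <- parts[, 2]
  sf <- stats::runif(length(lib_ids), 0.8, 1.5)

  base <- stats::rlnorm(nrow(truth), meanlog = log(150), sdlog = 1)
  n_lib <- length(lib_ids)
  g_idx <- rep(seq_len(nrow(truth)), times = n_lib)
  l_idx <- rep(seq_len(n_lib), each = nrow(truth))

  half <- truth$true_log2fc[g_idx] / 2
  affected <- truth$is_de[g_idx] &
    truth$de_sample_type[g_idx] == lib_st[l_idx]
  shift <- ifelse(affected, ifelse(lib_fam[l_idx] == "EA", half, -half), 0)
  mu <- base[g_idx] * sf[l_idx] * 2^shift
  count <- if (config$expr_dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$expr_dispersion)
  }
  data.frame(
    gene_id = truth$gene_id[g_idx],
    family = lib_fam[l_idx],
    sample_type = lib_st[l_idx],
    library_id = lib_ids[l_idx],
    count = as.integer(count),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete reciprocal-cross dataset
#'
#' Convenience wrapper running [generate_genome_layout()],
#' [plant_bias_truth()], [simulate_allele_counts()] and
#' [simulate_expression_counts()] in order.
#'
#' @param config A [sim_config()].
#' @return List of class `cross_dataset` with `layout`, `truth`, `counts`
#'   and `expression`.
#' @export
simulate_cross_dataset <- function(config = sim_config()) {
  layout <- generate_genome_layout(config)
  truth <- plant_bias_truth(layout, config)
  counts <- simulate_allele_counts(truth, layout, config)
  expression <- simulate_expression_counts(truth, config)
  structure(list(layout = layout, truth = truth, counts = counts,
                 expression = expression, config = config),
            class = "cross_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes `allele_counts.tsv`, `expression_counts.tsv`, `genes.bed`,
#' `qtl.bed` and `truth.tsv` into a directory, in the formats consumed by
#' the package readers (the BED files are 0-based half-open; the counts
#' table carries 1-based SNP positions).
#'
#' @param dataset A `cross_dataset` from [simulate_cross_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(
    counts = file.path(dir, "allele_counts.tsv"),
    expression = file.path(dir, "expression_counts.tsv"),
    genes = file.path(dir, "genes.bed"),
    qtl = file.path(dir, "qtl.bed"),
    truth = file.path(dir, "truth.tsv")
  )
  write_allele_counts(dataset$counts, paths["counts"])
  write_expression_counts(dataset$expression, paths["expression"])
  write_gene_bed(dataset$layout$genes, paths["genes"])
  write_qtl_bed(dataset$layout$qtl, paths["qtl"])
  utils::write.table(as.data.frame(dataset$truth), paths["truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
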