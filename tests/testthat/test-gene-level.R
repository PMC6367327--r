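test_that("SNV rates are per-kilobase", {
  expect_equal(snv_rate(30, 1000), 30)
  expect_equal(snv_rate(0, 1000), 0)
  expect_equal(snv_rate(45, 1500), 30)
  expect_error(snv_rate(3, 0))
})

test_that("susceptibility classes use strict thresholds", {
  expect_equal(classify_susceptibility(40, 0, 100, 10), "disease_sensitive")
  expect_equal(classify_susceptibility(0, 0, 0, 60), "disease_tolerant")
  expect_equal(classify_susceptibility(0, 0, 0, 50), "other")   # strict > 50
  expect_equal(classify_susceptibility(30, 0, 100, 10), "other") # strict > 30%
  expect_equal(classify_susceptibility(0, 1, 0, 80), "other")    # DM blocks tolerant
  expect_equal(classify_susceptibility(0, 0, 0, 0), "other")     # zero denominator
  # vectorized
  expect_equal(classify_susceptibility(c(40, 0), c(0, 0), c(100, 0), c(10, 60)),
               c("disease_sensitive", "disease_tolerant"))
})

test_that("expression maximum and specificity follow the information content", {
  expect_equal(expression_max(c(1, 5, 3)), 5)
  expect_equal(expression_max(c(0, 0)), 0)
  expect_equal(expression_max(7), 7)
  expect_equal(tissue_specificity(rep(1, 53)), 0, tolerance = 1e-12)
  expect_equal(tissue_specificity(c(7, rep(0, 52))), log2(53), tolerance = 1e-12)
  expect_equal(tissue_specificity(c(0.5, 0.5, 0, 0)), 1, tolerance = 1e-12)
  expect_true(is.na(tissue_specificity(rep(0, 5))))
  # bounds: always within [0, log2 n]
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:60, 1)
    v <- rgamma(n, runif(1, 0.2, 3))
    ts <- tissue_specificity(v)
    expect_gte(ts, -1e-12)
    expect_lte(ts, log2(n) + 1e-12)
  }
})

test_that("degree rank fractions preserve order with mean-rank ties", {
  expect_equal(ranked_degree(c(1, 2, 3)), c(1, 2, 3) / 3)
  n <- 7
  expect_equal(ranked_degree(rep(4, n)), rep((n + 1) / (2 * n), n))
  d <- c(5, 1, NA, 9)
  r <- ranked_degree(d)
  expect_true(is.na(r[3]))
  expect_equal(which.max(r), 4L)
  expect_equal(max(r, na.rm = TRUE), 1)
  # order preservation
  set.seed(10)
  dd <- sample(0:20, 30, TRUE)
  rr <- ranked_degree(dd)
  expect_true(all(diff(rr[order(dd)]) >= -1e-12))
})

test_that("pathogenic-count gene groups are nested with strict boundaries", {
  m <- group_by_pathogenic_count(c(21, 20, 0, 1))
  expect_equal(m[, "gt_0"], c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(m[, "gt_20"], c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(m[, "gt_20"] <= m[, "gt_0"]))
})

test_that("gene summaries count unique sites and join the gene-level inputs", {
  variants <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 10L, 20L, 30L, 40L),
    ref = c("A", "A", "C", "G", "T"), alt = c("G", "T", "T", "A", "C"),
    gene = c("G1", "G1", "G1", "G2", "G2"),
    clinvar = c("Pathogenic", "Pathogenic", "Benign", "Pathogenic", NA),
    hgmd_class = c("DM", "none", "none", "none", "none"))
  v <- annotate_site_groups(variants)
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      exon_length_bp = c(1000L, 2000L, 500L),
                      n_polymorphic = c(30L, 10L, 60L))
  expr <- data.frame(gene = c("G1", "G2", "G3"),
                     t1 = c(1, 8, 2), t2 = c(1, 0, 2), t3 = c(1, 0, 2))
  deg <- data.frame(gene = c("G1", "G2", "G3"), degree = c(3L, 9L, 3L))
  gs <- summarize_genes(v, genes, expr, deg)
  gs <- gs[match(c("G1", "G2", "G3"), gs$gene), ]
  # chr1:10 is one pathogenic site despite two alleles
  expect_equal(gs$n_pathogenic_sites, c(1L, 1L, 0L))
  expect_equal(gs$n_annotated_sites, c(2L, 2L, 0L))
  expect_equal(gs$n_dm_sites, c(1L, 0L, 0L))
  expect_equal(gs$snv_rate_kb, c(30, 5, 120))
  # 1 pathogenic of 2 annotated sites = 50% > 30% for G1 and G2
  expect_equal(gs$susceptibility,
               c("disease_sensitive", "disease_sensitive", "disease_tolerant"))
  expect_equal(gs$expression_max, c(1, 8, 2))
  expect_equal(gs$tissue_specificity, c(0, log2(3), 0), tolerance = 1e-12)
  expect_equal(gs$degree_rank, c(0.5, 1, 0.5))
})

test_that("gene-group ECDF comparisons report every configured contrast", {
  cohort <- small_cohort(seed = 3)
  v <- annotate_site_groups(cohort$variants)
  gs <- summarize_genes(v, cohort$genes, cohort$expression, cohort$degrees)
  comp <- gene_group_comparison(gs)
  expect_equal(nrow(comp), 2 * 2 * 3)  # arms x cuts x metrics
  expect_true(all(!is.na(comp$d) | comp$n_group == 0))
  olc <- occurrence_length_correlation(gs)
  expect_gt(olc$estimate, 0)  # longer exons accumulate more polymorphic sites
})
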