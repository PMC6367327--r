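# In-code fixtures shared across test files.

# A minimal, hand-checkable variant table (data.table) with scores for a
# subset of tools. `n` rows are cycled from the template.
toy_variant_table <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 100L, 5000L),
    ref = c("A", "A", "G"),
    alt = c("G", "T", "C"),
    gene = c("GENE1", "GENE1", "GENE2"),
    hgvs = c("c.12A>G", "c.12A>T", "c.90G>C"),
    clinvar = c("Pathogenic", "Benign", NA_character_),
    hgmd_class = c("DM", "none", "none"),
    ancestral_allele = c("G", "A", "G"),
    ancestral_confidence = c("high", "high", "high"),
    nondegenerate = c(TRUE, TRUE, FALSE),
    phastcons_vertebrate = c(0.95, 0.95, 0.1),
    phastcons_mammal = c(0.9, 0.9, 0.2),
    phastcons_primate = c(0.8, 0.8, 0.3),
    phylop_vertebrate = c(2.5, 2.5, -0.5),
    phylop_mammal = c(2.0, 2.0, -0.2),
    phylop_primate = c(1.0, 1.0, 0.1),
    rank_SIFT = c(0.9, 0.2, 0.4),
    rank_CADD = c(0.8, 0.3, NA_real_),
    rank_DANN = c(0.7, 0.6, 0.2))
}

# Deterministic small cohort for pipeline-level tests.
small_cohort <- function(seed = 11, n_genes = 60, ...) {
  generate_cohort(cohort_config(seed = seed, n_genes = n_genes,
                                n_epigenomes = 15, ...))
}

# Truth labels (pathogenic/benign or NA) from an annotated variant table.
truth_labels <- function(variants) {
  ifelse(variants$site_group %in% c("pathogenic", "benign"),
         variants$site_group, NA_character_)
}

# Independent brute-force Pearson chi-squared on a 2x2 from the textbook
# contingency formula (oracle; no library call).
oracle_chi2_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  exp <- outer(rs, cs) / n
  chi2 <- sum((tab - exp)^2 / exp)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Independent brute-force two-sided rank-sum p by full enumeration of
# group assignments (oracle; handles ties).
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  centre <- nx * length(y) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  u_all <- apply(idx, 2, function(ii) sum(r[ii])) - nx * (nx + 1) / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# Independent brute-force two-sample KS: statistic by direct ECDF scan,
# p by full enumeration of group assignments (valid without ties).
oracle_ks <- function(x, y) {
  d_stat <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
  }
  d_obs <- d_stat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  d_all <- apply(idx, 2, function(ii) d_stat(pooled[ii], pooled[-ii]))
  list(d = d_obs, p = mean(d_all >= d_obs - 1e-9))
}
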