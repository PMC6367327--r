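# Gene-level characterization: SNV occurrence rates, disease-susceptibility
# classes, expression abundance and tissue specificity, ranked PPI degree,
# and ECDF group comparisons.

#' SNV occurrence rate per kilobase
#'
#' @param n_polymorphic Number of polymorphic sites detected in the gene's
#'   exons.
#' @param exon_length_bp Total exon length in base pairs (>= 1).
#' @return Rate in sites per Kb: `1000 * n_polymorphic / exon_length_bp`.
#' @export
#' @examples
#' snv_rate(30, 1000)   # 30 sites/Kb
snv_rate <- function(n_polymorphic, exon_length_bp) {
  stopifnot(all(exon_length_bp >= 1))
  1000 * n_polymorphic / exon_length_bp
}

#' Disease-susceptibility class of a gene
#'
#' *Disease-sensitive* genes carry a high proportion (> `sens_prop`,
#' default 30%) of pathogenic variations among their annotated variant
#' sites; *disease-tolerant* genes have no pathogenic annotation (neither a
#' clinically pathogenic site nor an HGMD DM site) despite more than
#' `tol_min_poly` (default 50) polymorphic sites; everything else is
#' `"other"`. Genes whose proportion denominator is zero are `"other"`.
#'
#' @param n_pathogenic_sites Clinically pathogenic site count per gene.
#' @param n_dm_sites HGMD DM site count per gene.
#' @param n_annotated_sites Denominator of the pathogenic proportion:
#'   annotated variant sites in the gene (clinical + HGMD union).
#' @param n_polymorphic Polymorphic site count per gene.
#' @param sens_prop Proportion threshold (strict), default 0.30.
#' @param tol_min_poly Polymorphic-site threshold (strict), default 50.
#' @return Character vector: `"disease_sensitive"`, `"disease_tolerant"` or
#'   `"other"`.
#' @export
#' @examples
#' classify_susceptibility(40, 0, 100, 10)   # > 30% pathogenic
#' classify_susceptibility(0, 0, 0, 60)      # tolerant
classify_susceptibility <- function(n_pathogenic_sites, n_dm_sites,
                                    n_annotated_sites, n_polymorphic,
                                    sens_prop = 0.30, tol_min_poly = 50L) {
  prop <- ifelse(n_annotated_sites > 0,
                 n_pathogenic_sites / n_annotated_sites, NA_real_)
  ifelse(!is.na(prop) & prop > sens_prop, "disease_sensitive",
         ifelse(n_pathogenic_sites == 0 & n_dm_sites == 0 &
                  n_polymorphic > tol_min_poly, "disease_tolerant", "other"))
}

#' Maximum expression abundance of a profile
#'
#' The maximum abundance over tissues measures a gene's expression level
#' while avoiding averaging across biologically distinct conditions.
#'
#' @param values Numeric vector of non-negative abundances over tissues.
#' @return The maximum abundance; `NA` if all values are missing.
#' @export
expression_max <- function(values) {
  if (all(is.na(values))) return(NA_real_)
  max(values, na.rm = TRUE)
}

#' Tissue specificity as information content
#'
#' The information content of an expression profile over n tissues:
#' `log2(n) + sum(p_i * log2(p_i))` with `p_i` the fraction of total
#' abundance in tissue i and `p * log2(p) := 0` at `p = 0`. The score spans
#' \[0, log2 n\]: 0 for a perfectly uniform profile, log2 n for expression
#' confined to a single tissue.
#'
#' @param values Numeric vector of non-negative abundances over tissues.
#' @return Specificity in \[0, log2 n\]; `NA` when total abundance is 0.
#' @export
#' @examples
#' tissue_specificity(rep(1, 53))                 # 0
#' tissue_specificity(c(7, rep(0, 52)))           # log2(53)
tissue_specificity <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) return(NA_real_)
  if (any(values < 0)) stop("expression abundances must be non-negative")
  total <- sum(values)
  if (total == 0) return(NA_real_)
  p <- values / total
  plogp <- ifelse(p > 0, p * log2(p), 0)
  log2(n) + sum(plogp)
}

#' Rank fraction of PPI degrees
#'
#' Ranks genes by protein-protein interaction degree (ascending, mean ranks
#' for ties) and divides by the number of ranked genes, giving a rank
#' fraction in (0, 1\] with the maximum-degree gene at 1. Genes with a
#' missing degree get a missing rank.
#'
#' @param degrees Numeric vector of node degrees (NA allowed).
#' @return Numeric vector of rank fractions.
#' @export
#' @examples
#' ranked_degree(c(1, 2, 3))   # 1/3, 2/3, 1
ranked_degree <- function(degrees) {
  out <- rep(NA_real_, length(degrees))
  ok <- !is.na(degrees)
  if (!any(ok)) return(out)
  out[ok] <- rank(degrees[ok], ties.method = "average") / sum(ok)
  out
}

#' Gene groups by pathogenic-site count
#'
#' Membership of each gene in the nested groups defined by strict
#' comparisons on its pathogenic-site count — by default "at least one
#' pathogenic site" (n > 0) and "more than 20 pathogenic sites" (n > 20).
#'
#' @param n_sites Integer vector of pathogenic (or DM) site counts.
#' @param cuts Numeric thresholds (strict `>`), default `c(0, 20)`.
#' @return Logical matrix with one column per cut, named `gt_<cut>`.
#' @export
group_by_pathogenic_count <- function(n_sites, cuts = c(0, 20)) {
  m <- vapply(cuts, function(cut) n_sites > cut, logical(length(n_sites)))
  m <- matrix(m, nrow = length(n_sites),
              dimnames = list(NULL, paste0("gt_", cuts)))
  m
}

#' Build per-gene summaries from the variant table and gene-level inputs
#'
#' Aggregates a site-classified variant table to genes and joins the
#' gene-level inputs: exon length and polymorphic-site counts from the gene
#' metadata table, expression profiles (genes x tissues) and PPI degrees.
#' Derived columns: pathogenic / DM / annotated site counts, SNV occurrence
#' rate per Kb, disease-susceptibility class, maximum expression, tissue
#' specificity and degree rank fraction.
#'
#' @param variants Variant table annotated with `site_group` and `is_dm`
#'   (see [annotate_site_groups()]).
#' @param genes Gene metadata `data.frame`: columns `gene`,
#'   `exon_length_bp`, `n_polymorphic`.
#' @param expression Expression matrix `data.frame`: column `gene` plus one
#'   numeric column per tissue.
#' @param degrees Degree table `data.frame`: columns `gene`, `degree`.
#' @param sens_prop,tol_min_poly Susceptibility thresholds, see
#'   [classify_susceptibility()].
#' @return A `data.table` with one row per gene in `genes`.
#' @export
summarize_genes <- function(variants, genes, expression = NULL,
                            degrees = NULL, sens_prop = 0.30,
                            tol_min_poly = 50L) {
  vt <- data.table::as.data.table(variants)
  if (!all(c("site_group", "is_dm") %in% names(vt))) {
    stop("variants must be annotated with site_group/is_dm; see annotate_site_groups()")
  }
  gdt <- data.table::as.data.table(genes)
  stopifnot(all(c("gene", "exon_length_bp", "n_polymorphic") %in% names(gdt)))
  # Site-level counts: one site may carry several alleles; count sites once.
  site_counts <- vt[, .(site_group = site_group[1], is_dm = any(is_dm)),
                    by = .(gene, chrom, pos)][, .(
    n_pathogenic_sites = sum(site_group == "pathogenic"),
    n_dm_sites = sum(is_dm),
    n_annotated_sites = .N
  ), by = gene]
  out <- merge(gdt, site_counts, by = "gene", all.x = TRUE)
  for (col in c("n_pathogenic_sites", "n_dm_sites", "n_annotated_sites")) {
    out[is.na(get(col)), (col) := 0L]
  }
  out[, snv_rate_kb := snv_rate(n_polymorphic, exon_length_bp)]
  out[, susceptibility := classify_susceptibility(
    n_pathogenic_sites, n_dm_sites, n_annotated_sites, n_polymorphic,
    sens_prop = sens_prop, tol_min_poly = tol_min_poly)]
  if (!is.null(expression)) {
    edt <- data.table::as.data.table(expression)
    stopifnot("gene" %in% names(edt))
    tissue_cols <- setdiff(names(edt), "gene")
    em <- as.matrix(edt[, ..tissue_cols])
    expr <- data.table::data.table(
      gene = edt$gene,
      expression_max = apply(em, 1, expression_max),
      tissue_specificity = apply(em, 1, tissue_specificity))
    out <- merge(out, expr, by = "gene", all.x = TRUE)
  }
  if (!is.null(degrees)) {
    ddt <- data.table::as.data.table(degrees)
    stopifnot(all(c("gene", "degree") %in% names(ddt)))
    ddt <- ddt[, .(gene, ppi_degree = degree)]
    ddt[, degree_rank := ranked_degree(ppi_degree)]
    out <- merge(out, ddt, by = "gene", all.x = TRUE)
  }
  out[]
}

#' ECDF comparisons of gene metrics between gene groups
#'
#' For each gene metric (maximum expression, tissue specificity, degree
#' rank fraction), compares the gene groups defined by pathogenic-site
#' counts against the full gene universe with two-sample Kolmogorov-Smirnov
#' tests ([ecdf_compare()]): genes with at least one pathogenic site
#' (n > 0), genes with more than 20 (n > 20), and the same two groups on the
#' HGMD DM count.
#'
#' @param gene_summary Output of [summarize_genes()].
#' @param metrics Columns of `gene_summary` to compare.
#' @param cuts Count thresholds (strict `>`), default `c(0, 20)`.
#' @return A `data.table` with one row per metric, count arm (clinical or
#'   DM) and cut: group sizes, KS `d` and `p`.
#' @export
gene_group_comparison <- function(gene_summary,
                                  metrics = c("expression_max",
                                              "tissue_specificity",
                                              "degree_rank"),
                                  cuts = c(0, 20)) {
  gs <- data.table::as.data.table(gene_summary)
  metrics <- intersect(metrics, names(gs))
  if (!length(metrics)) stop("none of the requested metric columns are present")
  arms <- list(clinvar = gs$n_pathogenic_sites, hgmd_dm = gs$n_dm_sites)
  rows <- list()
  for (arm in names(arms)) {
    membership <- group_by_pathogenic_count(arms[[arm]], cuts)
    for (cut_col in colnames(membership)) {
      for (metric in metrics) {
        grp <- gs[[metric]][membership[, cut_col]]
        all_genes <- gs[[metric]]
        res <- ecdf_compare(grp, all_genes)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          arm = arm, group = cut_col, metric = metric,
          n_group = res$n_a, n_all = res$n_b, d = res$d, p = res$p)
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Correlation between polymorphic-site count and exon length
#'
#' Pearson correlation of log10 polymorphic-site counts against log10 exon
#' lengths over genes with at least one polymorphic site.
#'
#' @param gene_summary Output of [summarize_genes()].
#' @return List with `estimate`, `p`, `n`.
#' @export
occurrence_length_correlation <- function(gene_summary) {
  gs <- data.table::as.data.table(gene_summary)
  keep <- gs$n_polymorphic > 0 & gs$exon_length_bp > 0
  if (sum(keep) < 3) return(list(estimate = NA_real_, p = NA_real_, n = sum(keep)))
  ct <- stats::cor.test(log10(gs$n_polymorphic[keep]),
                        log10(gs$exon_length_bp[keep]), method = "pearson")
  list(estimate = unname(ct$estimate), p = unname(ct$p.value), n = sum(keep))
}
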