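# Replicated recovery of the planted effects: the package's validation
# harness. Each replicate draws a fresh synthetic cohort and re-runs the
# corresponding analysis stage from scratch. A planted effect counts as
# detected when the two-sided p-value falls below alpha AND the observed
# difference points in the planted direction; the identical directional
# procedure is applied under a null configuration, where the returned rates
# are the procedure's empirical type-I errors.

#' Replicate recovery of the planted cohort effects
#'
#' Runs the headline analyses over `n_replicates` independently seeded
#' synthetic cohorts and counts, per analysis, the replicates in which the
#' planted effect is detected at level `alpha` (in the planted direction):
#'
#' * `fp_enrichment_planted` / `fp_enrichment_null` — false-positive
#'   enrichment at highly conserved benign positions, for the
#'   conservation-over-reliant tools and for the remaining (null) tools
#'   (fraction of tool-replicate pairs rejected);
#' * `quartet_max` / `quartet_cv` — Wilcoxon rank-sum on the four-allele
#'   maximum (pathogenic above benign) and CV (pathogenic below benign);
#' * `gene_expression`, `gene_specificity`, `gene_degree` —
#'   Kolmogorov-Smirnov comparison of genes with at least one pathogenic
#'   site against the full gene universe;
#' * `polycomb_fn` — Wilcoxon rank-sum of repressed-PolyComb fractions,
#'   false-negative versus true-positive pathogenic/DM sites.
#'
#' The same directional detection rule is applied under
#' `effects = "null"`, so the returned rates are then the empirical type-I
#' errors of the detection procedure.
#'
#' @param seed Master seed; replicate r uses `seed + 101 * r` offsets.
#' @param n_replicates Number of replicates (default 20).
#' @param effects `"planted"` or `"null"`, forwarded to [cohort_config()].
#' @param alpha Significance level (default 0.05).
#' @param quartet_tool,polycomb_tool Representative tools for the quartet
#'   and FN-vs-TP analyses.
#' @param ... Further arguments to [cohort_config()].
#' @return A list with `rates` (named detection fractions), `counts`,
#'   `n_replicates`.
#' @export
recovery_rates <- function(seed, n_replicates = 20,
                           effects = c("planted", "null"), alpha = 0.05,
                           quartet_tool = "SIFT", polycomb_tool = "PROVEAN",
                           ...) {
  effects <- match.arg(effects)
  acc <- list()
  bump <- function(name, hit) {
    if (is.na(hit)) hit <- FALSE
    if (is.null(acc[[name]])) acc[[name]] <<- c(hits = 0L, n = 0L)
    acc[[name]] <<- acc[[name]] + c(hits = as.integer(hit), n = 1L)
  }
  for (r in seq_len(n_replicates)) {
    cfg <- cohort_config(seed = (seed + 101L * r) %% 2000000000L,
                         effects = effects, ...)
    bundle <- generate_cohort(cfg)
    v <- annotate_site_groups(bundle$variants)
    labels <- ifelse(v$site_group %in% c("pathogenic", "benign"),
                     v$site_group, NA_character_)
    calls <- call_tools(v)

    # Conservation over-reliance: FP enrichment at high conservation.
    # Under the null configuration no tool is over-reliant, so every tool
    # contributes to the null arm.
    planted_tools <- if (effects == "planted") cfg$overreliance_tools else character(0)
    prof <- conservation_profile_table(calls, labels, v$phastcons_vertebrate)
    fp <- prof[prof$arm == "fp_high_benign", ]
    for (i in seq_len(nrow(fp))) {
      detected <- !is.na(fp$p[i]) && fp$p[i] < alpha &&
        fp$proportion_group[i] > fp$proportion_background[i]
      arm <- if (fp$tool[i] %in% planted_tools) "fp_enrichment_planted"
             else "fp_enrichment_null"
      bump(arm, detected)
    }

    # Quartet max / CV group shifts.
    q <- generate_quartets(cfg)
    qs <- quartet_stats(q[q$tool == quartet_tool, ])
    pa <- qs[qs$group == "pathogenic", ]
    be <- qs[qs$group == "benign", ]
    tmax <- rank_sum_test(pa$s_max, be$s_max)
    tcv <- rank_sum_test(pa$cv, be$cv)
    hit_max <- !is.na(tmax$p) && tmax$p < alpha &&
      stats::median(pa$s_max) > stats::median(be$s_max)
    hit_cv <- !is.na(tcv$p) && tcv$p < alpha &&
      stats::median(pa$cv) < stats::median(be$cv)
    bump("quartet_max", hit_max)
    bump("quartet_cv", hit_cv)

    # Gene-level ECDF shifts (genes with >= 1 pathogenic site vs all
    # genes); planted direction: pathogenic-carrying genes shifted upward.
    gs <- summarize_genes(v, bundle$genes, bundle$expression, bundle$degrees)
    comp <- gene_group_comparison(gs, cuts = 0)
    comp <- comp[comp$arm == "clinvar", ]
    carrier <- gs$n_pathogenic_sites > 0
    for (metric in c("expression_max", "tissue_specificity", "degree_rank")) {
      p <- comp$p[comp$metric == metric]
      up <- stats::median(gs[[metric]][carrier], na.rm = TRUE) >
        stats::median(gs[[metric]], na.rm = TRUE)
      name <- c(expression_max = "gene_expression",
                tissue_specificity = "gene_specificity",
                degree_rank = "gene_degree")[[metric]]
      bump(name, length(p) == 1 && !is.na(p) && p < alpha && up)
    }

    # FN PolyComb upshift.
    fr <- state_fraction(v[, c("chrom", "pos")], bundle$tracks, "ReprPC")
    fn_tp <- suppressWarnings(fn_tp_state_comparison(
      fr, calls[, polycomb_tool, drop = FALSE], labels))
    hit_pc <- !is.na(fn_tp$p) && fn_tp$p < alpha &&
      !is.na(fn_tp$median_fn) && fn_tp$median_fn > fn_tp$median_tp
    bump("polycomb_fn", hit_pc)
  }
  counts <- acc
  rates <- vapply(acc, function(x) unname(x["hits"] / x["n"]), numeric(1))
  list(rates = rates, counts = counts, n_replicates = n_replicates)
}
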