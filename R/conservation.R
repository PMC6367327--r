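# Conservation stratification of prediction errors, and the
# derived-to-ancestral pathogenic back-mutation report.

#' Bin a phastCons score into high/low conservation
#'
#' Positions with a phastCons score at or above the cutoff are highly
#' conserved, those below are lowly conserved; missing scores propagate.
#' The default cutoff of 0.5 on the vertebrate score is the convention used
#' throughout the conservation-enrichment reports.
#'
#' @param score Numeric vector of phastCons values in \[0, 1\] (NA allowed).
#' @param cutoff Conservation cutoff in (0, 1), default 0.5.
#' @return Character vector of `"high"` / `"low"` / `NA`.
#' @export
#' @examples
#' bin_conservation(c(0.9, 0.1, 0.5, NA))
bin_conservation <- function(score, cutoff = 0.5) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0, cutoff < 1)
  ifelse(is.na(score), NA_character_, ifelse(score >= cutoff, "high", "low"))
}

#' Conservation enrichment of a tool's prediction errors
#'
#' Quantifies a tool's over-reliance on conservation by asking whether its
#' errors concentrate at particular conservation levels:
#'
#' * `direction = "FP-at-high"`: among *benign* variants, are false-positive
#'   calls enriched at highly conserved positions relative to all benign
#'   positions?
#' * `direction = "FN-at-low"`: among *pathogenic* variants, are
#'   false-negative calls enriched at lowly conserved positions relative to
#'   all pathogenic positions?
#'
#' The background is all labeled positions of the relevant truth class
#' (including the error group itself, mirroring the dashed reference line of
#' the usual figure). Significance is Pearson's chi-squared on the 2x2
#' (group vs background) x (high vs low) count table without continuity
#' correction, so equal proportions give p = 1 exactly. Positions with a
#' missing conservation score are excluded from both group and background.
#'
#' @param calls Character vector of one tool's calls
#'   (`"pathogenic"`/`"benign"`/`NA`).
#' @param labels Truth labels (`"pathogenic"`/`"benign"`), same length.
#' @param conservation Numeric phastCons scores, same length.
#' @param direction `"FP-at-high"` or `"FN-at-low"`.
#' @param cutoff Conservation cutoff passed to [bin_conservation()].
#' @return List of class `enrichment_test`: `group_count`, `group_total`,
#'   `background_count`, `background_total`, `proportion_group`,
#'   `proportion_background`, `chi2`, `p`, `stars`. When the error group is
#'   empty all statistics are `NA` and a warning is issued.
#' @export
error_conservation_profile <- function(calls, labels, conservation,
                                       direction = c("FP-at-high", "FN-at-low"),
                                       cutoff = 0.5) {
  direction <- match.arg(direction)
  stopifnot(length(calls) == length(labels), length(labels) == length(conservation))
  bin <- bin_conservation(conservation, cutoff)
  has_cons <- !is.na(bin)
  if (direction == "FP-at-high") {
    in_background <- has_cons & labels == "benign"
    in_group <- in_background & !is.na(calls) & calls == "pathogenic"
    counted <- bin == "high"
  } else {
    in_background <- has_cons & labels == "pathogenic"
    in_group <- in_background & !is.na(calls) & calls == "benign"
    counted <- bin == "low"
  }
  group_total <- sum(in_group)
  background_total <- sum(in_background)
  if (group_total == 0) {
    warning("empty error group for direction ", direction,
            "; enrichment reported missing")
    out <- list(group_count = 0L, group_total = 0L,
                background_count = sum(in_background & counted),
                background_total = background_total,
                proportion_group = NA_real_, proportion_background = NA_real_,
                chi2 = NA_real_, p = NA_real_, stars = NA_character_)
    class(out) <- "enrichment_test"
    return(out)
  }
  group_count <- sum(in_group & counted)
  background_count <- sum(in_background & counted)
  test <- proportion_chi2(group_count, group_total, background_count, background_total)
  out <- list(group_count = group_count, group_total = group_total,
              background_count = background_count,
              background_total = background_total,
              proportion_group = test$proportion_group,
              proportion_background = test$proportion_background,
              chi2 = test$chi2, p = test$p,
              stars = significance_stars(test$p))
  class(out) <- "enrichment_test"
  out
}

#' Conservation-enrichment table over all tools
#'
#' Runs [error_conservation_profile()] for every tool of a call matrix, for
#' false positives at high conservation among benign variants and for false
#' negatives at low conservation among pathogenic variants — the latter both
#' with the clinical-annotation truth and, separately, restricted to HGMD
#' disease-causing (DM) variants when `is_dm` is supplied.
#'
#' @param calls Call matrix from [call_tools()].
#' @param labels Truth labels (`"pathogenic"`/`"benign"`), `NA` for
#'   unlabeled rows (excluded).
#' @param conservation phastCons scores, one per row.
#' @param is_dm Optional logical vector flagging HGMD DM variants.
#' @param cutoff Conservation cutoff.
#' @return A `data.table` with one row per tool and analysis arm
#'   (`fp_high_benign`, `fn_low_pathogenic`, `fn_low_dm`), carrying the
#'   enrichment counts, proportions, `chi2`, `p` and `stars`.
#' @export
conservation_profile_table <- function(calls, labels, conservation,
                                       is_dm = NULL, cutoff = 0.5) {
  tools <- colnames(calls)
  arms <- list(fp_high_benign = list(direction = "FP-at-high", keep = NULL),
               fn_low_pathogenic = list(direction = "FN-at-low", keep = NULL))
  if (!is.null(is_dm)) {
    arms$fn_low_dm <- list(direction = "FN-at-low", keep = is_dm)
  }
  rows <- list()
  for (tool in tools) {
    for (arm in names(arms)) {
      keep <- !is.na(labels)
      if (!is.null(arms[[arm]]$keep)) keep <- keep & arms[[arm]]$keep
      res <- suppressWarnings(error_conservation_profile(
        calls[keep, tool], labels[keep], conservation[keep],
        direction = arms[[arm]]$direction, cutoff = cutoff))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tool = tool, arm = arm,
        group_count = res$group_count, group_total = res$group_total,
        background_count = res$background_count,
        background_total = res$background_total,
        proportion_group = res$proportion_group,
        proportion_background = res$proportion_background,
        chi2 = res$chi2, p = res$p, stars = res$stars)
    }
  }
  data.table::rbindlist(rows)
}

#' Report pathogenic derived-to-ancestral back mutations
#'
#' Filters a variant table to back mutations ([flag_back_mutation()]) that
#' qualify as pathogenic: the variant carries at least one
#' pathogenic-evidence clinical term (per `term_map`), or its HGMD class
#' belongs to `hgmd_set` (default `"DM"`, the disease-causing class; widen
#' to e.g. `c("DM","DM?","DP","DFP","FP")` for the broader class set).
#'
#' @param variants A variant table with ancestral-allele columns.
#' @param term_map Clinical term mapping, see [default_term_map()].
#' @param hgmd_set HGMD classes accepted as pathogenic evidence.
#' @param require_high_confidence Passed to [flag_back_mutation()].
#' @return List with `variants` (a `data.table` of qualifying rows:
#'   gene, hgvs, clinvar, hgmd_class and coordinates), `n_variants` and
#'   `n_genes` (unique gene symbols).
#' @export
back_mutation_report <- function(variants, term_map = default_term_map(),
                                 hgmd_set = "DM",
                                 require_high_confidence = TRUE) {
  dt <- data.table::as.data.table(variants)
  is_back <- flag_back_mutation(dt, require_high_confidence)
  has_path_term <- vapply(dt$clinvar, function(x) {
    terms <- split_terms(x)
    any(unname(term_map[terms[terms %in% names(term_map)]]) == "pathogenic")
  }, logical(1))
  qualifies <- is_back & (has_path_term | dt$hgmd_class %in% hgmd_set)
  keep_cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "hgvs",
                           "clinvar", "hgmd_class"), names(dt))
  hits <- dt[qualifies, ..keep_cols]
  list(variants = hits[], n_variants = nrow(hits),
       n_genes = length(unique(hits$gene)))
}

#' Packaged derived-to-ancestral pathogenic variant fixture
#'
#' Loads the packaged table of pathogenic mutations whose alternative allele
#' restores the inferred ancestral state: 35 variants in 33 genes, each with
#' its transcript-level HGVS change, clinical-significance terms, HGMD class
#' and orthologue counts from a 137-species comparison. Genomic coordinates
#' in this fixture are synthetic placeholders (the source table identifies
#' variants by transcript change only); the HGVS strings carry the variant
#' identity.
#'
#' @return A validated variant `data.table` (see [read_variant_table()]).
#' @export
#' @examples
#' fx <- ancestral_reversion_fixture()
#' back_mutation_report(fx)$n_variants
ancestral_reversion_fixture <- function() {
  path <- system.file("extdata", "ancestral_reversion_variants.tsv",
                      package = "varlevel", mustWork = TRUE)
  read_variant_table(path)
}

#' Descriptive phyloP summary per clade
#'
#' Sign counts and distribution quantiles of phyloP scores per clade and
#' site group. phyloP is a per-position -log p-value whose sign separates
#' conservation (positive) from acceleration (negative); the summary is
#' descriptive — no hypothesis test is attached.
#'
#' @param variants Variant table with `phylop_*` columns and a `site_group`
#'   column (see [annotate_site_groups()]).
#' @return A `data.table` with one row per clade and site group: counts of
#'   positive/negative scores and quartiles.
#' @export
phylop_summary <- function(variants) {
  dt <- data.table::as.data.table(variants)
  if (!"site_group" %in% names(dt)) stop("variants must carry a site_group column")
  cols <- intersect(paste0("phylop_", CLADE_NAMES), names(dt))
  if (!length(cols)) stop("no phylop_* columns present")
  rows <- lapply(cols, function(col) {
    dt[!is.na(get(col)), .(
      clade = sub("^phylop_", "", col),
      n = .N,
      n_positive = sum(get(col) > 0),
      n_negative = sum(get(col) < 0),
      q25 = stats::quantile(get(col), 0.25),
      median = stats::median(get(col)),
      q75 = stats::quantile(get(col), 0.75)
    ), by = site_group]
  })
  data.table::rbindlist(rows)
}
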