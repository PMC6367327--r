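# Pipeline orchestration: stage sequencing over an input bundle directory,
# per-stage TSV outputs, and a machine-readable JSON summary.

#' Run the multi-level analysis pipeline
#'
#' Executes the analysis stages in dependency order over an input directory
#' laid out as written by [write_cohort()] (`variants.tsv` mandatory;
#' `genes.tsv`, `expression.tsv`, `degrees.tsv`, `state_tracks.tsv`,
#' `quartets.tsv` optional, enabling their stages):
#'
#' 1. `classify` — site-group annotation and per-tool calls (always runs);
#' 2. `evaluate` — per-tool confusion metrics, pairwise agreement, the
#'    all-agree combination scan and its per-size summary;
#' 3. `conservation` — FP/FN conservation enrichment per tool, phyloP
#'    descriptive summary, back-mutation report;
#' 4. `sites` — four-allele quartet statistics and group comparisons
#'    (needs `quartets.tsv`), emitted under each configured
#'    reference-allele convention;
#' 5. `genes` — gene summaries, susceptibility classes, ECDF group
#'    comparisons (needs `genes.tsv`);
#' 6. `polycomb` — PolyComb state fractions, site-group and FN-vs-TP
#'    comparisons (needs `state_tracks.tsv`).
#'
#' Any stage failure aborts with the stage name in the error. When
#' `out_dir` is given, each stage writes its tables as TSV, a JSON summary
#' collects every computed statistic and p-value (including comparisons
#' reported missing), and `run_log.txt` records the resolved configuration
#' and its hash.
#'
#' @param input_dir Directory holding the input bundle.
#' @param out_dir Optional output directory for the report bundle.
#' @param stages Stages to run (subset of the names above; `classify` is
#'   implicit).
#' @param term_map,thresholds,cons_cutoff,sens_prop,tol_min_poly Analysis
#'   parameters; see [default_term_map()], [default_thresholds()],
#'   [bin_conservation()], [classify_susceptibility()].
#' @param ref_conventions Reference-allele conventions for the quartet
#'   stage (each one is reported).
#' @param state_denominator Denominator rule for [state_fraction()].
#' @return List of class `pipeline_report` with one element per executed
#'   stage plus `config`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         stages = c("evaluate", "conservation", "sites",
                                    "genes", "polycomb"),
                         term_map = default_term_map(),
                         thresholds = default_thresholds(),
                         cons_cutoff = 0.5,
                         sens_prop = 0.30, tol_min_poly = 50L,
                         ref_conventions = "zero",
                         state_denominator = "all") {
  stages <- match.arg(stages, c("evaluate", "conservation", "sites", "genes",
                                "polycomb"), several.ok = TRUE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, f) {
    if (!is.null(out_dir)) data.table::fwrite(x, file.path(out_dir, f),
                                              sep = "\t", na = ".", quote = FALSE)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list()
  cfg <- list(input_dir = input_dir, stages = stages, cons_cutoff = cons_cutoff,
              sens_prop = sens_prop, tol_min_poly = tol_min_poly,
              ref_conventions = ref_conventions,
              state_denominator = state_denominator,
              term_map = as.list(term_map), thresholds = as.list(thresholds))
  report$config <- cfg

  ## classify (always)
  variants <- stage("classify", {
    path <- file.path(input_dir, "variants.tsv")
    if (!file.exists(path)) stop("missing variants.tsv in ", input_dir)
    annotate_site_groups(read_variant_table(path), term_map)
  })
  labels <- ifelse(variants$site_group %in% c("pathogenic", "benign"),
                   variants$site_group, NA_character_)
  calls <- call_tools(variants, thresholds)
  labeled <- !is.na(labels)
  report$classify <- list(
    n_variants = nrow(variants),
    site_groups = as.list(table(variants$site_group)),
    n_dm = sum(variants$is_dm))

  if ("evaluate" %in% stages) {
    report$evaluate <- stage("evaluate", {
      per_tool <- data.table::rbindlist(lapply(colnames(calls), function(tool) {
        ct <- confusion(calls[labeled, tool], labels[labeled])
        met <- confusion_metrics(ct)
        data.table::data.table(tool = tool, tp = ct$tp, fp = ct$fp, tn = ct$tn,
                               fn = ct$fn, unclassified = ct$unclassified,
                               sensitivity = met[["sensitivity"]],
                               specificity = met[["specificity"]],
                               accuracy = met[["accuracy"]],
                               accuracy_called = met[["accuracy_called"]])
      }))
      agreement <- pairwise_agreement(calls)
      scan <- scan_combinations(calls[labeled, , drop = FALSE], labels[labeled])
      by_size <- summarize_by_size(scan)
      emit(per_tool, "tool_metrics.tsv")
      emit(data.table::as.data.table(agreement, keep.rownames = "tool"),
           "pairwise_agreement.tsv")
      emit(scan, "combination_scan.tsv")
      emit(by_size, "combination_by_size.tsv")
      list(per_tool = per_tool, agreement = agreement, scan = scan,
           by_size = by_size,
           agreement_range = range(agreement[upper.tri(agreement)], na.rm = TRUE))
    })
  }

  if ("conservation" %in% stages) {
    report$conservation <- stage("conservation", {
      prof <- conservation_profile_table(
        calls, labels, variants$phastcons_vertebrate,
        is_dm = variants$is_dm, cutoff = cons_cutoff)
      phylop <- phylop_summary(variants)
      back <- back_mutation_report(variants, term_map)
      emit(prof, "conservation_enrichment.tsv")
      emit(phylop, "phylop_summary.tsv")
      if (nrow(back$variants)) emit(back$variants, "back_mutations.tsv")
      list(enrichment = prof, phylop = phylop,
           back_mutations = back$variants,
           n_back_variants = back$n_variants, n_back_genes = back$n_genes)
    })
  }

  if ("sites" %in% stages && file.exists(file.path(input_dir, "quartets.tsv"))) {
    report$sites <- stage("sites", {
      quartets <- data.table::fread(file.path(input_dir, "quartets.tsv"),
                                    sep = "\t", na.strings = c(".", ""),
                                    showProgress = FALSE)
      out <- list()
      for (conv in ref_conventions) {
        qs <- quartet_stats(quartets, ref_convention = conv)
        grp <- data.table::copy(qs)
        if ("is_dm" %in% names(grp)) {
          dm_rows <- grp[is_dm == TRUE][, group := "dm"]
          grp <- rbind(grp, dm_rows)
        }
        comps <- data.table::rbindlist(lapply(unique(grp$tool), function(tl) {
          sub <- grp[tool == tl]
          rbind(
            cbind(statistic = "max", tool = tl,
                  compare_score_groups(sub$s_max, sub$group)),
            cbind(statistic = "cv", tool = tl,
                  compare_score_groups(sub$cv, sub$group)))
        }))
        cors <- data.table::rbindlist(lapply(unique(qs$tool), function(tl) {
          sub <- qs[tool == tl]
          cm <- score_conservation_correlation(sub$s_max, sub$phastcons_vertebrate)
          cc <- score_conservation_correlation(sub$cv, sub$phastcons_vertebrate)
          data.table::data.table(tool = tl,
                                 cor_max = cm$estimate, p_max = cm$p,
                                 cor_cv = cc$estimate, p_cv = cc$p)
        }))
        emit(qs, paste0("site_stats_", conv, ".tsv"))
        emit(comps, paste0("site_group_tests_", conv, ".tsv"))
        emit(cors, paste0("site_conservation_cor_", conv, ".tsv"))
        out[[conv]] <- list(stats = qs, comparisons = comps,
                            conservation_correlation = cors)
      }
      out
    })
  }

  if ("genes" %in% stages && file.exists(file.path(input_dir, "genes.tsv"))) {
    report$genes <- stage("genes", {
      genes <- data.table::fread(file.path(input_dir, "genes.tsv"), sep = "\t",
                                 na.strings = c(".", ""), showProgress = FALSE)
      read_opt <- function(f) {
        p <- file.path(input_dir, f)
        if (file.exists(p)) data.table::fread(p, sep = "\t",
                                              na.strings = c(".", ""),
                                              showProgress = FALSE) else NULL
      }
      gs <- summarize_genes(variants, genes, read_opt("expression.tsv"),
                            read_opt("degrees.tsv"), sens_prop, tol_min_poly)
      comp <- gene_group_comparison(gs)
      olc <- occurrence_length_correlation(gs)
      emit(gs, "gene_summary.tsv")
      emit(comp, "gene_group_tests.tsv")
      list(summary = gs, comparisons = comp,
           susceptibility = as.list(table(gs$susceptibility)),
           snv_rate_mean = mean(gs$snv_rate_kb),
           occurrence_length_correlation = olc)
    })
  }

  if ("polycomb" %in% stages &&
      file.exists(file.path(input_dir, "state_tracks.tsv"))) {
    report$polycomb <- stage("polycomb", {
      tracks <- read_state_tracks(file.path(input_dir, "state_tracks.tsv"))
      fr <- polycomb_fractions(variants[, .(chrom, pos)], tracks,
                               denominator = state_denominator)
      grp <- ifelse(variants$is_dm & variants$site_group != "pathogenic", "dm",
                    variants$site_group)
      frac_cols <- c("frac_ReprPC", "frac_ReprPCWk", "frac_ReprPC_or_Wk")
      group_tests <- data.table::rbindlist(lapply(frac_cols, function(col) {
        cbind(state = col, group_state_comparison(fr[[col]], grp))
      }))
      fn_tp <- data.table::rbindlist(lapply(frac_cols, function(col) {
        cbind(state = col,
              suppressWarnings(fn_tp_state_comparison(fr[[col]], calls, labels)))
      }))
      emit(cbind(variants[, .(chrom, pos, gene, site_group, is_dm)],
                 fr[, ..frac_cols]), "polycomb_fractions.tsv")
      emit(group_tests, "polycomb_group_tests.tsv")
      emit(fn_tp, "polycomb_fn_tp_tests.tsv")
      list(fractions = fr, group_tests = group_tests, fn_tp = fn_tp)
    })
  }

  if (!is.null(out_dir)) {
    summary_json <- summarize_report(report)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    cfg_text <- yaml::as.yaml(cfg)
    writeLines(c(paste0("config_hash: ",
                        substr(digest_string(cfg_text), 1, 16)),
                 "resolved config:", cfg_text),
               file.path(out_dir, "run_log.txt"))
  }
  class(report) <- "pipeline_report"
  invisible(report)
}

# Minimal stable hash (sum of char codes in blocks) for the run log; avoids
# a digest dependency while making config drift visible.
digest_string <- function(x) {
  bytes <- utf8ToInt(x)
  acc <- 0
  for (b in bytes) acc <- (acc * 31 + b) %% 2^48
  paste0(sprintf("%06x", acc %/% 2^24), sprintf("%06x", acc %% 2^24))
}

# Flatten the report into JSON-friendly lists of statistics and p-values.
summarize_report <- function(report) {
  out <- list()
  dtl <- function(x) if (data.table::is.data.table(x)) as.list(x) else x
  if (!is.null(report$classify)) out$classify <- report$classify
  if (!is.null(report$evaluate)) {
    out$evaluate <- list(per_tool = dtl(report$evaluate$per_tool),
                         by_size = dtl(report$evaluate$by_size),
                         agreement_range = report$evaluate$agreement_range,
                         n_combinations = nrow(report$evaluate$scan))
  }
  if (!is.null(report$conservation)) {
    out$conservation <- list(enrichment = dtl(report$conservation$enrichment),
                             n_back_variants = report$conservation$n_back_variants,
                             n_back_genes = report$conservation$n_back_genes)
  }
  if (!is.null(report$sites)) {
    out$sites <- lapply(report$sites, function(conv) {
      list(comparisons = dtl(conv$comparisons),
           conservation_correlation = dtl(conv$conservation_correlation))
    })
  }
  if (!is.null(report$genes)) {
    out$genes <- list(comparisons = dtl(report$genes$comparisons),
                      susceptibility = report$genes$susceptibility,
                      snv_rate_mean = report$genes$snv_rate_mean,
                      occurrence_length_correlation =
                        report$genes$occurrence_length_correlation)
  }
  if (!is.null(report$polycomb)) {
    out$polycomb <- list(group_tests = dtl(report$polycomb$group_tests),
                         fn_tp = dtl(report$polycomb$fn_tp))
  }
  out
}
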