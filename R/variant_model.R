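# Site classification, per-tool binary calls and ancestral back-mutation
# flagging.

#' Classify one genomic site from its clinical annotation terms
#'
#' Implements the four-group site classification: a site is *pathogenic* when
#' at least one of the terms attached to its observed alleles maps to
#' pathogenic evidence and none to benign evidence; *benign* symmetrically;
#' *both* when evidence of each kind is present; *other* when neither is.
#' Terms absent from `term_map` contribute no evidence and trigger a warning
#' (once per unknown term).
#'
#' @param terms Character vector of clinical-significance terms collected
#'   over every variant observed at the site (may be empty; `NA`s ignored).
#' @param term_map Named character vector mapping terms to `"pathogenic"` or
#'   `"benign"`; see [default_term_map()].
#' @return One of `"pathogenic"`, `"benign"`, `"both"`, `"other"`.
#' @export
#' @examples
#' classify_site(c("Pathogenic"))                      # "pathogenic"
#' classify_site(c("Benign", "Pathogenic"))            # "both"
#' classify_site(character(0))                         # "other"
classify_site <- function(terms, term_map = default_term_map()) {
  terms <- terms[!is.na(terms)]
  unknown <- setdiff(unique(terms), names(term_map))
  if (length(unknown)) {
    warning("clinical term(s) not in term_map treated as no evidence: ",
            paste(unknown, collapse = ", "))
  }
  evidence <- unname(term_map[terms[terms %in% names(term_map)]])
  has_path <- any(evidence == "pathogenic")
  has_ben <- any(evidence == "benign")
  if (has_path && has_ben) "both"
  else if (has_path) "pathogenic"
  else if (has_ben) "benign"
  else "other"
}

# Split a ";"-joined clinvar field into a term vector.
split_terms <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Classify every site of a variant table
#'
#' Pools the clinical terms of all variants sharing a genomic position
#' (multi-allelic sites contribute every allele's terms) and applies
#' [classify_site()] to each site. The classification is total and
#' exclusive: each site receives exactly one of the four groups. A site is
#' additionally flagged `is_dm` when any of its variants carries HGMD class
#' `"DM"`.
#'
#' @param variants A variant table (see [read_variant_table()]).
#' @param term_map Term-evidence mapping, see [default_term_map()].
#' @return A `data.table` with one row per site: `chrom`, `pos`,
#'   `site_group`, `is_dm`. Unknown terms are reported by a single warning
#'   listing them.
#' @export
classify_sites <- function(variants, term_map = default_term_map()) {
  dt <- data.table::as.data.table(variants)
  all_terms <- unlist(lapply(dt$clinvar, split_terms))
  unknown <- setdiff(unique(all_terms), names(term_map))
  if (length(unknown)) {
    warning("clinical term(s) not in term_map treated as no evidence: ",
            paste(unknown, collapse = ", "))
  }
  sites <- dt[, {
    terms <- unlist(lapply(clinvar, split_terms))
    evidence <- unname(term_map[terms[terms %in% names(term_map)]])
    has_path <- any(evidence == "pathogenic")
    has_ben <- any(evidence == "benign")
    grp <- if (has_path && has_ben) "both"
           else if (has_path) "pathogenic"
           else if (has_ben) "benign"
           else "other"
    list(site_group = grp, is_dm = any(hgmd_class == "DM"))
  }, by = .(chrom, pos)]
  sites[]
}

#' Annotate variant rows with their site group
#'
#' Convenience wrapper joining the per-site classification of
#' [classify_sites()] back onto the variant rows as columns `site_group`
#' and `is_dm`.
#'
#' @inheritParams classify_sites
#' @return The variant table with `site_group` and `is_dm` columns added.
#' @export
annotate_site_groups <- function(variants, term_map = default_term_map()) {
  dt <- data.table::as.data.table(variants)
  drop <- intersect(c("site_group", "is_dm"), names(dt))
  if (length(drop)) dt[, (drop) := NULL]
  sites <- classify_sites(dt, term_map)
  out <- merge(dt, sites, by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  out[]
}

#' Binary pathogenicity call from a rank score
#'
#' A tool calls a variant pathogenic when its rank score strictly exceeds
#' the tool's cutoff, benign when it is at or below the cutoff; a missing
#' score propagates to a missing call.
#'
#' @param score Numeric vector of rank scores in \[0, 1\] (NA = missing).
#' @param tool Tool name; must belong to [prediction_tools()].
#' @param thresholds Named cutoff vector, see [default_thresholds()].
#' @return Character vector of `"pathogenic"` / `"benign"` / `NA`.
#' @export
#' @examples
#' call_tool(c(0.51, 0.5, NA), "CADD")
call_tool <- function(score, tool, thresholds = default_thresholds()) {
  if (!tool %in% prediction_tools()) {
    stop("unknown tool: ", tool, " (must be one of the twelve-predictor panel)")
  }
  if (!tool %in% names(thresholds)) stop("no threshold configured for ", tool)
  ifelse(is.na(score), NA_character_,
         ifelse(score > thresholds[[tool]], "pathogenic", "benign"))
}

#' Per-tool call matrix for a variant table
#'
#' Applies [call_tool()] to every `rank_<tool>` column present in the table.
#'
#' @param variants A variant table carrying rank-score columns.
#' @param thresholds Named cutoff vector, see [default_thresholds()].
#' @param tools Tools to call; defaults to those with a score column present.
#' @return A character matrix (rows = variants, columns = tools) with
#'   entries `"pathogenic"`, `"benign"` or `NA`.
#' @export
call_tools <- function(variants, thresholds = default_thresholds(),
                       tools = NULL) {
  dt <- data.table::as.data.table(variants)
  present <- prediction_tools()[score_column(prediction_tools()) %in% names(dt)]
  if (is.null(tools)) tools <- present
  missing_tools <- setdiff(tools, present)
  if (length(missing_tools)) {
    stop("no rank-score column for tool(s): ", paste(missing_tools, collapse = ", "))
  }
  calls <- vapply(tools, function(tl) call_tool(dt[[score_column(tl)]], tl, thresholds),
                  character(nrow(dt)))
  calls <- matrix(calls, nrow = nrow(dt), dimnames = list(NULL, tools))
  calls
}

#' Flag derived-to-ancestral back mutations
#'
#' A variant is a back mutation when its alternative allele restores the
#' inferred ancestral nucleotide: the ancestral call is present (and
#' high-confidence, unless `require_high_confidence = FALSE`), `alt` equals
#' the ancestral nucleotide and `ref` differs from it. Variants without an
#' ancestral call are never flagged.
#'
#' @param variants A variant table with `ancestral_allele` and
#'   `ancestral_confidence` columns (see [read_variant_table()] for the
#'   1000G case-to-confidence convention).
#' @param require_high_confidence Only accept high-confidence ancestral
#'   calls (default `TRUE`).
#' @return Logical vector, one element per row.
#' @export
flag_back_mutation <- function(variants, require_high_confidence = TRUE) {
  dt <- data.table::as.data.table(variants)
  anc <- if ("ancestral_allele" %in% names(dt)) dt$ancestral_allele else rep(NA_character_, nrow(dt))
  conf <- if ("ancestral_confidence" %in% names(dt)) dt$ancestral_confidence else rep(NA_character_, nrow(dt))
  ok_conf <- if (require_high_confidence) !is.na(conf) & conf == "high" else !is.na(anc)
  !is.na(anc) & ok_conf & dt$alt == anc & dt$ref != anc
}
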