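# Fixed predictor panel and default configuration vocabularies.

#' The twelve-predictor panel
#'
#' Names of the twelve pathogenicity predictors whose dbNSFP-style rank
#' scores the package evaluates. Rank scores are quantile-transformed raw
#' scores, so every tool is scored on a common \[0, 1\] scale.
#'
#' @return Character vector of the twelve tool names.
#' @export
#' @examples
#' prediction_tools()
prediction_tools <- function() {
  c("SIFT", "PROVEAN", "MutationTaster", "FATHMM-MKL", "FATHMM-XF",
    "FATHMM", "MetaSVM", "MetaLR", "PolyPhen-2", "MutationAssessor",
    "CADD", "DANN")
}

#' Default per-tool pathogenicity thresholds
#'
#' A variant is called pathogenic by a tool when its rank score strictly
#' exceeds the tool's cutoff. The default places every cutoff at 0.5 (the
#' published rule for ranked CADD and DANN scores); individual tools can be
#' overridden.
#'
#' @param ... Named overrides, e.g. `SIFT = 0.39`. Names must belong to
#'   [prediction_tools()].
#' @return Named numeric vector of cutoffs over the twelve tools.
#' @export
#' @examples
#' default_thresholds()
#' default_thresholds(MetaSVM = 0.82)["MetaSVM"]
default_thresholds <- function(...) {
  cuts <- setNames(rep(0.5, 12L), prediction_tools())
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), prediction_tools())
    if (length(bad)) {
      stop("unknown tool(s) in threshold overrides: ", paste(bad, collapse = ", "))
    }
    cuts[names(dots)] <- as.numeric(unlist(dots))
  }
  if (any(cuts <= 0 | cuts >= 1)) stop("thresholds must lie strictly inside (0, 1)")
  cuts
}

#' Default ClinVar term mapping
#'
#' Maps clinical-significance terms to the evidence categories used by the
#' four-group site classification. "Pathogenic", "Likely pathogenic" and
#' their combined form count as pathogenic evidence; "Benign",
#' "Likely benign" and their combined form as benign evidence. Any term not
#' in the map (e.g. "risk factor", "association", "protective",
#' "Uncertain significance") contributes no evidence.
#'
#' @return Named character vector: term -> "pathogenic" or "benign".
#' @export
#' @examples
#' default_term_map()[["Likely pathogenic"]]
default_term_map <- function() {
  c("Pathogenic"                    = "pathogenic",
    "Likely pathogenic"             = "pathogenic",
    "Pathogenic/Likely pathogenic"  = "pathogenic",
    "Benign"                        = "benign",
    "Likely benign"                 = "benign",
    "Benign/Likely benign"          = "benign")
}

#' HGMD variant class vocabulary
#'
#' The closed vocabulary of HGMD classes carried on a variant record. "DM"
#' (disease-causing mutation) marks variants with cogent evidence of
#' pathogenicity; "none" encodes the absence of an HGMD record.
#'
#' @return Character vector of admissible class codes.
#' @export
hgmd_classes <- function() c("DM", "DM?", "DP", "DFP", "FP", "none")

#' Significance stars for enrichment p-values
#'
#' Encodes a p-value with the star convention used throughout the
#' conservation-enrichment reports: `"*"` for p < 0.05, `"**"` for
#' p < 1e-5 and `"***"` for p < 1e-10 (strict inequalities).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Character vector of `""`, `"*"`, `"**"` or `"***"` (NA for NA
#'   input).
#' @export
#' @examples
#' significance_stars(c(0.04, 1e-7, 1e-12, 0.05))
significance_stars <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 1e-10, "***",
             ifelse(p[ok] < 1e-5, "**",
             ifelse(p[ok] < 0.05, "*", "")))
  out
}

# Internal: column name carrying a tool's rank score in the variant table.
score_column <- function(tool) paste0("rank_", tool)

# Internal: nucleotide alphabet.
NUCLEOTIDES <- c("A", "C", "G", "T")
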