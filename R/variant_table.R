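# Variant-table ingestion and validation.
#
# The package's central input is a tab-separated variant table in which each
# row is one non-synonymous SNV (one alt allele; multi-allelic sites occupy
# several rows sharing chrom/pos). Missing values are encoded as "." or the
# empty string. Columns:
#
#   chrom, pos, ref, alt, gene, clinvar, hgmd_class        (mandatory)
#   hgvs, ancestral_allele, ancestral_confidence,          (optional)
#   nondegenerate, phastcons_{vertebrate,mammal,primate},
#   phylop_{vertebrate,mammal,primate}, rank_<tool> x 12
#
# `clinvar` holds the site's clinical-significance terms for that allele,
# joined with ";". Coordinates are 1-based and fully closed (VCF convention);
# chromosome names are stored verbatim unless normalization is requested.

MANDATORY_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "clinvar", "hgmd_class")

CLADE_NAMES <- c("vertebrate", "mammal", "primate")

conservation_columns <- function() {
  c(paste0("phastcons_", CLADE_NAMES), paste0("phylop_", CLADE_NAMES))
}

#' Read and validate a variant table
#'
#' Parses a tab-separated variant table, applying the package's validation
#' rules: rank scores must lie in \[0, 1\], phastCons scores in \[0, 1\],
#' `ref`/`alt` must be distinct single nucleotides, `pos` a positive integer,
#' and `hgmd_class` must come from [hgmd_classes()] (absence becomes
#' `"none"`). Rows violating a rule are removed and reported — with their row
#' index and the offending field — via a warning and the `"row_errors"`
#' attribute, never silently dropped. A missing mandatory column is a
#' configuration error and aborts.
#'
#' 1000 Genomes-style ancestral calls use lowercase letters for
#' low-confidence inferences; when no `ancestral_confidence` column is
#' present the parser maps case to confidence (uppercase = high,
#' lowercase = low) and uppercases the allele.
#'
#' @param path Path to the TSV file.
#' @param normalize_chrom If `TRUE`, strip a leading `"chr"` from chromosome
#'   names. Default `FALSE` (names stored verbatim).
#' @return A `data.table` with one validated row per variant, missing values
#'   as `NA`, and attribute `"row_errors"` (a `data.frame` with columns
#'   `row` and `message`; zero rows when the file is clean).
#' @seealso [write_variant_table()] for the inverse operation.
#' @export
read_variant_table <- function(path, normalize_chrom = FALSE) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", na.strings = c(".", "", "NA"),
                          colClasses = list(character = "chrom"),
                          showProgress = FALSE)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_variant_table(dt, normalize_chrom = normalize_chrom)
}

# Validation shared by the file reader and in-memory tables. Returns the
# cleaned table with a "row_errors" attribute.
validate_variant_table <- function(dt, normalize_chrom = FALSE) {
  dt <- data.table::copy(data.table::as.data.table(dt))
  n <- nrow(dt)
  errors <- list()
  bad <- rep(FALSE, n)
  note <- function(rows, msg) {
    rows <- which(rows)
    if (length(rows)) {
      errors[[length(errors) + 1L]] <<- data.frame(row = rows, message = msg)
      bad[rows] <<- TRUE
    }
  }

  dt[, chrom := as.character(chrom)]
  if (normalize_chrom) dt[, chrom := sub("^chr", "", chrom)]

  pos_num <- suppressWarnings(as.numeric(dt$pos))
  note(is.na(pos_num) | pos_num < 1 | pos_num != floor(pos_num),
       "unparseable or non-positive coordinate")
  dt[, pos := pos_num]

  for (col in c("ref", "alt")) {
    data.table::set(dt, j = col, value = toupper(as.character(dt[[col]])))
    note(!dt[[col]] %in% NUCLEOTIDES, paste0("malformed ", col, " allele"))
  }
  note(!is.na(dt$ref) & !is.na(dt$alt) & dt$ref == dt$alt,
       "ref and alt alleles identical")

  dt[is.na(hgmd_class), hgmd_class := "none"]
  note(!dt$hgmd_class %in% hgmd_classes(), "hgmd_class outside the closed vocabulary")

  # Ancestral call: map 1000G case convention to explicit confidence.
  if (!"ancestral_allele" %in% names(dt)) dt[, ancestral_allele := NA_character_]
  dt[, ancestral_allele := as.character(ancestral_allele)]
  if (!"ancestral_confidence" %in% names(dt)) {
    dt[, ancestral_confidence := data.table::fifelse(
      is.na(ancestral_allele), NA_character_,
      data.table::fifelse(ancestral_allele == toupper(ancestral_allele), "high", "low"))]
  }
  dt[, ancestral_allele := toupper(ancestral_allele)]
  note(!is.na(dt$ancestral_allele) & !dt$ancestral_allele %in% NUCLEOTIDES,
       "malformed ancestral allele")
  note(!is.na(dt$ancestral_confidence) &
         !dt$ancestral_confidence %in% c("high", "low"),
       "ancestral confidence must be 'high' or 'low'")

  for (tool in prediction_tools()) {
    col <- score_column(tool)
    if (!col %in% names(dt)) next
    v <- suppressWarnings(as.numeric(dt[[col]]))
    note(!is.na(dt[[col]]) & is.na(v), paste0("non-numeric rank score for ", tool))
    note(!is.na(v) & (v < 0 | v > 1), paste0("rank score outside [0, 1] for ", tool))
    data.table::set(dt, j = col, value = v)
  }
  for (col in intersect(paste0("phastcons_", CLADE_NAMES), names(dt))) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    note(!is.na(v) & (v < 0 | v > 1), paste0(col, " outside [0, 1]"))
    data.table::set(dt, j = col, value = v)
  }
  for (col in intersect(paste0("phylop_", CLADE_NAMES), names(dt))) {
    data.table::set(dt, j = col, value = suppressWarnings(as.numeric(dt[[col]])))
  }
  if ("nondegenerate" %in% names(dt)) {
    dt[, nondegenerate := as.logical(as.integer(nondegenerate))]
  }
  if ("clinvar" %in% names(dt)) dt[, clinvar := as.character(clinvar)]

  row_errors <- if (length(errors)) {
    do.call(rbind, errors)[order(do.call(rbind, errors)$row), , drop = FALSE]
  } else {
    data.frame(row = integer(), message = character())
  }
  if (nrow(row_errors)) {
    warning(sum(bad), " row(s) rejected during variant-table validation; ",
            "see attr(, 'row_errors')")
  }
  out <- dt[!bad]
  out[, pos := as.integer(pos)]
  data.table::setattr(out, "row_errors", row_errors)
  out
}

#' Write a variant table
#'
#' Serializes a variant table to TSV with the package's missing-value
#' convention (`NA` written as `"."`), so that [read_variant_table()]
#' round-trips it field for field.
#'
#' @param variants A variant `data.table` / `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  data.table::fwrite(data.table::as.data.table(variants), path, sep = "\t",
                     na = ".", quote = FALSE)
  invisible(path)
}
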