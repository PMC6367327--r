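test_that("variant tables round-trip through write and read", {
  dt <- toy_variant_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(dt, path)
  back <- read_variant_table(path)
  expect_equal(nrow(back), 3L)
  for (col in names(dt)) expect_equal(back[[col]], dt[[col]], info = col)
  expect_equal(nrow(attr(back, "row_errors")), 0L)
})

test_that("validation rejects bad rows with index and reason, keeps the rest", {
  dt <- toy_variant_table()
  dt$rank_SIFT[2] <- 1.2                       # rank score out of [0, 1]
  dt$alt[3] <- "AT"                            # malformed allele
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(dt, path)
  expect_warning(back <- read_variant_table(path), "rejected")
  errs <- attr(back, "row_errors")
  expect_setequal(errs$row, c(2L, 3L))
  expect_true(any(grepl("rank score outside", errs$message)))
  expect_true(any(grepl("malformed alt", errs$message)))
  expect_equal(nrow(back), 1L)
})

test_that("missing values encoded as '.' become NA, missing columns abort", {
  dt <- toy_variant_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(dt, path)
  back <- read_variant_table(path)
  expect_true(is.na(back$rank_CADD[3]))        # written as "."
  expect_true(is.na(back$clinvar[3]))

  dt2 <- toy_variant_table()
  dt2$clinvar <- NULL
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(dt2, path2)
  expect_error(read_variant_table(path2), "mandatory column")
})

test_that("1000G-style lowercase ancestral calls map to low confidence", {
  dt <- toy_variant_table()
  dt$ancestral_confidence <- NULL
  dt$ancestral_allele <- c("g", "A", "G")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(dt, path)
  back <- read_variant_table(path)
  expect_equal(back$ancestral_allele, c("G", "A", "G"))
  expect_equal(back$ancestral_confidence, c("low", "high", "high"))
})

test_that("site classification follows the four-group evidence rule", {
  expect_equal(classify_site("Pathogenic"), "pathogenic")
  expect_equal(classify_site(c("Benign", "Pathogenic")), "both")
  expect_equal(classify_site(character(0)), "other")
  expect_equal(classify_site(c("Likely benign", "Benign")), "benign")
  expect_warning(out <- classify_site(c("risk factor")), "not in term_map")
  expect_equal(out, "other")
})

test_that("site classification is total, exclusive and permutation-invariant", {
  groups <- c("pathogenic", "benign", "both", "other")
  terms_pool <- c(names(default_term_map()), NA_character_)
  set.seed(99)
  for (i in 1:50) {
    terms <- sample(terms_pool, sample(0:5, 1), replace = TRUE)
    g <- classify_site(terms)
    expect_true(g %in% groups)
    expect_equal(classify_site(rev(terms)), g)
    expect_equal(classify_site(sample(terms)), g)
  }
})

test_that("multi-allelic sites pool evidence across alleles", {
  dt <- toy_variant_table()      # two alleles at chr1:100 (Pathogenic, Benign)
  sites <- classify_sites(dt)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites[sites$chrom == "chr1" & sites$pos == 100, ]$site_group, "both")
  expect_true(sites[sites$chrom == "chr1", ]$is_dm)
  ann <- annotate_site_groups(dt)
  expect_equal(ann$site_group[ann$pos == 100], rep("both", 2))
})

test_that("tool calls use strict > on the cutoff and propagate missing", {
  expect_equal(call_tool(0.51, "CADD"), "pathogenic")
  expect_equal(call_tool(0.5, "DANN"), "benign")
  expect_true(is.na(call_tool(NA_real_, "SIFT")))
  expect_error(call_tool(0.7, "NotATool"), "unknown tool")
  # monotonicity: raising a score never flips pathogenic -> benign
  scores <- sort(runif(50))
  calls <- call_tool(scores, "SIFT")
  first_path <- match("pathogenic", calls)
  if (!is.na(first_path)) {
    expect_true(all(calls[first_path:length(calls)] == "pathogenic"))
  }
  # per-tool override respected
  expect_equal(call_tool(0.45, "SIFT", default_thresholds(SIFT = 0.4)),
               "pathogenic")
})

test_that("back mutations require alt = ancestral != ref at high confidence", {
  fx <- data.table::data.table(
    chrom = "chr1", pos = 1:5 * 10L,
    ref = c("G", "A", "G", "G", "C"),
    alt = c("A", "G", "A", "A", "T"),
    gene = "G1", clinvar = NA_character_, hgmd_class = "none",
    ancestral_allele = c("A", "A", "A", "G", NA),
    ancestral_confidence = c("high", "high", "low", "high", NA))
  expect_equal(flag_back_mutation(fx),
               c(TRUE,    # alt restores high-confidence ancestral
                 FALSE,   # derived-direction change (ref = ancestral)
                 FALSE,   # low-confidence call rejected by default
                 FALSE,   # ancestral equals ref, alt moves away
                 FALSE))  # no ancestral call
  expect_equal(flag_back_mutation(fx, require_high_confidence = FALSE)[3], TRUE)
})
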