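# Chromatin-state overlap: the half-open/1-based conversion is the classic
# off-by-one site, so boundary positions are checked against a brute-force
# linear interval scan.

# Oracle: is 1-based position p covered by a 0-based half-open [start, end)
# interval of the given state in this epigenome's track?
oracle_in_state <- function(tracks, epi, chrom, p, states) {
  tr <- tracks[tracks$epigenome == epi & tracks$chrom == chrom &
                 tracks$state %in% states, ]
  any(tr$start <= p - 1 & p - 1 < tr$end)
}

oracle_fraction <- function(sites, tracks, states) {
  epis <- unique(tracks$epigenome)
  vapply(seq_len(nrow(sites)), function(i) {
    mean(vapply(epis, function(e) {
      oracle_in_state(tracks, e, sites$chrom[i], sites$pos[i], states)
    }, logical(1)))
  }, numeric(1))
}

test_that("state fractions count covering epigenomes over all tracks", {
  n_epi <- 127
  tracks <- data.table::data.table(
    epigenome = sprintf("E%03d", 1:n_epi), chrom = "chr1",
    start = 99L, end = 101L, state = "Quies")
  tracks$state[1:25] <- "ReprPC"
  site <- data.frame(chrom = "chr1", pos = 100L)
  expect_equal(state_fraction(site, tracks, "ReprPC"), 25 / 127)
  expect_equal(state_fraction(site, tracks, c("ReprPC", "Quies")), 1)
  # a site on a chromosome absent from every track is in-state nowhere
  expect_equal(state_fraction(data.frame(chrom = "chrX", pos = 100L),
                              tracks, "ReprPC"), 0)
})

test_that("boundary positions match the brute-force interval scan", {
  tracks <- data.table::data.table(
    epigenome = rep(c("E001", "E002", "E003"), each = 2),
    chrom = "chr1",
    start = c(100L, 300L, 100L, 250L, 90L, 400L),
    end = c(200L, 350L, 150L, 320L, 110L, 500L),
    state = c("ReprPC", "ReprPCWk", "ReprPC", "ReprPC", "ReprPCWk", "ReprPC"))
  # positions chosen at starts, ends, and one-off each side
  pos <- c(100L, 101L, 150L, 151L, 200L, 201L, 90L, 91L, 110L, 111L,
           299L, 300L, 301L, 320L, 321L, 350L, 500L, 501L)
  sites <- data.frame(chrom = "chr1", pos = pos)
  for (states in list("ReprPC", "ReprPCWk", c("ReprPC", "ReprPCWk"))) {
    expect_equal(state_fraction(sites, tracks, states),
                 oracle_fraction(sites, tracks, states),
                 info = paste(states, collapse = "+"))
  }
  # explicit off-by-one checks: pos = start is NOT covered, pos = start + 1
  # and pos = end are covered
  one <- tracks[1, ]  # [100, 200) in E001
  p_start <- state_fraction(data.frame(chrom = "chr1", pos = 100L), one, "ReprPC")
  p_in <- state_fraction(data.frame(chrom = "chr1", pos = 101L), one, "ReprPC")
  p_end <- state_fraction(data.frame(chrom = "chr1", pos = 200L), one, "ReprPC")
  p_past <- state_fraction(data.frame(chrom = "chr1", pos = 201L), one, "ReprPC")
  expect_equal(c(p_start, p_in, p_end, p_past), c(0, 1, 1, 0))
})

test_that("a mutually exclusive state vocabulary sums to 1 at covered sites", {
  set.seed(44)
  states <- c("ReprPC", "ReprPCWk", "Quies")
  tracks <- data.table::rbindlist(lapply(1:10, function(e) {
    data.table::data.table(epigenome = sprintf("E%03d", e), chrom = "chr1",
                           start = 0L, end = 1000L, state = sample(states, 1))
  }))
  site <- data.frame(chrom = "chr1", pos = 500L)
  total <- sum(vapply(states, function(s) state_fraction(site, tracks, s),
                      numeric(1)))
  expect_equal(total, 1)
})

test_that("the covered-epigenome denominator restricts per chromosome", {
  tracks <- data.table::data.table(
    epigenome = c("E001", "E002", "E003", "E003"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0L, 0L, 0L, 500L), end = c(100L, 100L, 100L, 600L),
    state = c("ReprPC", "Quies", "ReprPC", "ReprPC"))
  site <- data.frame(chrom = "chr1", pos = 50L)
  expect_equal(state_fraction(site, tracks, "ReprPC"), 1 / 3)
  expect_equal(state_fraction(site, tracks, "ReprPC", denominator = "covered"),
               1 / 2)
})

test_that("track reading handles per-epigenome BED and concatenated tables", {
  dir <- withr::local_tempdir()
  bed1 <- file.path(dir, "E001.bed")
  writeLines(c("chr1\t100\t200\tReprPC", "chr1\t300\t400\tQuies"), bed1)
  bed2 <- file.path(dir, "E002.bed")
  writeLines("chr1\t150\t250\tReprPCWk", bed2)
  tr <- read_state_tracks(c(bed1, bed2))
  expect_equal(nrow(tr), 3L)
  expect_setequal(unique(tr$epigenome), c("E001", "E002"))
  concat <- file.path(dir, "all.tsv")
  data.table::fwrite(tr, concat, sep = "\t")
  tr2 <- read_state_tracks(concat)
  expect_equal(tr2, tr)
})

test_that("FN-vs-TP comparisons find planted upshifts and flag empty groups", {
  frac <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  calls <- cbind(SIFT = c(rep("pathogenic", 3), rep("benign", 3)))
  labels <- rep("pathogenic", 6)
  res <- fn_tp_state_comparison(frac, calls, labels)
  expect_equal(res$n_fn, 3L)
  expect_equal(res$n_tp, 3L)
  expect_equal(res$p, 0.1, tolerance = 1e-9)  # exact enumeration at 3 vs 3
  expect_gt(res$median_fn, res$median_tp)
  # identical distributions: p near 1
  same <- fn_tp_state_comparison(rep(0.4, 6), calls, labels)
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_warning(
    empty <- fn_tp_state_comparison(frac, cbind(SIFT = rep("pathogenic", 6)),
                                    labels),
    "empty FN or TP")
  expect_true(is.na(empty$p))
})
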