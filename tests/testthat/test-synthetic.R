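test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(seed = 99, n_genes = 40, n_epigenomes = 10)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$tracks, b2$tracks)
  expect_identical(b1$expression, b2$expression)
  expect_identical(generate_quartets(cfg), generate_quartets(cfg))
  # byte-identical bundles on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(b1, d1); write_cohort(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  b3 <- generate_cohort(cohort_config(seed = 100, n_genes = 40,
                                      n_epigenomes = 10))
  expect_false(identical(b1$variants, b3$variants))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, site_fractions = c(pathogenic = 0.5,
                                                          benign = 0.5)),
               "site_fractions")
  expect_error(cohort_config(seed = 1, dm_rate = 1.5), "dm_rate")
  expect_error(cohort_config(seed = 1, overreliance_tools = "NotATool"),
               "overreliance_tools")
  expect_error(cohort_config(seed = 1, overreliance_weight = 1),
               "overreliance_weight")
})

test_that("generated files round-trip through the package readers cleanly", {
  bundle <- small_cohort(seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(bundle, dir)
  expect_no_warning(v <- read_variant_table(file.path(dir, "variants.tsv")))
  expect_equal(nrow(v), nrow(bundle$variants))
  expect_equal(v$pos, bundle$variants$pos)
  expect_equal(v$rank_SIFT, bundle$variants$rank_SIFT, tolerance = 1e-12)
  tr <- read_state_tracks(file.path(dir, "state_tracks.tsv"))
  expect_equal(nrow(tr), nrow(bundle$tracks))
  expect_no_warning(classify_sites(v))  # only mapped clinical terms emitted
})

test_that("emitted values respect their domains and configured proportions", {
  cfg <- cohort_config(seed = 31, n_genes = 300, effects = "null",
                       n_epigenomes = 10)
  bundle <- generate_cohort(cfg)
  v <- bundle$variants
  for (tool in prediction_tools()) {
    s <- v[[paste0("rank_", tool)]]
    expect_true(all(is.na(s) | (s >= 0 & s <= 1)), info = tool)
  }
  for (col in paste0("phastcons_", c("vertebrate", "mammal", "primate"))) {
    expect_true(all(v[[col]] >= 0 & v[[col]] <= 1), info = col)
  }
  expect_true(all(bundle$tracks$start < bundle$tracks$end))
  # truth-table class proportions within binomial sampling error (4 sigma)
  tv <- bundle$truth_variants
  n <- nrow(tv)
  for (cls in names(cfg$site_fractions)) {
    f <- cfg$site_fractions[[cls]]
    tol <- 4 * sqrt(f * (1 - f) / n)
    expect_lt(abs(mean(tv$class == cls) - f), tol + 1e-9, label = cls)
  }
  # truth classes agree with the site classification of the emitted terms
  ann <- annotate_site_groups(v)
  expect_equal(ann$site_group, tv$class)
})

test_that("quartet generator separates location and dispersion effects", {
  # location only: the maximum shifts while CV stays null
  cfg_loc <- cohort_config(seed = 51, quartet_dispersion_effect = 0,
                           n_quartet_sites = 600)
  q <- generate_quartets(cfg_loc)
  qs <- quartet_stats(q[q$tool == "SIFT", ])
  pa <- qs[qs$group == "pathogenic", ]; be <- qs[qs$group == "benign", ]
  expect_lt(rank_sum_test(pa$s_max, be$s_max)$p, 0.05)
  expect_gt(rank_sum_test(pa$cv, be$cv)$p, 0.05)
  # dispersion effect lowers the pathogenic CV
  cfg_full <- cohort_config(seed = 51, n_quartet_sites = 600)
  q2 <- generate_quartets(cfg_full)
  qs2 <- quartet_stats(q2[q2$tool == "SIFT", ])
  pa2 <- qs2[qs2$group == "pathogenic", ]; be2 <- qs2[qs2$group == "benign", ]
  expect_lt(rank_sum_test(pa2$cv, be2$cv)$p, 0.05)
  expect_lt(median(pa2$cv), median(be2$cv))
})

test_that("planted effects are recovered and absent effects stay silent", {
  # scaled-down battery for routine testing; the full 20-replicate battery
  # runs in the acceptance suite
  res <- recovery_rates(seed = 77, n_replicates = 3, n_genes = 250)
  expect_equal(unname(res$rates["quartet_max"]), 1)
  expect_equal(unname(res$rates["quartet_cv"]), 1)
  expect_equal(unname(res$rates["fp_enrichment_planted"]), 1)
  expect_equal(unname(res$rates["polycomb_fn"]), 1)
  expect_lte(unname(res$rates["fp_enrichment_null"]), 0.2)
})
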