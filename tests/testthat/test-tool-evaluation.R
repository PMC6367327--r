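test_that("confusion counts classify every labeled variant exactly once", {
  calls <- c(rep("pathogenic", 8), rep("benign", 2),      # 10 pathogenic
             rep("benign", 85), rep("pathogenic", 5))     # 90 benign
  labels <- c(rep("pathogenic", 10), rep("benign", 90))
  ct <- confusion(calls, labels)
  expect_equal(ct[c("tp", "fn", "tn", "fp", "unclassified")],
               list(tp = 8L, fn = 2L, tn = 85L, fp = 5L, unclassified = 0L))
  # degenerate inputs
  all_missing <- confusion(rep(NA_character_, 7), rep("pathogenic", 7))
  expect_equal(all_missing$unclassified, 7L)
  expect_equal(all_missing$tp + all_missing$fp + all_missing$tn + all_missing$fn, 0L)
  all_benign <- confusion(rep("benign", 4), rep("benign", 4))
  expect_equal(all_benign$tn, 4L)
  empty <- confusion(character(0), character(0))
  expect_equal(empty$tp + empty$fp + empty$tn + empty$fn + empty$unclassified, 0L)
  # conservation of counts on random inputs
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    cl <- sample(c("pathogenic", "benign", NA), n, replace = TRUE)
    lb <- sample(c("pathogenic", "benign"), n, replace = TRUE)
    cc <- confusion(cl, lb)
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn + cc$unclassified, n)
  }
})

test_that("metrics penalize no-calls on sensitivity and handle empty tables", {
  met <- confusion_metrics(confusion(
    c(rep("pathogenic", 8), rep("benign", 2), rep("benign", 85), rep("pathogenic", 5)),
    c(rep("pathogenic", 10), rep("benign", 90))))
  expect_equal(met[["sensitivity"]], 0.8)
  expect_equal(met[["specificity"]], 85 / 90)
  expect_equal(met[["accuracy"]], 0.93)
  # a pathogenic no-call counts against sensitivity: tp=3, fn=1, unclassified=1
  met2 <- confusion_metrics(confusion(
    c("pathogenic", "pathogenic", "pathogenic", "benign", NA),
    rep("pathogenic", 5)))
  expect_equal(met2[["sensitivity"]], 0.6)
  met0 <- confusion_metrics(confusion(character(0), character(0)))
  expect_true(all(is.na(met0)))
})

test_that("pairwise agreement is the co-called identical fraction", {
  a <- c(rep("pathogenic", 5), rep("benign", 5))
  m <- pairwise_agreement(cbind(t1 = a, t2 = a))
  expect_equal(m["t1", "t2"], 1)
  flip <- ifelse(a == "pathogenic", "benign", "pathogenic")
  expect_equal(pairwise_agreement(cbind(t1 = a, t2 = flip))["t1", "t2"], 0)
  b <- a; b[1:3] <- ifelse(a[1:3] == "pathogenic", "benign", "pathogenic")
  expect_equal(pairwise_agreement(cbind(t1 = a, t2 = b))["t1", "t2"], 0.7)
  # missing calls shrink the co-called denominator; no co-calls -> NA
  c2 <- a; c2[1:5] <- NA
  d2 <- a; d2[6:10] <- NA
  m2 <- pairwise_agreement(cbind(t1 = c2, t2 = d2))
  expect_true(is.na(m2["t1", "t2"]))
  expect_equal(diag(m2), c(t1 = 1, t2 = 1))
  # symmetry on random matrices
  set.seed(8)
  cm <- matrix(sample(c("pathogenic", "benign", NA), 60, TRUE), ncol = 3,
               dimnames = list(NULL, c("x", "y", "z")))
  mm <- pairwise_agreement(cm)
  expect_equal(mm, t(mm))
})

test_that("all-agree combination calls only on unanimity", {
  calls <- cbind(SIFT = c("pathogenic", "pathogenic", "benign", NA),
                 CADD = c("pathogenic", "benign", "benign", "pathogenic"))
  expect_equal(combine_calls("SIFT", calls), calls[, "SIFT"])
  combined <- combine_calls(c("SIFT", "CADD"), calls)
  expect_equal(combined, c("pathogenic", NA, "benign", NA))
  three <- cbind(a = rep("benign", 2), b = rep("benign", 2), c = rep("benign", 2))
  expect_equal(combine_calls(c("a", "b", "c"), three), rep("benign", 2))
  expect_error(combine_calls(character(0), calls), "non-empty")
})

test_that("the combination scan enumerates all subsets and matches brute force", {
  set.seed(21)
  n <- 20
  tools <- c("SIFT", "CADD", "DANN")
  calls <- matrix(sample(c("pathogenic", "benign", NA), n * 3, TRUE,
                         prob = c(0.45, 0.45, 0.1)),
                  ncol = 3, dimnames = list(NULL, tools))
  labels <- sample(c("pathogenic", "benign"), n, TRUE)
  scan <- scan_combinations(calls, labels)
  expect_equal(nrow(scan), 7L)
  expect_equal(anyDuplicated(scan$subset), 0L)
  # brute-force oracle: per-variant unanimity by explicit loop
  for (i in seq_len(nrow(scan))) {
    subset <- strsplit(scan$subset[i], ";", fixed = TRUE)[[1]]
    tp <- fp <- tn <- fn <- 0L
    for (v in seq_len(n)) {
      vc <- calls[v, subset]
      verdict <- if (anyNA(vc)) NA
        else if (all(vc == "pathogenic")) "pathogenic"
        else if (all(vc == "benign")) "benign" else NA
      if (is.na(verdict)) next
      if (verdict == "pathogenic" && labels[v] == "pathogenic") tp <- tp + 1L
      if (verdict == "pathogenic" && labels[v] == "benign") fp <- fp + 1L
      if (verdict == "benign" && labels[v] == "benign") tn <- tn + 1L
      if (verdict == "benign" && labels[v] == "pathogenic") fn <- fn + 1L
    }
    expect_equal(unlist(scan[i, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn), info = scan$subset[i])
    expect_equal(scan$unclassified[i], n - tp - fp - tn - fn)
  }
  # singleton subsets equal the tool's own evaluation
  single <- scan[scan$subset == "SIFT", ]
  own <- confusion_metrics(confusion(calls[, "SIFT"], labels))
  expect_equal(single$sensitivity, own[["sensitivity"]])
  expect_equal(single$specificity, own[["specificity"]])
  expect_error(scan_combinations(calls, labels, tools = character(0)))
})

test_that("per-size summaries match hand computation on a two-tool toy", {
  calls <- cbind(a = c("pathogenic", "benign", "pathogenic", "benign"),
                 b = c("pathogenic", "pathogenic", "benign", "benign"))
  labels <- c("pathogenic", "pathogenic", "benign", "benign")
  scan <- scan_combinations(calls, labels)
  bs <- summarize_by_size(scan)
  expect_equal(nrow(bs), 2L)
  singles <- scan[scan$size == 1, ]
  expect_equal(bs$mean_sensitivity[1], mean(singles$sensitivity))
  expect_equal(bs$max_accuracy[1], max(singles$accuracy))
  # identical tools: metrics constant across sizes
  same <- cbind(a = calls[, "a"], b = calls[, "a"])
  scan2 <- scan_combinations(same, labels)
  expect_equal(length(unique(scan2$sensitivity)), 1L)
  expect_equal(length(unique(scan2$specificity)), 1L)
})

test_that("nested subsets shrink the called set monotonically", {
  cohort <- small_cohort(seed = 5)
  v <- suppressWarnings(annotate_site_groups(cohort$variants))
  labels <- truth_labels(v)
  keep <- !is.na(labels)
  calls <- call_tools(v)[keep, , drop = FALSE]
  labels <- labels[keep]
  set.seed(14)
  for (chain in 1:10) {
    order <- sample(colnames(calls))
    prev_called <- NULL
    prev_sens <- Inf; prev_spec <- -Inf
    for (k in seq_along(order)) {
      combined <- combine_calls(order[1:k], calls)
      called <- !is.na(combined)
      if (!is.null(prev_called)) expect_true(all(called <= prev_called))
      met <- confusion_metrics(confusion(combined, labels))
      expect_lte(met[["sensitivity"]], prev_sens + 1e-12)
      expect_gte(met[["specificity"]], prev_spec - 1e-12)
      prev_called <- called
      prev_sens <- met[["sensitivity"]]; prev_spec <- met[["specificity"]]
    }
  }
})
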