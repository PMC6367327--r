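# Four-allele score statistics at non-degenerate sites.
#
# At a non-degenerate site every nucleotide substitution changes the amino
# acid, so each of the four nucleotides A/C/G/T carries a prediction score.
# Predictors only score the three alternative alleles; the score of the
# reference nucleotide is a convention (default 0: no predicted
# deleteriousness for no change). The per-site statistics are the maximum of
# the four scores and their coefficient of variation CV = sigma/mu with
# mu = sum(S_i)/4 and sigma the standard deviation with divisor 3. A low CV
# marks a site intolerant to any change rather than to a particular change.

#' Assemble a four-allele score quartet
#'
#' Builds the (A, C, G, T) score quartet of a non-degenerate site from the
#' three alternative-allele rank scores and a reference-allele convention:
#' `"zero"` assigns the reference nucleotide a score of 0, `"mean-of-alts"`
#' the mean of the three alternative scores, and `"exclude-and-rescale"`
#' leaves it missing so the statistics are computed over the three
#' alternatives only (with divisor 2 for the standard deviation).
#'
#' @param alt_scores Named numeric vector of the three alternative
#'   nucleotides' rank scores (names in A/C/G/T, all present, in \[0, 1\]).
#' @param ref The reference nucleotide.
#' @param ref_convention One of `"zero"`, `"mean-of-alts"`,
#'   `"exclude-and-rescale"`.
#' @return Named numeric vector of length 4 over A, C, G, T (`NA` at the
#'   reference position under `"exclude-and-rescale"`).
#' @export
#' @examples
#' assemble_quartet(c(C = 0.8, G = 0.9, T = 0.7), "A")
assemble_quartet <- function(alt_scores, ref,
                             ref_convention = c("zero", "mean-of-alts",
                                                "exclude-and-rescale")) {
  ref_convention <- match.arg(ref_convention)
  if (!ref %in% NUCLEOTIDES) stop("ref must be one of A, C, G, T")
  alts <- setdiff(NUCLEOTIDES, ref)
  if (!setequal(names(alt_scores), alts)) {
    stop("alt_scores must name exactly the three non-reference nucleotides")
  }
  if (anyNA(alt_scores)) stop("all three alternative scores must be present")
  if (any(alt_scores < 0 | alt_scores > 1)) stop("rank scores must lie in [0, 1]")
  q <- setNames(rep(NA_real_, 4), NUCLEOTIDES)
  q[alts] <- alt_scores[alts]
  q[ref] <- switch(ref_convention,
                   "zero" = 0,
                   "mean-of-alts" = mean(alt_scores),
                   "exclude-and-rescale" = NA_real_)
  q
}

#' Maximum of a score quartet
#'
#' @param q Quartet from [assemble_quartet()].
#' @return The maximum score over the (present) nucleotides.
#' @export
quartet_max <- function(q) max(q, na.rm = TRUE)

#' Coefficient of variation of a score quartet
#'
#' CV = sigma/mu with mu the mean of the four scores and sigma the standard
#' deviation with divisor 3 (n - 1 over the present scores in general).
#' Undefined (`NA`) when mu = 0.
#'
#' @param q Quartet from [assemble_quartet()].
#' @return Non-negative CV, or `NA` when the mean is 0.
#' @export
#' @examples
#' quartet_cv(c(A = 0.2, C = 0.4, G = 0.6, T = 0.8))  # ~0.5164
quartet_cv <- function(q) {
  q <- q[!is.na(q)]
  n <- length(q)
  if (n < 2) return(NA_real_)
  mu <- sum(q) / n
  if (mu == 0) return(NA_real_)
  sigma <- sqrt(sum((q - mu)^2) / (n - 1))
  sigma / mu
}

#' Per-site quartet statistics for a quartet table
#'
#' Vectorized maximum and CV over a long-format quartet table as emitted by
#' [generate_quartets()]: one row per site and tool with columns `ref` and
#' `score_A` ... `score_T` (the reference nucleotide's entry missing). The
#' reference score is filled per `ref_convention` before the statistics are
#' computed; rows with fewer than three alternative scores are dropped and
#' counted in the attached coverage attribute.
#'
#' @param quartets A `data.table` with columns `ref`, `score_A`, `score_C`,
#'   `score_G`, `score_T` (plus any identifying columns, carried through).
#' @param ref_convention See [assemble_quartet()].
#' @return The table with columns `s_max` and `cv` added; attribute
#'   `"n_skipped"` counts rows dropped for incomplete alternative scores.
#' @export
quartet_stats <- function(quartets, ref_convention = c("zero", "mean-of-alts",
                                                       "exclude-and-rescale")) {
  ref_convention <- match.arg(ref_convention)
  dt <- data.table::as.data.table(quartets)
  score_cols <- paste0("score_", NUCLEOTIDES)
  stopifnot(all(c("ref", score_cols) %in% names(dt)))
  m <- as.matrix(dt[, ..score_cols])
  colnames(m) <- NUCLEOTIDES
  ridx <- cbind(seq_len(nrow(m)), match(dt$ref, NUCLEOTIDES))
  m[ridx] <- NA_real_  # ignore any supplied reference score; convention decides
  n_alt <- rowSums(!is.na(m))
  complete <- n_alt == 3
  n_skipped <- sum(!complete)
  dt <- dt[complete]
  m <- m[complete, , drop = FALSE]
  ridx <- ridx[complete, , drop = FALSE]
  alt_mean <- rowSums(m, na.rm = TRUE) / 3
  m[ridx] <- switch(ref_convention,
                    "zero" = 0,
                    "mean-of-alts" = alt_mean,
                    "exclude-and-rescale" = NA_real_)
  n_present <- rowSums(!is.na(m))
  mu <- rowSums(m, na.rm = TRUE) / n_present
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  sigma <- sqrt(ss / (n_present - 1))
  dt[, s_max := apply(m, 1, max, na.rm = TRUE)]
  dt[, cv := data.table::fifelse(mu == 0, NA_real_, sigma / mu)]
  data.table::setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Pairwise group comparison of a per-site statistic
#'
#' Two-sided Wilcoxon rank-sum tests ([rank_sum_test()]) between every pair
#' of groups of a per-site statistic — typically the quartet maximum or CV
#' across the site groups (pathogenic, benign, both, other) and the HGMD DM
#' class. Pairs involving a group with no values are reported missing.
#'
#' @param values Numeric vector of the statistic.
#' @param groups Character/factor vector of group labels, same length.
#' @return A `data.table` with one row per unordered group pair: `group_a`,
#'   `group_b`, `n_a`, `n_b`, `median_a`, `median_b`, `p`.
#' @export
compare_score_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  levels <- unique(groups)
  if (length(levels) < 2) stop("need at least two groups with values")
  pairs <- utils::combn(levels, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    res <- if (length(a) && length(b)) rank_sum_test(a, b) else list(p = NA_real_)
    data.table::data.table(
      group_a = pairs[1, i], group_b = pairs[2, i],
      n_a = length(a), n_b = length(b),
      median_a = if (length(a)) stats::median(a) else NA_real_,
      median_b = if (length(b)) stats::median(b) else NA_real_,
      p = res$p)
  })
  data.table::rbindlist(rows)
}

#' Correlation between a site statistic and conservation
#'
#' Pearson product-moment correlation between a per-site statistic (quartet
#' maximum or CV) and a per-site conservation score, over complete pairs.
#' Reported missing with fewer than 3 complete pairs.
#'
#' @param stat Numeric vector of the per-site statistic.
#' @param conservation Numeric vector of conservation scores, same length.
#' @return List with `estimate` (correlation coefficient), `p`, `n`.
#' @export
score_conservation_correlation <- function(stat, conservation) {
  stopifnot(length(stat) == length(conservation))
  ok <- stats::complete.cases(stat, conservation)
  if (sum(ok) < 3) return(list(estimate = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(stat[ok], conservation[ok], method = "pearson")
  list(estimate = unname(ct$estimate), p = unname(ct$p.value), n = sum(ok))
}
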