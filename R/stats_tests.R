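# Statistical engines shared by the comparison stages.
#
# All group comparisons in the package funnel through three tests:
# Pearson's chi-squared on a 2x2 proportion table (conservation enrichment),
# the two-sided Wilcoxon rank-sum test (score and chromatin-state
# comparisons) and the two-sample Kolmogorov-Smirnov test (gene-level ECDF
# comparisons). Small samples are handled exactly; large ones by the usual
# asymptotics.

#' Pearson chi-squared test of two proportions
#'
#' Tests whether the proportion of "successes" in a group differs from that
#' in a background set, via Pearson's chi-squared statistic on the 2x2 table
#' of counts, without Yates continuity correction. When the two proportions
#' are equal the statistic is exactly 0 and p exactly 1.
#'
#' @param group_count,group_total Successes and size of the group.
#' @param background_count,background_total Successes and size of the
#'   background (the background may contain the group).
#' @return List with `chi2`, `p`, `proportion_group`,
#'   `proportion_background`.
#' @export
#' @examples
#' proportion_chi2(30, 100, 300, 1000)$p   # equal proportions -> 1
proportion_chi2 <- function(group_count, group_total,
                            background_count, background_total) {
  stopifnot(group_count >= 0, background_count >= 0,
            group_count <= group_total, background_count <= background_total)
  if (group_total == 0 || background_total == 0) {
    return(list(chi2 = NA_real_, p = NA_real_,
                proportion_group = NA_real_, proportion_background = NA_real_))
  }
  tab <- rbind(c(group_count, group_total - group_count),
               c(background_count, background_total - background_count))
  if (any(colSums(tab) == 0)) {
    # Degenerate margin (all high or all low): no departure measurable.
    chi2 <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  list(chi2 = chi2, p = p,
       proportion_group = group_count / group_total,
       proportion_background = background_count / background_total)
}

# Exact two-sided rank-sum p-value by enumeration of all splits of the
# combined sample; valid with ties. The Mann-Whitney U distribution is
# symmetric about nx*ny/2, so the two-sided p is the probability of a
# departure from the centre at least as large as observed.
rank_sum_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  centre <- nx * ny / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
  eps <- 1e-9
  mean(abs(u_all - centre) >= abs(u_obs - centre) - eps)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum test with a small-sample exact path:
#' without ties and below 50 observations per group the exact distribution
#' is used; with ties, complete enumeration of all splits is used while the
#' number of splits is manageable (<= `enum_limit`); otherwise the normal
#' approximation with tie correction (no continuity correction) applies.
#'
#' @param x,y Numeric samples.
#' @param enum_limit Maximum number of group assignments to enumerate for
#'   the tied-exact path (default 2e5).
#' @return List with `u` (Mann-Whitney U for `x`), `p` (two-sided) and
#'   `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p   # 0.1, fully separated n=3 vs 3
rank_sum_test <- function(x, y, enum_limit = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) return(list(u = NA_real_, p = NA_real_, method = "empty"))
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && nx < 50 && ny < 50) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else if (choose(nx + ny, nx) <= enum_limit) {
    p <- rank_sum_exact_enum(x, y)
    method <- "exact-enumeration"
  } else {
    n <- nx + ny
    tie_sizes <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (u - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal-tie-corrected"
  }
  list(u = unname(u), p = min(1, unname(p)), method = method)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test of the empirical cumulative distributions of
#' two groups. The exact p-value is computed when the combined sample size
#' is below 35 and the data are tie-free; otherwise the asymptotic
#' distribution is used.
#'
#' @param group_a,group_b Numeric samples.
#' @return List with `d` (the KS statistic), `p`, `n_a`, `n_b`.
#' @export
#' @examples
#' ecdf_compare(1:3, 10:12)$d   # disjoint supports -> 1
ecdf_compare <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0) {
    return(list(d = NA_real_, p = NA_real_,
                n_a = length(group_a), n_b = length(group_b)))
  }
  exact <- (length(group_a) + length(group_b)) < 35 &&
    !anyDuplicated(c(group_a, group_b))
  kt <- suppressWarnings(stats::ks.test(group_a, group_b, exact = exact))
  list(d = unname(kt$statistic), p = unname(kt$p.value),
       n_a = length(group_a), n_b = length(group_b))
}
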