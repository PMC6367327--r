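# Chromatin-state overlap of variant sites across epigenomes.
#
# State tracks follow the chromHMM convention: per-epigenome genomic
# intervals in 0-based half-open [start, end) coordinates labeled with state
# mnemonics, among them ReprPC ("repressed PolyComb") and ReprPCWk ("weak
# repressed PolyComb"). Variant positions are 1-based, so a position p is
# covered by an interval iff start <= p - 1 < end. That conversion lives in
# one place (site_track_overlap) and is exercised at interval boundaries by
# the test suite.

#' Read chromatin-state tracks from BED
#'
#' Reads one BED file per epigenome (columns chrom, start, end, state) or a
#' single concatenated table with an explicit `epigenome` column, into the
#' track table used by [state_fraction()].
#'
#' @param paths Character vector of BED file paths. For per-epigenome files
#'   the names of the vector (or the file base names) become the epigenome
#'   ids; a file whose header contains an `epigenome` column is treated as
#'   concatenated.
#' @return A `data.table` with columns `epigenome`, `chrom`, `start`, `end`
#'   (0-based half-open), `state`.
#' @export
read_state_tracks <- function(paths) {
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.bed$", "", basename(paths))
  rows <- lapply(seq_along(paths), function(i) {
    dt <- data.table::fread(paths[i], sep = "\t", showProgress = FALSE)
    if ("epigenome" %in% names(dt)) {
      dt <- dt[, .(epigenome = as.character(epigenome), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   state = as.character(state))]
    } else {
      if (ncol(dt) < 4) stop("BED track needs >= 4 columns (chrom, start, end, state): ",
                             paths[i])
      data.table::setnames(dt, 1:4, c("chrom", "start", "end", "state"))
      dt <- dt[, .(epigenome = ids[i], chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   state = as.character(state))]
    }
    dt
  })
  out <- data.table::rbindlist(rows)
  if (any(out$start >= out$end)) stop("state track has intervals with start >= end")
  out
}

# Internal: (site index, epigenome) pairs for sites covered by an interval
# of any of the given states. Central 1-based/half-open conversion.
site_track_overlap <- function(sites, tracks, states) {
  tr <- tracks[tracks$state %in% states, ]
  if (!nrow(tr)) {
    return(data.table::data.table(site = integer(), epigenome = character()))
  }
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
  # BED 0-based half-open [start, end) == 1-based closed [start+1, end].
  track_gr <- GenomicRanges::GRanges(
    seqnames = tr$chrom,
    ranges = IRanges::IRanges(start = tr$start + 1L, end = tr$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, track_gr))
  unique(data.table::data.table(
    site = S4Vectors::queryHits(hits),
    epigenome = tr$epigenome[S4Vectors::subjectHits(hits)]))
}

#' Fraction of epigenomes with a site in a chromatin state
#'
#' For each variant site, the fraction of epigenomes whose state track
#' contains an interval of the given state covering the site's position.
#' Passing several states counts an epigenome when the site is in *any* of
#' them (the union event, e.g. repressed or weak repressed PolyComb). By
#' default every epigenome present in `tracks` counts in the denominator,
#' whether or not it has data on the site's chromosome ("percentage of cell
#' types"); `denominator = "covered"` restricts to epigenomes with at least
#' one interval on that chromosome.
#'
#' @param sites A `data.frame` with columns `chrom` and `pos` (1-based).
#' @param tracks Track table from [read_state_tracks()] (or the same
#'   columns built in memory).
#' @param state Character vector of state labels (single state, or several
#'   for the union event).
#' @param denominator `"all"` (default) or `"covered"`.
#' @return Numeric vector of fractions in \[0, 1\], one per site row.
#' @export
state_fraction <- function(sites, tracks, state = "ReprPC",
                           denominator = c("all", "covered")) {
  denominator <- match.arg(denominator)
  sites <- data.table::as.data.table(sites)
  tracks <- data.table::as.data.table(tracks)
  if (!nrow(tracks)) stop("need at least one state track")
  epis <- unique(tracks$epigenome)
  ov <- site_track_overlap(sites, tracks, state)
  counts <- integer(nrow(sites))
  if (nrow(ov)) {
    tab <- ov[, .N, by = site]
    counts[tab$site] <- tab$N
  }
  if (denominator == "all") {
    denom <- rep(length(epis), nrow(sites))
  } else {
    cov <- unique(tracks[, .(epigenome, chrom)])
    per_chrom <- cov[, .(n = length(unique(epigenome))), by = chrom]
    denom <- per_chrom$n[match(sites$chrom, per_chrom$chrom)]
    denom[is.na(denom)] <- 0L
  }
  ifelse(denom > 0, counts / denom, NA_real_)
}

#' PolyComb state fractions for a set of sites
#'
#' Convenience wrapper computing, per site, the epigenome fractions for the
#' repressed PolyComb state, the weak repressed PolyComb state, and their
#' union.
#'
#' @inheritParams state_fraction
#' @return A `data.table` with the site columns plus `frac_ReprPC`,
#'   `frac_ReprPCWk`, `frac_ReprPC_or_Wk`.
#' @export
polycomb_fractions <- function(sites, tracks, denominator = c("all", "covered")) {
  denominator <- match.arg(denominator)
  out <- data.table::as.data.table(sites)
  out[, frac_ReprPC := state_fraction(sites, tracks, "ReprPC", denominator)]
  out[, frac_ReprPCWk := state_fraction(sites, tracks, "ReprPCWk", denominator)]
  out[, frac_ReprPC_or_Wk := state_fraction(sites, tracks,
                                            c("ReprPC", "ReprPCWk"), denominator)]
  out[]
}

#' Compare state fractions between groups of sites
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of site groups on
#' their per-site state fractions — e.g. pathogenic/DM versus benign sites.
#' A thin wrapper over [compare_score_groups()].
#'
#' @param fractions Numeric vector of per-site state fractions.
#' @param groups Group labels, same length.
#' @return A `data.table` of pairwise comparisons (see
#'   [compare_score_groups()]).
#' @export
group_state_comparison <- function(fractions, groups) {
  compare_score_groups(fractions, groups)
}

#' FN-versus-TP state comparison per tool
#'
#' For each tool, restricts to truth-pathogenic variants and compares the
#' state fractions of sites with false-negative predictions (called benign)
#' against sites with true-positive predictions (called pathogenic) by a
#' two-sided Wilcoxon rank-sum test. No-calls are excluded. An empty group
#' yields a missing comparison with a warning.
#'
#' @param fractions Numeric vector of per-site state fractions, one per
#'   variant row.
#' @param calls Call matrix from [call_tools()].
#' @param labels Truth labels; only `"pathogenic"` rows enter.
#' @return A `data.table` with one row per tool: `n_fn`, `n_tp`,
#'   `median_fn`, `median_tp`, `p`.
#' @export
fn_tp_state_comparison <- function(fractions, calls, labels) {
  stopifnot(length(fractions) == nrow(calls), length(labels) == nrow(calls))
  rows <- lapply(colnames(calls), function(tool) {
    path <- !is.na(labels) & labels == "pathogenic"
    fn <- fractions[path & !is.na(calls[, tool]) & calls[, tool] == "benign"]
    tp <- fractions[path & !is.na(calls[, tool]) & calls[, tool] == "pathogenic"]
    fn <- fn[!is.na(fn)]; tp <- tp[!is.na(tp)]
    if (!length(fn) || !length(tp)) {
      warning("empty FN or TP group for tool ", tool, "; comparison missing")
      p <- NA_real_
    } else {
      p <- rank_sum_test(fn, tp)$p
    }
    data.table::data.table(
      tool = tool, n_fn = length(fn), n_tp = length(tp),
      median_fn = if (length(fn)) stats::median(fn) else NA_real_,
      median_tp = if (length(tp)) stats::median(tp) else NA_real_,
      p = p)
  })
  data.table::rbindlist(rows)
}
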