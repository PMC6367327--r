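# Per-tool and combined-tool evaluation against clinical truth labels.
#
# Truth labels are restricted to "pathogenic"/"benign" (sites classified
# "both" or "other" are excluded upstream). A missing call is never dropped:
# it is counted as unclassified, so denominators stay constant across tool
# subsets and a pathogenic variant left uncalled counts against sensitivity.

#' Confusion table of calls against truth labels
#'
#' @param calls Character vector of `"pathogenic"` / `"benign"` / `NA`
#'   (no-call), one per variant.
#' @param labels Character vector of truth labels, `"pathogenic"` or
#'   `"benign"`, same length.
#' @return List of class `confusion_table` with counts `tp`, `fp`, `tn`,
#'   `fn`, `unclassified`, and the label-split no-call counts
#'   `unclassified_pathogenic`, `unclassified_benign`. Cells always sum to
#'   `length(labels)`.
#' @export
#' @examples
#' confusion(c("pathogenic", NA, "benign"),
#'           c("pathogenic", "pathogenic", "benign"))
confusion <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  if (length(labels) && !all(labels %in% c("pathogenic", "benign"))) {
    stop("labels must be 'pathogenic' or 'benign'; exclude 'both'/'other' sites upstream")
  }
  lab_p <- labels == "pathogenic"
  called_p <- !is.na(calls) & calls == "pathogenic"
  called_b <- !is.na(calls) & calls == "benign"
  out <- list(
    tp = sum(called_p & lab_p),
    fp = sum(called_p & !lab_p),
    tn = sum(called_b & !lab_p),
    fn = sum(called_b & lab_p),
    unclassified_pathogenic = sum(is.na(calls) & lab_p),
    unclassified_benign = sum(is.na(calls) & !lab_p))
  out$unclassified <- out$unclassified_pathogenic + out$unclassified_benign
  class(out) <- "confusion_table"
  out
}

#' Sensitivity, specificity and accuracy of a confusion table
#'
#' No-calls are penalized on the sensitivity side: a pathogenic variant with
#' no definitive call is a miss, so sensitivity = tp / (all labeled
#' pathogenic). Specificity counts a benign variant as correctly handled
#' unless it is actively flagged pathogenic: specificity = 1 - fp / (all
#' labeled benign). Accuracy = (tp + tn) / (all labeled variants);
#' `accuracy_called` restricts the denominator to variants with a definitive
#' call. Any metric with a zero denominator is reported `NA`.
#'
#' @param ct A `confusion_table` from [confusion()].
#' @return Named numeric vector: `sensitivity`, `specificity`, `accuracy`,
#'   `accuracy_called`.
#' @export
confusion_metrics <- function(ct) {
  n_path <- ct$tp + ct$fn + ct$unclassified_pathogenic
  n_ben <- ct$tn + ct$fp + ct$unclassified_benign
  n_called <- ct$tp + ct$tn + ct$fp + ct$fn
  c(sensitivity = if (n_path > 0) ct$tp / n_path else NA_real_,
    specificity = if (n_ben > 0) 1 - ct$fp / n_ben else NA_real_,
    accuracy = if (n_path + n_ben > 0) (ct$tp + ct$tn) / (n_path + n_ben) else NA_real_,
    accuracy_called = if (n_called > 0) (ct$tp + ct$tn) / n_called else NA_real_)
}

#' Pairwise agreement between tools
#'
#' For each pair of tools, the fraction of variants — among those where both
#' tools give a definitive call — on which the binary calls coincide. Pairs
#' with no co-called variant are `NA`; the diagonal is 1.
#'
#' @param calls Character matrix from [call_tools()] (rows = variants,
#'   columns = tools).
#' @return Symmetric numeric matrix of agreement fractions.
#' @export
pairwise_agreement <- function(calls) {
  if (is.null(dim(calls)) || ncol(calls) < 2) stop("need calls for at least two tools")
  tools <- colnames(calls)
  k <- length(tools)
  m <- matrix(NA_real_, k, k, dimnames = list(tools, tools))
  diag(m) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      both <- !is.na(calls[, i]) & !is.na(calls[, j])
      m[i, j] <- m[j, i] <- if (any(both)) {
        mean(calls[both, i] == calls[both, j])
      } else NA_real_
    }
  }
  m
}

#' Combine per-tool calls under the all-agree rule
#'
#' A tool subset classifies a variant only when every member gives the same
#' definitive call: pathogenic if all members call pathogenic, benign if all
#' call benign, and no-call (`NA`) otherwise — including whenever any member
#' score is missing. Enlarging the subset can therefore only shrink the set
#' of classified variants.
#'
#' @param subset Character vector of tool names (non-empty, columns of
#'   `calls`).
#' @param calls Character call matrix from [call_tools()].
#' @return Character vector of combined calls, one per variant.
#' @export
combine_calls <- function(subset, calls) {
  if (!length(subset)) stop("tool subset must be non-empty")
  missing_tools <- setdiff(subset, colnames(calls))
  if (length(missing_tools)) stop("tools absent from call matrix: ",
                                  paste(missing_tools, collapse = ", "))
  sub <- calls[, subset, drop = FALSE]
  n_path <- rowSums(sub == "pathogenic")
  k <- length(subset)
  ifelse(is.na(n_path), NA_character_,
         ifelse(n_path == k, "pathogenic",
                ifelse(n_path == 0, "benign", NA_character_)))
}

#' Exhaustive evaluation of all tool combinations
#'
#' Evaluates every non-empty subset of the given tools under the all-agree
#' combination rule: for k tools, exactly 2^k - 1 subsets (4095 for the full
#' twelve-predictor panel). Each subset's combined calls are scored against
#' the truth labels with [confusion()] / [confusion_metrics()].
#'
#' @param calls Character call matrix from [call_tools()].
#' @param labels Truth labels (`"pathogenic"` / `"benign"`), one per row of
#'   `calls`.
#' @param tools Tools to scan (default: all columns of `calls`).
#' @param force Allow more than 20 tools (default `FALSE`; the scan is
#'   exponential in the number of tools).
#' @return A `data.table` with one row per subset: `subset` (sorted,
#'   semicolon-joined tool names), `size`, the confusion counts and the
#'   metrics of [confusion_metrics()].
#' @export
scan_combinations <- function(calls, labels, tools = colnames(calls),
                              force = FALSE) {
  k <- length(tools)
  if (k < 1) stop("need at least one tool")
  if (k > 20 && !force) {
    stop("refusing to scan 2^", k, " - 1 subsets; pass force = TRUE to override")
  }
  if (!all(labels %in% c("pathogenic", "benign"))) {
    stop("labels must be 'pathogenic' or 'benign'")
  }
  m <- matrix(NA_real_, nrow(calls), k)
  for (j in seq_len(k)) {
    cj <- calls[, tools[j]]
    m[, j] <- ifelse(is.na(cj), NA_real_, as.numeric(cj == "pathogenic"))
  }
  lab_p <- labels == "pathogenic"
  n_path_total <- sum(lab_p)
  n_ben_total <- sum(!lab_p)
  bits <- 2^(seq_len(k) - 1)
  masks <- seq_len(2^k - 1)
  rows <- vector("list", length(masks))
  for (mask in masks) {
    members <- which(bitwAnd(mask, bits) > 0)
    ksub <- length(members)
    s <- rowSums(m[, members, drop = FALSE])
    called_p <- !is.na(s) & s == ksub
    called_b <- !is.na(s) & s == 0
    tp <- sum(called_p & lab_p); fp <- sum(called_p & !lab_p)
    tn <- sum(called_b & !lab_p); fn <- sum(called_b & lab_p)
    ct <- list(tp = tp, fp = fp, tn = tn, fn = fn,
               unclassified_pathogenic = n_path_total - tp - fn,
               unclassified_benign = n_ben_total - tn - fp)
    ct$unclassified <- ct$unclassified_pathogenic + ct$unclassified_benign
    met <- confusion_metrics(ct)
    rows[[mask]] <- data.table::data.table(
      subset = paste(sort(tools[members]), collapse = ";"), size = ksub,
      tp = tp, fp = fp, tn = tn, fn = fn, unclassified = ct$unclassified,
      sensitivity = met[["sensitivity"]], specificity = met[["specificity"]],
      accuracy = met[["accuracy"]], accuracy_called = met[["accuracy_called"]])
  }
  data.table::rbindlist(rows)
}

#' Summarize a combination scan by subset size
#'
#' One row per subset size with the mean and maximum of sensitivity,
#' specificity and accuracy over all subsets of that size — the view in
#' which combined predictions are usually compared to the number of
#' algorithms combined.
#'
#' @param results Output of [scan_combinations()].
#' @return A `data.table` keyed by `size`.
#' @export
summarize_by_size <- function(results) {
  if (!nrow(results)) stop("empty combination-scan results")
  dt <- data.table::as.data.table(results)
  dt[, .(
    n_subsets = .N,
    mean_sensitivity = mean(sensitivity, na.rm = TRUE),
    max_sensitivity = max_or_na(sensitivity),
    mean_specificity = mean(specificity, na.rm = TRUE),
    max_specificity = max_or_na(specificity),
    mean_accuracy = mean(accuracy, na.rm = TRUE),
    max_accuracy = max_or_na(accuracy)
  ), keyby = size]
}

max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
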