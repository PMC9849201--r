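# Scoring predicted chilling requirement against observed chill hours,
# and concordance between two genotyping platforms.

#' Build prediction records from diplotype labels and observed chill hours
#'
#' Attaches each sample's expected chill-hour range (from the panel's
#' diplotype table, with the documented fallback for unobserved class
#' pairs) and scores it against the observed phenotype under the
#' boundary convention of [in_range()].
#'
#' @param samples sample identifiers
#' @param labels diplotype class-pair labels (e.g. `"H|M"`)
#' @param actual_ch observed chill hours (may be `NA`; such records carry
#'   no correctness verdict)
#' @param panel a `cr_panel`
#' @return `data.frame` with `sample`, `label`, `expected`, `actual_ch`,
#'   `correct`
#' @export
prediction_records <- function(samples, labels, actual_ch,
                               panel = builtin_ppecr1()) {
  stopifnot(length(samples) == length(labels),
            length(labels) == length(actual_ch))
  expected <- character(length(labels))
  correct <- rep(NA, length(labels))
  for (i in seq_along(labels)) {
    lr <- label_range(labels[i], panel)
    expected[i] <- format(lr$range)
    if (!is.na(actual_ch[i])) correct[i] <- in_range(actual_ch[i], lr$range)
  }
  data.frame(sample = samples, label = labels, expected = expected,
             actual_ch = actual_ch, correct = correct,
             stringsAsFactors = FALSE)
}

#' Accuracy of chilling-requirement predictions by diplotype
#'
#' Groups prediction records by diplotype label and reports the percent
#' of samples whose observed chill hours fall inside the predicted range,
#' per group and overall.  Percentages are rounded to one decimal, half
#' away from zero.
#'
#' @param records a `data.frame` with columns `label`, `actual_ch` and
#'   either `correct` (logical) or enough information to recompute it
#'   (`expected` ranges are re-derived from `panel` when `correct` is
#'   absent)
#' @param panel panel used to re-derive ranges when needed
#' @return a `cr_accuracy` object: `by_group` data frame (`label`, `n`,
#'   `n_correct`, `accuracy_pct`) sorted by label, and `overall`
#' @export
evaluate_predictions <- function(records, panel = builtin_ppecr1()) {
  if (!nrow(records)) stopf("no prediction records to evaluate")
  if (is.null(records$correct)) {
    records <- prediction_records(
      records$sample %||% seq_len(nrow(records)),
      records$label, records$actual_ch, panel)
  }
  if (any(is.na(records$correct)))
    stopf("every record needs an observed chill-hour value to be scored")
  agg_n <- tapply(records$correct, records$label, length)
  agg_c <- tapply(records$correct, records$label, sum)
  by_group <- data.frame(
    label = names(agg_n),
    n = as.integer(agg_n),
    n_correct = as.integer(agg_c),
    accuracy_pct = round_half_up(100 * as.integer(agg_c) / as.integer(agg_n), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  overall <- list(n = nrow(records), n_correct = sum(records$correct),
                  accuracy_pct = round_half_up(
                    100 * sum(records$correct) / nrow(records), 1))
  structure(list(by_group = by_group, overall = overall),
            class = "cr_accuracy")
}

#' @export
print.cr_accuracy <- function(x, ...) {
  cat("chilling-requirement prediction accuracy\n")
  g <- x$by_group
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-6s %5.1f%%  (%d/%d)\n", g$label[i], g$accuracy_pct[i],
                g$n_correct[i], g$n[i]))
  cat(sprintf("  overall %.1f%% (%d/%d)\n", x$overall$accuracy_pct,
              x$overall$n_correct, x$overall$n))
  invisible(x)
}

#' Concordance between two genotype call tables
#'
#' Compares calls from two platforms (say KASP vs SNP array) over the
#' intersection of their sample/assay keys.  Missing calls (`NA` or
#' `NOAMP`) on either side are excluded from the denominator.  Reports
#' per-assay and overall agreement plus the list of mismatches.
#'
#' @param calls_x,calls_y `data.frame`s with columns `sample`, `assay`,
#'   `call`
#' @return a `cr_concordance` object: `overall` (compared, matches,
#'   agreement_pct), `by_assay`, and `mismatches`
#' @export
concordance <- function(calls_x, calls_y) {
  for (d in list(calls_x, calls_y))
    if (!all(c("sample", "assay", "call") %in% names(d)))
      stopf("call tables need columns sample, assay, call")
  m <- merge(calls_x[, c("sample", "assay", "call")],
             calls_y[, c("sample", "assay", "call")],
             by = c("sample", "assay"), suffixes = c("_x", "_y"))
  if (!nrow(m)) stopf("no shared sample/assay keys between the two tables")
  usable <- !(is.na(m$call_x) | is.na(m$call_y) |
                m$call_x == "NOAMP" | m$call_y == "NOAMP")
  m <- m[usable, , drop = FALSE]
  if (!nrow(m)) stopf("no comparable (non-missing) calls in the intersection")
  m$match <- m$call_x == m$call_y
  agg_n <- tapply(m$match, m$assay, length)
  agg_c <- tapply(m$match, m$assay, sum)
  by_assay <- data.frame(
    assay = names(agg_n), compared = as.integer(agg_n),
    matches = as.integer(agg_c),
    agreement_pct = round_half_up(100 * as.integer(agg_c) / as.integer(agg_n), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  mism <- m[!m$match, c("sample", "assay", "call_x", "call_y")]
  rownames(mism) <- NULL
  structure(list(
    overall = list(compared = nrow(m), matches = sum(m$match),
                   agreement_pct = round_half_up(100 * sum(m$match) / nrow(m), 1)),
    by_assay = by_assay, mismatches = mism), class = "cr_concordance")
}

#' @export
print.cr_concordance <- function(x, ...) {
  cat(sprintf("call concordance: %.1f%% (%d/%d)\n",
              x$overall$agreement_pct, x$overall$matches, x$overall$compared))
  g <- x$by_assay
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s %5.1f%% (%d/%d)\n", g$assay[i], g$agreement_pct[i],
                g$matches[i], g$compared[i]))
  if (nrow(x$mismatches)) {
    cat("mismatches:\n")
    for (i in seq_len(nrow(x$mismatches)))
      cat(sprintf("  %s %s: %s vs %s\n", x$mismatches$sample[i],
                  x$mismatches$assay[i], x$mismatches$call_x[i],
                  x$mismatches$call_y[i]))
  }
  invisible(x)
}
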