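# Packaged validation roster and the end-to-end pipeline driver.

germplasm_fixture_md5 <- "ffee3a647d05e8ff4d4c3152b4592a32"

#' The packaged validation roster
#'
#' The 83 peach accessions (cultivars plus F2 selections) used to
#' validate the Ppe.CR.1 test, transcribed from the published validation
#' table: accession name and type, the KASP-derived diplotype class pair,
#' the SNP-array diplotype where array data exist (35 accessions), and
#' the observed chilling requirement in chill hours.  The published
#' narrative mentions one further high-chill (H|H) accession with array
#' data whose row is not recoverable from the available text, so the
#' roster carries 13 rather than 14 H|H entries; all other diplotype
#' groups are complete.
#'
#' @param check_integrity verify the packaged file's checksum before use
#' @return `data.frame`: `name`, `type`, `kasp_diplotype`,
#'   `array_diplotype` (`NA` without array data), `actual_ch`
#' @export
germplasm_fixture <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "germplasm_cr.csv", package = "kaspcr",
                      mustWork = TRUE)
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, germplasm_fixture_md5))
      stopf("validation roster checksum mismatch (%s); packaged data corrupted",
            md5)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$array_diplotype[d$array_diplotype %in% c("", "NA")] <- NA_character_
  d
}

published_accuracy <- function() {
  path <- system.file("extdata", "published_accuracy.csv", package = "kaspcr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Re-derive the validation accuracy table from the packaged roster
#'
#' Runs the prediction + evaluation stages on the packaged validation
#' roster with the built-in panel: each accession's KASP diplotype is
#' mapped to its expected chill-hour range and scored against the
#' observed chilling requirement, then accuracies are tabulated per
#' diplotype group and compared with the published per-group accuracies.
#'
#' @param panel the marker panel (built-in Ppe.CR.1 by default)
#' @return a `paper_reproduction`: `accuracy` (a `cr_accuracy`),
#'   `comparison` (per-group computed vs published accuracy with
#'   differences), and `records`
#' @export
reproduce_paper <- function(panel = builtin_ppecr1()) {
  roster <- germplasm_fixture()
  records <- prediction_records(roster$name, roster$kasp_diplotype,
                                roster$actual_ch, panel)
  acc <- evaluate_predictions(records, panel)
  pub <- published_accuracy()
  comp <- merge(acc$by_group, pub, by = "label", all = TRUE)
  comp$diff <- comp$accuracy_pct - comp$accuracy_pct_published
  comp <- comp[order(match(comp$label, pub$label)), ]
  rownames(comp) <- NULL
  structure(list(accuracy = acc, comparison = comp, records = records),
            class = "paper_reproduction")
}

#' @export
print.paper_reproduction <- function(x, ...) {
  cat("validation-roster reproduction (built-in Ppe.CR.1 panel)\n")
  c <- x$comparison
  cat(sprintf("  %-6s %6s %6s %10s %10s %7s\n",
              "group", "n", "n.pub", "acc", "acc.pub", "diff"))
  for (i in seq_len(nrow(c)))
    cat(sprintf("  %-6s %6s %6s %10.1f %10.1f %+7.1f\n", c$label[i],
                c$n[i], c$n_published[i], c$accuracy_pct[i],
                c$accuracy_pct_published[i], c$diff[i]))
  cat(sprintf("  overall %.1f%% (%d/%d)\n", x$accuracy$overall$accuracy_pct,
              x$accuracy$overall$n_correct, x$accuracy$overall$n))
  invisible(x)
}

#' Run the full calling-to-evaluation pipeline
#'
#' Normalises and calls one or more fluorescence plates, assembles
#' genotype vectors, infers diplotypes with CR predictions, and -- when
#' observed phenotypes are supplied -- scores prediction accuracy.
#' Stage outputs are returned and, when `out_dir` is given, also written
#' as CSV/JSON.  The pipeline is deterministic: identical inputs give
#' identical outputs.
#'
#' @param plates a plate `data.frame`, a list of them, or paths to plate
#'   CSV files
#' @param panel a `cr_panel`
#' @param thresholds calling thresholds (see [call_genotypes()])
#' @param phenotypes optional `data.frame` with `sample`, `actual_ch`
#' @param policy diplotype selection policy
#' @param out_dir optional output directory (created if absent)
#' @return list with `calls`, `controls`, `diplotypes`, `predictions`
#'   (when phenotypes given: scored records and `accuracy`)
#' @export
run_pipeline <- function(plates, panel = builtin_ppecr1(),
                         thresholds = default_thresholds(),
                         phenotypes = NULL, policy = "frequency",
                         out_dir = NULL) {
  if (is.data.frame(plates)) plates <- list(plates)
  plates <- lapply(plates, function(p) if (is.character(p)) read_plate(p) else p)
  calls_list <- list(); ctrl_list <- list()
  for (p in plates) {
    norm <- normalize_plate(p)
    calls <- call_genotypes(norm, thresholds)
    calls_list[[length(calls_list) + 1L]] <- calls
    ctrl_list[[length(ctrl_list) + 1L]] <- validate_controls(calls, norm)
  }
  calls <- do.call(rbind, calls_list)
  unknowns <- calls[calls$role == "unknown", , drop = FALSE]
  diplos <- infer_diplotypes(unknowns, panel, policy)
  out <- list(calls = calls, controls = ctrl_list, diplotypes = diplos)
  if (!is.null(phenotypes)) {
    m <- merge(diplos, phenotypes, by = "sample")
    ok <- m$label != "inconsistent" & !is.na(m$actual_ch)
    records <- prediction_records(m$sample[ok], m$label[ok], m$actual_ch[ok],
                                  panel)
    out$predictions <- records
    out$accuracy <- evaluate_predictions(records, panel)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(calls, file.path(out_dir, "calls.csv"))
    utils::write.csv(diplos, file.path(out_dir, "diplotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(out$predictions)) {
      utils::write.csv(out$predictions, file.path(out_dir, "predictions.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(by_group = out$accuracy$by_group, overall = out$accuracy$overall),
        file.path(out_dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
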