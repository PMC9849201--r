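# Fluorescence -> genotype calls (delta method).
#
# A KASP endpoint read gives every well two raw signals: FAM RFU (reports
# the A allele) and HEX RFU (reports the B allele).  Signals are first
# normalised per channel to percent of the plate maximum, then classified
# from the delta value %FAM - %HEX:
#   both channels below the NTC threshold -> NOAMP (no amplification)
#   delta above the heterozygous upper bound -> AA
#   delta below the heterozygous lower bound -> BB
#   otherwise                               -> AB
# Delta exactly on a bound is called AB (the heterozygous band is closed
# at both ends); the NTC comparison is strict.

plate_columns <- c("assay", "well", "sample", "role", "expected_genotype",
                   "rfu_fam", "rfu_hex")

#' Read a fluorescence plate CSV
#'
#' Expected columns: `assay`, `well`, `sample`, `role`
#' (`unknown`/`ntc`/`positive_control`), `expected_genotype` (blank unless
#' the well is a positive control), `rfu_fam`, `rfu_hex`.
#'
#' @param path path to the plate CSV
#' @return a validated plate `data.frame`
#' @export
read_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate(plate)
}

validate_plate <- function(plate) {
  missing <- setdiff(setdiff(plate_columns, "expected_genotype"), names(plate))
  if (length(missing))
    stopf("plate is missing columns: %s", paste(missing, collapse = ", "))
  if (is.null(plate$expected_genotype)) plate$expected_genotype <- NA_character_
  plate$expected_genotype[plate$expected_genotype %in% c("", "NA")] <- NA_character_
  bad <- setdiff(unique(plate$role), c("unknown", "ntc", "positive_control"))
  if (length(bad)) stopf("unknown well role(s): %s", paste(bad, collapse = ", "))
  pc <- plate$role == "positive_control"
  if (any(pc & is.na(plate$expected_genotype)))
    stopf("positive-control wells need an expected_genotype")
  if (any(!is.finite(plate$rfu_fam)) || any(!is.finite(plate$rfu_hex)) ||
      any(plate$rfu_fam < 0) || any(plate$rfu_hex < 0))
    stopf("RFU values must be finite and non-negative")
  plate
}

#' Normalise plate fluorescence to percent of plate maximum
#'
#' Adds `pct_fam` and `pct_hex` columns: each channel is scaled to
#' 100 * RFU / max(RFU over the plate) so values lie in \[0, 100\] and the
#' brightest well of each channel defines 100%.  When the plate carries
#' several assays, each assay is normalised on its own (one physical plate
#' per assay).  Calls downstream are therefore invariant to any uniform
#' rescaling of a channel (gain settings, exposure).
#'
#' @param plate a plate `data.frame` (see [read_plate()])
#' @return the plate with `pct_fam`/`pct_hex` columns added
#' @export
normalize_plate <- function(plate) {
  plate <- validate_plate(plate)
  groups <- if (is.null(plate$assay)) list(seq_len(nrow(plate)))
            else split(seq_len(nrow(plate)), plate$assay)
  plate$pct_fam <- NA_real_
  plate$pct_hex <- NA_real_
  for (idx in groups) {
    max_fam <- max(plate$rfu_fam[idx])
    max_hex <- max(plate$rfu_hex[idx])
    if (max_fam <= 0) stopf("no signal in FAM channel")
    if (max_hex <= 0) stopf("no signal in HEX channel")
    plate$pct_fam[idx] <- 100 * plate$rfu_fam[idx] / max_fam
    plate$pct_hex[idx] <- 100 * plate$rfu_hex[idx] / max_hex
  }
  plate
}

#' Calling thresholds for one KASP assay
#'
#' @param het_lower,het_upper bounds of the heterozygous delta band
#'   (delta = %FAM - %HEX); the band includes its bounds
#' @param ntc percent-fluorescence threshold below which (in both
#'   channels) a well is declared NOAMP; default 20
#' @return a `call_thresholds` object
#' @export
call_thresholds <- function(het_lower, het_upper, ntc = 20) {
  if (!(het_lower < het_upper)) stopf("het_lower must be below het_upper")
  structure(list(het_lower = het_lower, het_upper = het_upper, ntc = ntc),
            class = "call_thresholds")
}

#' Default delta thresholds for the Ppe.CR.1 assays
#'
#' Heterozygous lower/upper delta bounds tuned per assay on real-time PCR
#' validation plates: -10/34 (Ppe.CR.1-1), -40/10 (-2), -15/40 (-3),
#' -18/20 (-4); the no-template threshold of 20% applies to all four.
#' Thresholds are adjustable per assay when cluster positions shift
#' (different chemistry lots, end-point reads).
#'
#' @return named list of [call_thresholds()], keyed by assay id
#' @export
default_thresholds <- function() {
  list(
    "Ppe.CR.1-1" = call_thresholds(-10, 34),
    "Ppe.CR.1-2" = call_thresholds(-40, 10),
    "Ppe.CR.1-3" = call_thresholds(-15, 40),
    "Ppe.CR.1-4" = call_thresholds(-18, 20)
  )
}

threshold_for <- function(thresholds, assay) {
  if (inherits(thresholds, "call_thresholds")) return(thresholds)
  th <- thresholds[[assay]]
  if (is.null(th)) stopf("no calling thresholds for assay '%s'", assay)
  th
}

#' Call genotypes from a normalised plate
#'
#' Classifies every well as AA, AB, BB or NOAMP from its delta value
#' (see the rules in the package vignette): a well below the NTC
#' threshold in both channels has not amplified; otherwise delta above
#' the heterozygous upper bound is AA (FAM/A-allele homozygote), below
#' the lower bound BB, and inside the closed band AB.
#'
#' @param plate a plate normalised by [normalize_plate()]
#' @param thresholds a single [call_thresholds()] applied to all wells, or
#'   a named list keyed by assay id (default [default_thresholds()])
#' @return a `data.frame` of class `kasp_calls`: one row per well with
#'   `sample`, `assay`, `well`, `role`, `call`, `pct_fam`, `pct_hex`,
#'   `delta`
#' @export
call_genotypes <- function(plate, thresholds = default_thresholds()) {
  if (is.null(plate$pct_fam) || is.null(plate$pct_hex))
    stopf("plate is not normalised; run normalize_plate() first")
  n <- nrow(plate)
  call <- character(n)
  delta <- plate$pct_fam - plate$pct_hex
  for (i in seq_len(n)) {
    th <- threshold_for(thresholds, plate$assay[i])
    call[i] <-
      if (plate$pct_fam[i] < th$ntc && plate$pct_hex[i] < th$ntc) "NOAMP"
      else if (delta[i] > th$het_upper) "AA"
      else if (delta[i] < th$het_lower) "BB"
      else "AB"
  }
  out <- data.frame(sample = plate$sample, assay = plate$assay,
                    well = plate$well, role = plate$role, call = call,
                    pct_fam = plate$pct_fam, pct_hex = plate$pct_hex,
                    delta = delta, stringsAsFactors = FALSE)
  class(out) <- c("kasp_calls", "data.frame")
  out
}

#' Check plate controls against expectations
#'
#' Every NTC well must come out NOAMP and every positive control must
#' reproduce its known genotype; otherwise the plate is flagged `FAIL`.
#' Replicated positive controls are additionally summarised for
#' within-plate agreement.
#'
#' @param calls output of [call_genotypes()]
#' @param plate the plate the calls were made from (for expected
#'   genotypes); defaults to the information carried in `calls`
#' @return a `control_report`: `controls` data frame (one row per control
#'   well with expected/observed and a failure reason), `replicates`
#'   agreement summary, and overall `status` ("PASS"/"FAIL")
#' @export
validate_controls <- function(calls, plate = NULL) {
  expected <- rep(NA_character_, nrow(calls))
  if (!is.null(plate)) {
    key_c <- paste(calls$assay, calls$well)
    key_p <- paste(plate$assay, plate$well)
    expected <- plate$expected_genotype[match(key_c, key_p)]
  }
  is_ctrl <- calls$role %in% c("ntc", "positive_control")
  ctrl <- calls[is_ctrl, c("assay", "well", "sample", "role", "call")]
  ctrl$expected <- ifelse(ctrl$role == "ntc", "NOAMP", expected[is_ctrl])
  ctrl$ok <- ctrl$call == ctrl$expected
  ctrl$reason <- ifelse(ctrl$ok, "",
                 ifelse(ctrl$role == "ntc", "NTC amplified",
                        sprintf("control called %s, expected %s",
                                ctrl$call, ctrl$expected)))
  rownames(ctrl) <- NULL
  # replicate agreement among positive controls of the same target genotype
  pc <- ctrl[ctrl$role == "positive_control", ]
  reps <- if (nrow(pc)) {
    grp <- paste(pc$assay, pc$expected, sep = ":")
    agg <- tapply(pc$call, grp, function(x) length(unique(x)) == 1L)
    data.frame(group = names(agg), consistent = as.logical(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(group = character(), consistent = logical())
  structure(list(controls = ctrl, replicates = reps,
                 status = if (all(ctrl$ok)) "PASS" else "FAIL"),
            class = "control_report")
}

#' @export
print.control_report <- function(x, ...) {
  cat(sprintf("plate controls: %s (%d control wells)\n",
              x$status, nrow(x$controls)))
  bad <- x$controls[!x$controls$ok, ]
  if (nrow(bad)) {
    cat("failures:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s %s (%s): %s\n", bad$assay[i], bad$well[i],
                  bad$sample[i], bad$reason[i]))
  }
  invisible(x)
}

#' Write genotype calls to CSV
#'
#' @param calls a `kasp_calls` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
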