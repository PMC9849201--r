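# Chill-hour accumulation (Weinberger model) and chilling-requirement
# determination from budbreak forcing observations.

#' Accumulate Weinberger chill hours from hourly temperatures
#'
#' Each hour contributes one chill hour when its temperature lies in
#' (0, 7.2] degrees C, and nothing otherwise.  Both comparisons follow
#' the model exactly: 7.2 itself counts, 0 and sub-zero temperatures do
#' not (unlike e.g. the Utah model, freezing hours add nothing here).
#'
#' Input is either a plain numeric vector of hourly temperatures or a
#' `data.frame` with `timestamp` (ISO 8601 or `POSIXct`) and `temp_c`
#' columns.  Timestamped series may be windowed with `start`/`end`;
#' gaps longer than one hour are skipped (they contribute nothing) with a
#' warning, since the model defines no interpolation.
#'
#' @param temps numeric vector, or `data.frame` with `timestamp`, `temp_c`
#' @param start,end optional window bounds (anything `as.POSIXct` accepts)
#' @return a `chill_accumulation`: `data` (per-hour `temp_c`, `chill`,
#'   `cum_ch`, plus `timestamp` when given) and `total_ch`
#' @examples
#' accumulate_chill(c(5, 7.2, 7.3, 0, -1, 3))$total_ch  # 3
#' @export
accumulate_chill <- function(temps, start = NULL, end = NULL) {
  ts <- NULL
  if (is.data.frame(temps)) {
    if (!all(c("timestamp", "temp_c") %in% names(temps)))
      stopf("temperature table needs columns timestamp, temp_c")
    ts <- as.POSIXct(temps$timestamp, tz = "UTC")
    if (any(is.na(ts))) stopf("unparseable timestamp in temperature series")
    if (is.unsorted(as.numeric(ts), strictly = TRUE))
      stopf("timestamps must be strictly increasing")
    x <- temps$temp_c
    if (!is.null(start)) {
      keep <- ts >= as.POSIXct(start, tz = "UTC")
      ts <- ts[keep]; x <- x[keep]
    }
    if (!is.null(end)) {
      keep <- ts <= as.POSIXct(end, tz = "UTC")
      ts <- ts[keep]; x <- x[keep]
    }
    if (!length(x)) stopf("empty window: no temperatures between start and end")
    gaps <- diff(as.numeric(ts)) / 3600
    if (any(gaps > 1 + 1e-9))
      warnf("%d gap(s) longer than one hour in the series; missing hours contribute no chill",
            sum(gaps > 1 + 1e-9))
  } else {
    x <- as.numeric(temps)
    if (!length(x)) stopf("empty temperature series")
  }
  if (any(!is.finite(x))) stopf("temperatures must be finite")
  chill <- as.integer(x > 0 & x <= 7.2)
  data <- data.frame(temp_c = x, chill = chill, cum_ch = cumsum(chill))
  if (!is.null(ts)) data <- cbind(timestamp = ts, data)
  structure(list(data = data, total_ch = sum(chill)),
            class = "chill_accumulation")
}

#' @export
print.chill_accumulation <- function(x, ...) {
  cat(sprintf("chill accumulation: %d CH over %d hours\n",
              x$total_ch, nrow(x$data)))
  invisible(x)
}

#' Determine chilling requirement from budbreak forcing observations
#'
#' Shoots are collected at known chill accumulations (typically every
#' 100 CH) and forced in warmth; the chilling requirement is considered
#' fulfilled at the first collection point where at least 50% of floral
#' buds open.  No interpolation is done between collection points: the
#' requirement snaps to the first sampled point reaching 50%.  Samples
#' that never reach 50% are right-censored at the highest chill tested.
#'
#' @param forcing `data.frame` with columns `sample`, `chill_hours`,
#'   `percent_budbreak` (0-100); one row per sample and collection point
#' @param threshold budbreak percentage counting as fulfilment (50)
#' @return `data.frame` with one row per sample: `cr_ch` (NA when
#'   censored), `censored`, `max_tested`
#' @examples
#' f <- data.frame(sample = "x", chill_hours = c(200, 300, 400),
#'                 percent_budbreak = c(0, 10, 60))
#' determine_cr(f)  # cr_ch = 400
#' @export
determine_cr <- function(forcing, threshold = 50) {
  need <- c("sample", "chill_hours", "percent_budbreak")
  if (!all(need %in% names(forcing)))
    stopf("forcing table needs columns: %s", paste(need, collapse = ", "))
  if (any(forcing$percent_budbreak < 0 | forcing$percent_budbreak > 100))
    stopf("percent_budbreak must lie in [0, 100]")
  rows <- lapply(split(forcing, forcing$sample), function(d) {
    d <- d[order(d$chill_hours), , drop = FALSE]
    hit <- which(d$percent_budbreak >= threshold)
    data.frame(sample = d$sample[1L],
               cr_ch = if (length(hit)) d$chill_hours[hit[1L]] else NA_real_,
               censored = !length(hit),
               max_tested = max(d$chill_hours),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
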