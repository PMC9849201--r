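#' Chill-hour range for a predicted diplotype
#'
#' A `chill_range` describes the chill hours (CH) expected for a diplotype
#' as one of three shapes: `at_most` (printed "< x"), `between` (printed
#' "a-b"), or `at_least` (printed "> x").
#'
#' Boundary semantics are deliberate and matter for scoring: `at_most x`
#' accepts `ch <= x`, `at_least x` accepts `ch >= x`, and `between a b`
#' accepts `a <= ch < b`.  In other words, the printed "<"/">" bounds are
#' treated as inclusive and the upper bound of a two-sided range as
#' exclusive.  This is the unique simple convention under which the
#' published per-diplotype validation accuracies of the Ppe.CR.1 test are
#' reproduced from its validation roster (see [evaluate_predictions()]),
#' so it is adopted package-wide.
#'
#' @param kind one of `"at_most"`, `"between"`, `"at_least"`
#' @param low lower bound in CH (`between`/`at_least`)
#' @param high upper bound in CH (`between`/`at_most`)
#' @return an object of class `chill_range`
#' @examples
#' chill_range("between", 600, 850)  # accepts 600 <= ch < 850
#' chill_range("at_least", 750)      # accepts ch >= 750
#' @export
chill_range <- function(kind = c("at_most", "between", "at_least"),
                        low = NULL, high = NULL) {
  kind <- match.arg(kind)
  if (kind == "between") {
    if (is.null(low) || is.null(high))
      stopf("a 'between' chill range needs both bounds")
    if (!(low < high)) stopf("'between' range requires low < high (got %s, %s)", low, high)
  } else if (kind == "at_most") {
    if (is.null(high)) stopf("an 'at_most' chill range needs 'high'")
    low <- NULL
  } else {
    if (is.null(low)) stopf("an 'at_least' chill range needs 'low'")
    high <- NULL
  }
  structure(list(kind = kind, low = low, high = high), class = "chill_range")
}

#' @export
format.chill_range <- function(x, ...) {
  switch(x$kind,
    at_most  = sprintf("< %g", x$high),
    at_least = sprintf("> %g", x$low),
    between  = sprintf("%g-%g", x$low, x$high))
}

#' @export
print.chill_range <- function(x, ...) {
  cat("chill range:", format(x), "CH\n")
  invisible(x)
}

# Representative midpoint of a range, used by the cohort simulator.
# Open-ended ranges use the bound offset inward/outward by 100 CH, the
# granularity of the forcing design.
range_midpoint <- function(r, open_offset = 100) {
  switch(r$kind,
    between  = (r$low + r$high) / 2,
    at_most  = r$high - open_offset,
    at_least = r$low + open_offset)
}

#' Membership of a chill-hour value in a chill range
#'
#' Applies the boundary convention documented in [chill_range()]:
#' `at_most x` accepts `ch <= x`; `at_least x` accepts `ch >= x`;
#' `between a b` accepts `a <= ch < b`.
#'
#' @param ch positive chill hours (vectorised)
#' @param range a [chill_range()]
#' @return logical vector
#' @export
in_range <- function(ch, range) {
  stopifnot(inherits(range, "chill_range"))
  if (any(!is.finite(ch) | ch <= 0)) stopf("chill hours must be positive and finite")
  switch(range$kind,
    at_most  = ch <= range$high,
    at_least = ch >= range$low,
    between  = ch >= range$low & ch < range$high)
}

# The four CR phenotype classes used to bin cultivars by chilling need.
default_class_bins <- function() {
  data.frame(
    label = c("L", "LM", "M", "H"),
    low   = c(0, 400, 650, 850),
    high  = c(400, 650, 850, Inf),
    stringsAsFactors = FALSE
  )
}

#' Bin chill hours into chilling-requirement classes
#'
#' Cultivars are conventionally grouped into four CR classes by their
#' chill hours: low (`L`, < 400 CH), low-moderate (`LM`, 400-650 CH),
#' moderate (`M`, 650-850 CH) and high (`H`, >= 850 CH).  Bins are closed
#' below and open above, with `H` closed below at 850, so the four classes
#' tile the positive axis with no gaps or overlap.
#'
#' @param ch positive chill hours (vectorised)
#' @param bins a class-bin table as in a panel's `class_bins` field
#' @return character vector of class labels
#' @examples
#' cr_class_of(c(350, 675, 850))  # "L" "M" "H"
#' @export
cr_class_of <- function(ch, bins = default_class_bins()) {
  if (any(!is.finite(ch) | ch <= 0)) stopf("chill hours must be positive and finite")
  out <- character(length(ch))
  for (i in seq_len(nrow(bins))) {
    hit <- ch >= bins$low[i] & ch < bins$high[i]
    out[hit] <- bins$label[i]
  }
  out
}

new_cr_panel <- function(name, markers, alleles, diplotype_ranges,
                         class_bins = default_class_bins()) {
  p <- structure(
    list(name = name, markers = markers, alleles = alleles,
         diplotype_ranges = diplotype_ranges, class_bins = class_bins),
    class = "cr_panel")
  validate_panel(p)
}

#' Validate a marker panel
#'
#' Enforces the panel invariants: FAM reports the A allele (an A or T
#' nucleotide) and HEX the B allele (G or C); haplotype patterns are
#' strings over `{A,B}` with one letter per marker in marker order; and
#' patterns are unique within the panel.
#'
#' @param panel a `cr_panel`
#' @return the panel, invisibly usable in a pipeline
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "cr_panel"))
  m <- panel$markers
  a <- panel$alleles
  need_m <- c("marker_id", "assay_id", "allele_a_base", "allele_b_base")
  if (!all(need_m %in% names(m)))
    stopf("panel markers need columns: %s", paste(need_m, collapse = ", "))
  if (!all(m$allele_a_base %in% c("A", "T")))
    stopf("allele A must be an A or T nucleotide (FAM-labelled)")
  if (!all(m$allele_b_base %in% c("C", "G")))
    stopf("allele B must be a C or G nucleotide (HEX-labelled)")
  need_a <- c("allele_id", "pattern", "cr_class", "mean_ch", "carrier_count")
  if (!all(need_a %in% names(a)))
    stopf("panel alleles need columns: %s", paste(need_a, collapse = ", "))
  if (any(nchar(a$pattern) != nrow(m)))
    stopf("allele pattern length must equal the number of markers (%d)", nrow(m))
  if (any(grepl("[^AB]", a$pattern)))
    stopf("allele patterns must use only letters A and B")
  if (anyDuplicated(a$pattern))
    stopf("duplicate allele pattern in panel: %s",
          paste(unique(a$pattern[duplicated(a$pattern)]), collapse = ", "))
  if (any(a$carrier_count < 0)) stopf("carrier counts must be non-negative")
  if (!all(a$cr_class %in% panel$class_bins$label))
    stopf("allele cr_class values must be one of: %s",
          paste(panel$class_bins$label, collapse = ", "))
  if (!all(vapply(panel$diplotype_ranges, inherits, TRUE, "chill_range")))
    stopf("diplotype_ranges must all be chill_range objects")
  panel
}

#' The built-in Ppe.CR.1 chilling-requirement panel
#'
#' The Ppe.CR.1 DNA test targets the major chilling-requirement QTL region
#' at the bottom of peach chromosome 1 (43.58-43.78 Mbp), which overlaps
#' the dormancy-associated MADS-box (DAM) genes.  Four KASP assays
#' (Ppe.CR.1-1 to -4) genotype four SNPs whose joint pattern
#' distinguishes seven haplotypes ("alleles") segregating in U.S. peach
#' breeding germplasm.  Each allele carries a CR class (L, LM, M or H), a
#' mean chill-hour effect estimated in 86 reference accessions, and a
#' carrier count used as a frequency prior when diplotype inference is
#' ambiguous.
#'
#' Marker order in every haplotype pattern is SNP_IGA_134730,
#' SNP_1_46157131, SNP_IGA_134631, SNP_IGA_134484 (assays Ppe.CR.1-1,
#' -2, -3, -4).  Pattern letters use the SNP-array convention: `A` is the
#' FAM-labelled allele (A/T nucleotide), `B` the HEX-labelled allele
#' (G/C).
#'
#' @return a `cr_panel` with 4 markers, 7 alleles, and the expected
#'   chill-hour range for each observed diplotype class pair
#' @examples
#' p <- builtin_ppecr1()
#' p$alleles
#' format(p$diplotype_ranges[["M|M"]])
#' @export
builtin_ppecr1 <- function() {
  markers <- data.frame(
    marker_id    = c("SNP_IGA_134730", "SNP_1_46157131",
                     "SNP_IGA_134631", "SNP_IGA_134484"),
    assay_id     = c("Ppe.CR.1-1", "Ppe.CR.1-2", "Ppe.CR.1-3", "Ppe.CR.1-4"),
    allele_a_base = c("A", "T", "T", "T"),
    allele_b_base = c("G", "G", "C", "C"),
    chromosome   = rep("Chr1", 4),
    fluor_a      = rep("FAM", 4),
    fluor_b      = rep("HEX", 4),
    stringsAsFactors = FALSE
  )
  # One row per haplotype; patterns in marker order above.
  alleles <- data.frame(
    allele_id     = c(3L, 4L, 5L, 1L, 6L, 2L, 7L),
    pattern       = c("BBAA", "BBBB", "BBAB", "AAAA", "ABAA", "AAAB", "ABAB"),
    cr_class      = c("L", "LM", "M", "H", "H", "H", "H"),
    mean_ch       = c(291, 604, 772, 855, 860, 869, 903),
    carrier_count = c(7L, 25L, 61L, 13L, 17L, 27L, 14L),
    stringsAsFactors = FALSE
  )
  ranges <- list(
    "L|L"   = chill_range("at_most",  high = 350),
    "L|LM"  = chill_range("at_most",  high = 450),
    "L|M"   = chill_range("at_most",  high = 650),
    "LM|LM" = chill_range("between",  low = 300, high = 700),
    "M|LM"  = chill_range("between",  low = 400, high = 750),
    "H|LM"  = chill_range("between",  low = 500, high = 850),
    "M|M"   = chill_range("between",  low = 600, high = 850),
    "H|M"   = chill_range("at_least", low = 750),
    "H|H"   = chill_range("at_least", low = 850)
  )
  new_cr_panel("Ppe.CR.1", markers, alleles, ranges)
}

#' @export
print.cr_panel <- function(x, ...) {
  cat(sprintf("<cr_panel> %s: %d markers, %d alleles\n",
              x$name, nrow(x$markers), nrow(x$alleles)))
  cat("markers:", paste(x$markers$marker_id, collapse = ", "), "\n")
  cat("alleles (pattern | class | mean CH | carriers):\n")
  a <- x$alleles
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %d: %s | %-2s | %4g | %d\n", a$allele_id[i], a$pattern[i],
                a$cr_class[i], a$mean_ch[i], a$carrier_count[i]))
  cat("diplotype ranges:",
      paste(sprintf("%s %s", names(x$diplotype_ranges),
                    vapply(x$diplotype_ranges, format, "")), collapse = "; "),
      "\n")
  invisible(x)
}

#' Read a marker panel from JSON
#'
#' The panel document holds the panel name, its markers (with allele
#' nucleotides), its haplotype patterns with class/effect/carrier
#' metadata, and the expected chill-hour range per diplotype class pair.
#' Documents written by [write_panel()] round-trip exactly.
#'
#' @param path path to a panel JSON file
#' @return a validated `cr_panel`
#' @seealso [write_panel()], [builtin_ppecr1()]
#' @export
read_panel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("name", "markers", "alleles", "diplotype_ranges"))
    if (is.null(doc[[f]])) stopf("panel document is missing field '%s'", f)
  markers <- do.call(rbind, lapply(doc$markers, function(m) {
    for (f in c("marker_id", "assay_id", "allele_a_base", "allele_b_base"))
      if (is.null(m[[f]])) stopf("panel marker is missing field '%s'", f)
    data.frame(marker_id = m$marker_id, assay_id = m$assay_id,
               allele_a_base = m$allele_a_base, allele_b_base = m$allele_b_base,
               chromosome = m$chromosome %||% NA_character_,
               fluor_a = "FAM", fluor_b = "HEX", stringsAsFactors = FALSE)
  }))
  alleles <- do.call(rbind, lapply(doc$alleles, function(a) {
    for (f in c("allele_id", "pattern", "cr_class", "mean_chill_hours", "carrier_count"))
      if (is.null(a[[f]])) stopf("panel allele is missing field '%s'", f)
    data.frame(allele_id = as.integer(a$allele_id), pattern = a$pattern,
               cr_class = a$cr_class, mean_ch = as.numeric(a$mean_chill_hours),
               carrier_count = as.integer(a$carrier_count),
               stringsAsFactors = FALSE)
  }))
  ranges <- lapply(doc$diplotype_ranges, function(r) {
    if (is.null(r$kind)) stopf("diplotype range is missing field 'kind'")
    chill_range(r$kind,
                low = if (!is.null(r$low)) as.numeric(r$low),
                high = if (!is.null(r$high)) as.numeric(r$high))
  })
  bins <- if (!is.null(doc$class_bins)) {
    do.call(rbind, lapply(doc$class_bins, function(b)
      data.frame(label = b$label, low = as.numeric(b$low),
                 high = if (is.null(b$high)) Inf else as.numeric(b$high),
                 stringsAsFactors = FALSE)))
  } else default_class_bins()
  new_cr_panel(doc$name, markers, alleles, ranges, bins)
}

#' Write a marker panel to JSON
#'
#' @param panel a `cr_panel`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  doc <- list(
    name = panel$name,
    markers = lapply(seq_len(nrow(panel$markers)), function(i) {
      m <- panel$markers[i, ]
      list(marker_id = m$marker_id, assay_id = m$assay_id,
           allele_a_base = m$allele_a_base, allele_b_base = m$allele_b_base,
           chromosome = m$chromosome)
    }),
    alleles = lapply(seq_len(nrow(panel$alleles)), function(i) {
      a <- panel$alleles[i, ]
      list(allele_id = a$allele_id, pattern = a$pattern, cr_class = a$cr_class,
           mean_chill_hours = a$mean_ch, carrier_count = a$carrier_count)
    }),
    diplotype_ranges = lapply(panel$diplotype_ranges, function(r) {
      out <- list(kind = r$kind)
      if (!is.null(r$low)) out$low <- r$low
      if (!is.null(r$high)) out$high <- r$high
      out
    }),
    class_bins = lapply(seq_len(nrow(panel$class_bins)), function(i) {
      b <- panel$class_bins[i, ]
      out <- list(label = b$label, low = b$low)
      if (is.finite(b$high)) out$high <- b$high
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
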