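# Diplotype inference: which unordered pair of panel haplotypes explains
# an unphased genotype vector, and what chilling requirement does that
# pair predict.
#
# With only 7 panel haplotypes over 4 SNPs, panel-constrained enumeration
# over the 28 unordered haplotype pairs is exact and instantaneous; no
# statistical phasing is involved.

pattern_chars <- function(pattern) strsplit(pattern, "")[[1]]

# Genotype implied at one marker by an unordered pair of pattern letters
combine_letters <- function(a, b) {
  if (a == "A" && b == "A") "AA"
  else if (a == "B" && b == "B") "BB"
  else "AB"
}

#' Combine two haplotype patterns into an unphased genotype vector
#'
#' @param px,py haplotype pattern strings over `{A,B}`, e.g. `"BBAB"`
#' @return character vector of per-marker genotypes (`AA`/`AB`/`BB`)
#' @export
combine_patterns <- function(px, py) {
  a <- pattern_chars(px); b <- pattern_chars(py)
  stopifnot(length(a) == length(b))
  mapply(combine_letters, a, b, USE.NAMES = FALSE)
}

# Class-pair label in the published table style, e.g. "H|M", "M|LM" but
# "L|LM", "L|M": the higher class leads mixed pairs except that L always
# leads, matching the printed diplotype keys.
class_pair_label <- function(cx, cy, class_order = c("L", "H", "M", "LM")) {
  r <- match(c(cx, cy), class_order)
  if (any(is.na(r))) stopf("unknown CR class in pair: %s, %s", cx, cy)
  paste(class_order[sort(r)], collapse = "|")
}

#' Enumerate candidate diplotypes for an unphased genotype vector
#'
#' Tests every unordered pair of panel haplotypes (including
#' homozygous pairs) and keeps the pairs whose marker-wise combination
#' reproduces the genotype exactly.  Missing calls (`NA`, or `"NOAMP"`)
#' impose no constraint at their marker, so candidates are the union over
#' the unobserved possibilities.
#'
#' Each candidate carries a frequency weight built from the panel's
#' carrier counts in Hardy-Weinberg style: `count(x) * count(y)`, doubled
#' for heterozygous pairs.  The weights act as a prior when several
#' haplotype pairs explain the same genotype.
#'
#' @param genotype character vector of per-marker calls in panel marker
#'   order (`AA`/`AB`/`BB`, `NA` or `"NOAMP"` for missing)
#' @param panel a `cr_panel`
#' @return `data.frame` with one row per candidate: `allele_x`,
#'   `allele_y` (allele ids, x <= y by panel order), `label` (class pair),
#'   `weight`; zero rows when no pair is compatible
#' @examples
#' p <- builtin_ppecr1()
#' enumerate_diplotypes(c("AB", "AB", "AB", "AB"), p)  # unique pair {1, 4}
#' @export
enumerate_diplotypes <- function(genotype, panel) {
  stopifnot(inherits(panel, "cr_panel"))
  nm <- nrow(panel$markers)
  if (length(genotype) != nm)
    stopf("genotype vector must have %d entries (one per marker)", nm)
  genotype[genotype %in% "NOAMP"] <- NA
  known <- !is.na(genotype)
  if (any(!genotype[known] %in% c("AA", "AB", "BB")))
    stopf("genotype entries must be AA, AB, BB or missing")
  a <- panel$alleles
  pats <- lapply(a$pattern, pattern_chars)
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in i:nrow(a)) {
      g <- mapply(combine_letters, pats[[i]], pats[[j]], USE.NAMES = FALSE)
      if (all(g[known] == genotype[known])) {
        w <- a$carrier_count[i] * a$carrier_count[j] * (if (i == j) 1 else 2)
        ids <- sort(c(a$allele_id[i], a$allele_id[j]))
        out[[length(out) + 1L]] <- data.frame(
          allele_x = ids[1L], allele_y = ids[2L],
          label = class_pair_label(a$cr_class[i], a$cr_class[j]),
          weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(allele_x = integer(), allele_y = integer(),
                      label = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Expected range for a class-pair label.  Labels outside the panel's
# observed diplotype table fall back to a band of half-width 125 CH
# centred on the mean of the two haplotype chill-hour effects (the
# allele means when the pair is known, else carrier-weighted class
# means), flagged as such.
label_range <- function(label, panel, allele_x = NULL, allele_y = NULL) {
  r <- panel$diplotype_ranges[[label]]
  if (!is.null(r)) return(list(range = r, fallback = FALSE))
  a <- panel$alleles
  if (!is.null(allele_x) && !is.null(allele_y)) {
    mx <- a$mean_ch[match(allele_x, a$allele_id)]
    my <- a$mean_ch[match(allele_y, a$allele_id)]
  } else {
    classes <- strsplit(label, "|", fixed = TRUE)[[1L]]
    if (length(classes) != 2L || !all(classes %in% a$cr_class))
      stopf("no expected chill range for diplotype '%s'", label)
    class_mean <- function(cl) {
      rows <- a[a$cr_class == cl, ]
      sum(rows$mean_ch * rows$carrier_count) / sum(rows$carrier_count)
    }
    mx <- class_mean(classes[1L]); my <- class_mean(classes[2L])
  }
  mid <- (mx + my) / 2
  list(range = chill_range("between", low = mid - 125, high = mid + 125),
       fallback = TRUE)
}

#' Select a diplotype among candidates
#'
#' Policy `"frequency"` (default) keeps the candidate with the largest
#' carrier-frequency weight, breaking exact ties by lowest allele ids;
#' policy `"strict"` only selects when a single candidate exists.  The
#' result is flagged ambiguous whenever the candidates disagree at the
#' phenotype level, i.e. map to more than one class-pair label --
#' candidate pairs sharing a label (say two different H|H pairs) are not
#' a phenotype ambiguity.
#'
#' The expected chill-hour range is looked up in the panel's diplotype
#' table; class pairs never observed in the reference germplasm fall back
#' to a band centred on the mean of the two allele effects and are
#' flagged (`range_fallback`).
#'
#' @param candidates output of [enumerate_diplotypes()]
#' @param panel a `cr_panel`
#' @param policy `"frequency"` or `"strict"`
#' @return a `diplotype_result`: `candidates`, `selected` (row or `NULL`),
#'   `label`, `expected_range`, `ambiguity`, `range_fallback`
#' @export
resolve_diplotype <- function(candidates, panel,
                              policy = c("frequency", "strict")) {
  policy <- match.arg(policy)
  if (nrow(candidates) == 0L)
    stopf("genotype inconsistent with panel: no haplotype pair reproduces it")
  ord <- order(-candidates$weight, candidates$allele_x, candidates$allele_y)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  ambiguity <- length(unique(candidates$label)) > 1L
  selected <- NULL
  label <- NA_character_
  range <- NULL
  fallback <- FALSE
  if (policy == "frequency" || nrow(candidates) == 1L) {
    selected <- candidates[1L, ]
    label <- selected$label
    lr <- label_range(label, panel, selected$allele_x, selected$allele_y)
    range <- lr$range
    fallback <- lr$fallback
  }
  structure(list(candidates = candidates, selected = selected, label = label,
                 expected_range = range, ambiguity = ambiguity,
                 range_fallback = fallback, policy = policy),
            class = "diplotype_result")
}

#' @export
print.diplotype_result <- function(x, ...) {
  if (is.null(x$selected)) {
    cat(sprintf("diplotype: unresolved (%d candidates, policy %s)\n",
                nrow(x$candidates), x$policy))
  } else {
    cat(sprintf("diplotype: %s (alleles %d|%d), expected %s CH%s%s\n",
                x$label, x$selected$allele_x, x$selected$allele_y,
                format(x$expected_range),
                if (x$ambiguity) ", AMBIGUOUS" else "",
                if (x$range_fallback) ", fallback range" else ""))
  }
  invisible(x)
}

#' Pivot per-assay calls into genotype vectors and infer diplotypes
#'
#' Takes a call table (one row per sample x assay, e.g. from
#' [call_genotypes()]) for the panel's assays, assembles each sample's
#' genotype vector in panel marker order (NOAMP or absent calls become
#' missing), and runs [enumerate_diplotypes()] +
#' [resolve_diplotype()] per sample.
#'
#' @param calls `data.frame` with columns `sample`, `assay`, `call`
#' @param panel a `cr_panel`
#' @param policy selection policy, see [resolve_diplotype()]
#' @return `data.frame` with one row per sample: `sample`, `allele_x`,
#'   `allele_y`, `label`, `expected` (printed range), `expected_kind`,
#'   `expected_low`, `expected_high`, `ambiguity`, `n_candidates`,
#'   `n_missing`; samples whose genotype is inconsistent with the panel
#'   get `NA` alleles and label `"inconsistent"`
#' @export
infer_diplotypes <- function(calls, panel, policy = "frequency") {
  assays <- panel$markers$assay_id
  samples <- unique(calls$sample[calls$role %in% c(NA, "unknown") |
                                   is.null(calls$role)])
  if (!length(samples)) samples <- unique(calls$sample)
  rows <- lapply(samples, function(s) {
    g <- vapply(assays, function(a) {
      v <- calls$call[calls$sample == s & calls$assay == a]
      if (!length(v)) NA_character_ else v[[1L]]
    }, "")
    g[g %in% "NOAMP"] <- NA
    cand <- enumerate_diplotypes(g, panel)
    if (nrow(cand) == 0L)
      return(data.frame(sample = s, allele_x = NA_integer_,
                        allele_y = NA_integer_, label = "inconsistent",
                        expected = NA_character_, expected_kind = NA_character_,
                        expected_low = NA_real_, expected_high = NA_real_,
                        ambiguity = NA, n_candidates = 0L,
                        n_missing = sum(is.na(g)), stringsAsFactors = FALSE))
    res <- resolve_diplotype(cand, panel, policy)
    r <- res$expected_range
    data.frame(sample = s,
               allele_x = if (is.null(res$selected)) NA_integer_ else res$selected$allele_x,
               allele_y = if (is.null(res$selected)) NA_integer_ else res$selected$allele_y,
               label = res$label,
               expected = if (is.null(r)) NA_character_ else format(r),
               expected_kind = if (is.null(r)) NA_character_ else r$kind,
               expected_low = if (is.null(r) || is.null(r$low)) NA_real_ else r$low,
               expected_high = if (is.null(r) || is.null(r$high)) NA_real_ else r$high,
               ambiguity = res$ambiguity, n_candidates = nrow(cand),
               n_missing = sum(is.na(g)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-assay screen: split haplotypes at 800 chill hours
#'
#' The first assay of the panel (Ppe.CR.1-1, SNP_IGA_134730) alone
#' separates haplotypes below and above 800 CH: every B-carrying panel
#' haplotype averages under 800 CH and every A-carrying one over 800 CH.
#' A BB call therefore means both haplotypes are low-chill (< 800 CH), AA
#' means both are high-chill (> 800 CH), and AB one of each.  This is the
#' cheapest culling step for a programme breeding away from high (or low)
#' chilling requirement.
#'
#' @param call per-sample genotype call at Ppe.CR.1-1 (vectorised)
#' @return character vector: `"both_below_800"`, `"both_above_800"`,
#'   `"one_below_one_above_800"`, or `NA` for NOAMP/missing
#' @export
step1_classify <- function(call) {
  out <- rep(NA_character_, length(call))
  out[call == "BB"] <- "both_below_800"
  out[call == "AA"] <- "both_above_800"
  out[call == "AB"] <- "one_below_one_above_800"
  bad <- !is.na(call) & !call %in% c("AA", "AB", "BB", "NOAMP")
  if (any(bad)) stopf("invalid genotype call: %s", call[bad][1L])
  out
}

# Projection of the panel onto assays 1 and 4: two-letter haplotypes,
# their CR class in the reduced scheme, and pooled carrier counts.
step2_projection <- function(panel) {
  i1 <- match("Ppe.CR.1-1", panel$markers$assay_id)
  i4 <- match("Ppe.CR.1-4", panel$markers$assay_id)
  if (is.na(i1) || is.na(i4)) stopf("panel lacks assays Ppe.CR.1-1/-4")
  a <- panel$alleles
  proj <- vapply(a$pattern, function(p) {
    ch <- pattern_chars(p); paste0(ch[i1], ch[i4])
  }, "")
  counts <- tapply(a$carrier_count, proj, sum)
  # class of each 2-letter haplotype: A_ at assay 1 is high chill; among
  # B_ haplotypes, assay 4 separates low (BA) from moderate (BB)
  cls <- c(AA = "H", AB = "H", BA = "L", BB = "M")
  data.frame(hap = names(counts), class = cls[names(counts)],
             weight = as.numeric(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-assay step classifier: low / moderate / high chilling requirement
#'
#' Using only assays Ppe.CR.1-1 and Ppe.CR.1-4, haplotypes fall into
#' three classes: `A` at assay 1 marks high CR (> 800 CH) regardless of
#' assay 4; among `B` haplotypes at assay 1, `A` at assay 4 marks low CR
#' (< 450 CH) and `B` moderate CR (450-800 CH).  The pair of two-marker
#' haplotypes is enumerated against the two genotype calls; the
#' double-heterozygote (AB, AB), compatible with both H+M and H+L pairs,
#' is resolved by pooled carrier frequencies, which favour H|M.
#'
#' @param call1,call4 genotype calls at Ppe.CR.1-1 and Ppe.CR.1-4
#' @param panel a `cr_panel` (for the carrier-frequency projection)
#' @return list with `label` (e.g. `"H|M"`), `candidates` data frame
#'   (haplotype pairs with weights), and `ambiguity`
#' @export
step2_classify <- function(call1, call4, panel = builtin_ppecr1()) {
  for (cl in c(call1, call4))
    if (!cl %in% c("AA", "AB", "BB"))
      stopf("step2_classify needs non-missing AA/AB/BB calls (got %s)", cl)
  proj <- step2_projection(panel)
  haps <- proj$hap
  out <- list()
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      h1 <- pattern_chars(haps[i]); h2 <- pattern_chars(haps[j])
      g1 <- combine_letters(h1[1], h2[1])
      g4 <- combine_letters(h1[2], h2[2])
      if (g1 == call1 && g4 == call4) {
        w <- proj$weight[i] * proj$weight[j] * (if (i == j) 1 else 2)
        out[[length(out) + 1L]] <- data.frame(
          hap_x = haps[i], hap_y = haps[j],
          label = class_pair_label(proj$class[i], proj$class[j]),
          weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    stopf("genotype pair (%s, %s) inconsistent with panel haplotypes",
          call1, call4)
  cand <- do.call(rbind, out)
  cand <- cand[order(-cand$weight, cand$hap_x, cand$hap_y), , drop = FALSE]
  rownames(cand) <- NULL
  list(label = cand$label[1L], candidates = cand,
       ambiguity = length(unique(cand$label)) > 1L)
}

#' Expand a diplotype class-pair label into a genotype vector
#'
#' Inverse-direction helper for class-labelled data (e.g. array calls
#' recorded only as "H|M"): each CR class is represented by its most
#' frequent panel allele, and the two representative patterns are
#' combined marker-wise.  This is an approximation -- classes with several
#' alleles (H) lose within-class detail -- but concordance counts at the
#' call level are insensitive to the representative chosen when both
#' tables use the same expansion.
#'
#' @param label class-pair label, e.g. `"H|M"` (separator `|`)
#' @param panel a `cr_panel`
#' @return character vector of per-marker genotypes
#' @export
expand_diplotype <- function(label, panel = builtin_ppecr1()) {
  classes <- strsplit(label, "|", fixed = TRUE)[[1L]]
  if (length(classes) != 2L) stopf("diplotype label must be 'X|Y' (got '%s')", label)
  a <- panel$alleles
  rep_pattern <- function(cl) {
    rows <- a[a$cr_class == cl, , drop = FALSE]
    if (!nrow(rows)) stopf("no panel allele of class '%s'", cl)
    rows$pattern[which.max(rows$carrier_count)]
  }
  combine_patterns(rep_pattern(classes[1L]), rep_pattern(classes[2L]))
}
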