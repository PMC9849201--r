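# KASP primer design QC: sequence composition, melting temperature,
# simple secondary-structure screen, and the standard acceptance criteria
# for allele-specific primer sets.

#' Universal KASP tail sequences
#'
#' Every KASP forward primer carries one of two universal 5' tails that
#' route the reaction to the FAM or HEX FRET cassette.  The tails are
#' fixed by the chemistry, not designed per assay, so design criteria are
#' evaluated on the primer body after tail removal.
#'
#' @return named character vector with elements `FAM` and `HEX`
#' @export
kasp_tails <- function() {
  c(FAM = "GAAGGTGACCAAGTTCATGCT",
    HEX = "GAAGGTCGGAGTCAACGGATT")
}

#' GC content of a primer sequence
#'
#' @param seq A/C/G/T string (case-insensitive)
#' @return percent G+C, 0-100
#' @examples
#' gc_content("GCGC")  # 100
#' @export
gc_content <- function(seq) {
  s <- check_dna(seq, "primer sequence")
  ch <- strsplit(s, "")[[1L]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keyed by the 5'->3' top-strand
# dinucleotide (complementary steps share values).
nn_params <- function() {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  # complementary steps
  comp <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA", CC = "GG")
  dH <- c(dH, stats::setNames(dH[comp], names(comp)))
  dS <- c(dS, stats::setNames(dS[comp], names(comp)))
  list(dH = dH, dS = dS)
}

#' Primer melting temperature
#'
#' Two conventions are offered.  `"nearest_neighbor"` (default) is the
#' SantaLucia unified stack-sum model with terminal initiation terms, a
#' monovalent-salt entropy correction, and the duplex equilibrium
#' formula Tm = dH / (dS + R ln(C/4)) - 273.15; defaults are 50 mM Na+
#' and 250 nM total oligo, typical qPCR conditions.  `"wallace"` is the
#' composition rule 2(A+T) + 4(G+C), handy for quick hand checks on
#' short oligos.  Both are deterministic.
#'
#' @param seq A/C/G/T string
#' @param method `"nearest_neighbor"` or `"wallace"`
#' @param na_molar monovalent cation concentration (mol/L)
#' @param oligo_molar total single-strand concentration (mol/L)
#' @return melting temperature in degrees C
#' @examples
#' melting_temperature("ATGC", method = "wallace")  # 12
#' @export
melting_temperature <- function(seq,
                                method = c("nearest_neighbor", "wallace"),
                                na_molar = 0.05, oligo_molar = 250e-9) {
  method <- match.arg(method)
  s <- check_dna(seq, "primer sequence")
  ch <- strsplit(s, "")[[1L]]
  if (method == "wallace")
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  if (length(ch) < 2L) stopf("nearest-neighbor Tm needs at least 2 bases")
  p <- nn_params()
  steps <- paste0(ch[-length(ch)], ch[-1L])
  dH <- sum(p$dH[steps])
  dS <- sum(p$dS[steps])
  # initiation terms per terminal base pair
  for (term in ch[c(1L, length(ch))]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (length(ch) - 1) * log(na_molar)
  R <- 1.987  # cal/(mol K)
  1000 * dH / (dS + R * log(oligo_molar / 4)) - 273.15
}

#' Composition motifs relevant to primer design
#'
#' Reports the longest homopolymer run, the longest tandem dinucleotide
#' repeat (in repeat units, so `ATATATAT` counts 4), and the number of
#' G/C bases among the five 3'-terminal positions (the "GC clamp"
#' region, where excess G/C promotes mispriming).
#'
#' @param seq A/C/G/T string
#' @return list with `max_homopolymer`, `max_dinucleotide_repeats`,
#'   `gc_in_last5`
#' @export
sequence_motifs <- function(seq) {
  s <- check_dna(seq, "primer sequence")
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  runs <- rle(ch)
  max_homo <- max(runs$lengths)
  # longest tandem run of any 2-mer
  max_di <- 0L
  if (n >= 2L) {
    for (phase in 0:1) {
      idx <- seq.int(1L + phase, n - 1L, by = 2L)
      if (!length(idx)) next
      pairs <- paste0(ch[idx], ch[idx + 1L])
      r <- rle(pairs)
      max_di <- max(max_di, r$lengths)
    }
  }
  last5 <- ch[max(1L, n - 4L):n]
  list(max_homopolymer = as.integer(max_homo),
       max_dinucleotide_repeats = as.integer(max_di),
       gc_in_last5 = sum(last5 %in% c("G", "C")))
}

dna_complement <- function(ch) c(A = "T", C = "G", G = "C", T = "A")[ch]

#' Self-structure free-energy screen
#'
#' Scans the primer against itself for antiparallel complementary
#' stretches (hairpin stems and self-dimer registers) of at least three
#' base pairs, scores each stretch by summing nearest-neighbor stack free
#' energies at 37 degrees C, and returns the most negative total.  A
#' sequence with no complementary stretch scores 0.  This is a screening
#' heuristic for the "secondary structure more positive than -9
#' kcal/mol" design rule, not a partition-function fold.
#'
#' @param seq A/C/G/T string
#' @return Gibbs free energy in kcal/mol (always <= 0)
#' @export
self_structure_dg <- function(seq) {
  s <- check_dna(seq, "primer sequence")
  ch <- strsplit(s, "")[[1L]]
  n <- length(ch)
  if (n < 6L) return(0)
  p <- nn_params()
  dg <- p$dH - 310.15 * p$dS / 1000
  best <- 0
  # pair (i, j), i < j, means ch[i] binds ch[j] in an antiparallel stem;
  # along one register i + j is constant and stems advance (i+1, j-1)
  for (const in 3L:(2L * n - 1L)) {
    i <- max(1L, const - n):min(n, const - 1L)
    j <- const - i
    keep <- i < j
    i <- i[keep]; j <- j[keep]
    if (length(i) < 3L) next
    paired <- ch[i] == dna_complement(ch[j])
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 3L)) {
      run_i <- i[starts[k]:ends[k]]
      steps <- paste0(ch[run_i[-length(run_i)]], ch[run_i[-1L]])
      total <- sum(dg[steps])
      if (total < best) best <- total
    }
  }
  best
}

#' A KASP primer set
#'
#' Bundles the two allele-specific forward primers (universal FAM/HEX
#' tail + assay-specific body ending on the SNP base) and the common
#' reverse primer for one assay.  The two forward bodies must be
#' identical except at their 3'-terminal (SNP) base.
#'
#' @param assay_id assay name, e.g. `"Ppe.CR.1-1"`
#' @param fam_forward,hex_forward full tailed forward primers (5'->3')
#' @param common_reverse common reverse primer (5'->3')
#' @return a `kasp_primer_set`
#' @export
kasp_primer_set <- function(assay_id, fam_forward, hex_forward,
                            common_reverse) {
  tails <- kasp_tails()
  fam <- check_dna(fam_forward, "FAM forward primer")
  hex <- check_dna(hex_forward, "HEX forward primer")
  rev <- check_dna(common_reverse, "common reverse primer")
  if (!startsWith(fam, tails[["FAM"]]))
    stopf("FAM forward primer of %s does not start with the universal FAM tail",
          assay_id)
  if (!startsWith(hex, tails[["HEX"]]))
    stopf("HEX forward primer of %s does not start with the universal HEX tail",
          assay_id)
  fam_body <- substring(fam, nchar(tails[["FAM"]]) + 1L)
  hex_body <- substring(hex, nchar(tails[["HEX"]]) + 1L)
  if (nchar(fam_body) != nchar(hex_body) ||
      substr(fam_body, 1L, nchar(fam_body) - 1L) !=
        substr(hex_body, 1L, nchar(hex_body) - 1L))
    stopf("forward primer bodies of %s must differ only at the 3' SNP base",
          assay_id)
  structure(list(assay_id = assay_id, fam_forward = fam, hex_forward = hex,
                 common_reverse = rev, fam_body = fam_body,
                 hex_body = hex_body),
            class = "kasp_primer_set")
}

#' Built-in primer sets of the Ppe.CR.1 test
#'
#' The four validated assay primer sets, with universal tails attached
#' and the SNP base as the final position of each forward body.
#'
#' @return named list of [kasp_primer_set()] objects
#' @export
builtin_primers <- function() {
  t <- kasp_tails()
  list(
    "Ppe.CR.1-1" = kasp_primer_set("Ppe.CR.1-1",
      paste0(t[["FAM"]], "TTTGCACAAATTCCCATGAAAGAA"),
      paste0(t[["HEX"]], "TTTGCACAAATTCCCATGAAAGAG"),
      "GACCAAGAAATCAGCTTCAACTGTG"),
    "Ppe.CR.1-2" = kasp_primer_set("Ppe.CR.1-2",
      paste0(t[["FAM"]], "TTCTCAAAAACCACTGCTTGCAT"),
      paste0(t[["HEX"]], "TTCTCAAAAACCACTGCTTGCAG"),
      "CCTCTGAAGAAGATTAACAAATATGTGAC"),
    "Ppe.CR.1-3" = kasp_primer_set("Ppe.CR.1-3",
      paste0(t[["FAM"]], "GGTTCTCTTGGAAAGCTCCCTT"),
      paste0(t[["HEX"]], "GGTTCTCTTGGAAAGCTCCCTC"),
      "TCTGTAGTGGAGATATCATATTTCTCAC"),
    "Ppe.CR.1-4" = kasp_primer_set("Ppe.CR.1-4",
      paste0(t[["FAM"]], "GGCTACTTTTGAATACTCTGGACT"),
      paste0(t[["HEX"]], "GGCTACTTTTGAATACTCTGGACC"),
      "CTGAGAATGCCCGTATAGGAGTAC")
  )
}

#' Primer design criteria
#'
#' The standard acceptance window for KASP primer bodies: GC content
#' 30-55%, nearest-neighbor Tm 62-66 degrees C, length 21-30 nt, PCR
#' product 42-100 bp, self-structure dG above -9 kcal/mol, at most 4
#' tandem dinucleotide repeats, at most 4 identical bases in a row
#' (relaxable to 5; the convention is ambiguous), and at most 3 G/C among
#' the last five 3' bases.  Set any field to `NULL` to disable that
#' check.
#'
#' @param gc_min,gc_max GC-content bounds (percent)
#' @param tm_min,tm_max melting-temperature bounds (degrees C)
#' @param len_min,len_max body-length bounds (nt)
#' @param product_min,product_max product-size bounds (bp)
#' @param structure_dg_min minimum tolerated self-structure dG (kcal/mol)
#' @param max_dinucleotide_repeats,max_homopolymer,max_gc_last5 motif caps
#' @return a `design_criteria` list
#' @export
design_criteria <- function(gc_min = 30, gc_max = 55,
                            tm_min = 62, tm_max = 66,
                            len_min = 21, len_max = 30,
                            product_min = 42, product_max = 100,
                            structure_dg_min = -9,
                            max_dinucleotide_repeats = 4,
                            max_homopolymer = 4,
                            max_gc_last5 = 3) {
  structure(list(gc_min = gc_min, gc_max = gc_max, tm_min = tm_min,
                 tm_max = tm_max, len_min = len_min, len_max = len_max,
                 product_min = product_min, product_max = product_max,
                 structure_dg_min = structure_dg_min,
                 max_dinucleotide_repeats = max_dinucleotide_repeats,
                 max_homopolymer = max_homopolymer,
                 max_gc_last5 = max_gc_last5),
            class = "design_criteria")
}

reverse_complement <- function(seq) {
  ch <- strsplit(check_dna(seq), "")[[1L]]
  paste(rev(dna_complement(ch)), collapse = "")
}

#' Check a KASP primer set against design criteria
#'
#' Evaluates every enabled criterion on each primer of the set.  All
#' composition and thermodynamic checks run on the primer BODY with the
#' universal tail removed: the tails are fixed by the chemistry, shared
#' by every assay, and would otherwise dominate composition measures.
#' The product-size check runs only when a template sequence is supplied;
#' the forward body and the reverse complement of the reverse primer must
#' then each occur exactly once in the template.
#'
#' @param primers a [kasp_primer_set()]
#' @param criteria a [design_criteria()]
#' @param template optional template sequence (A/C/G/T string) spanning
#'   the amplicon
#' @param tm_method melting-temperature convention, see
#'   [melting_temperature()]
#' @return a `primer_report`: `checks` data frame (`primer`, `criterion`,
#'   `value`, `pass`) and overall `pass`
#' @export
check_assay <- function(primers, criteria = design_criteria(),
                        template = NULL, tm_method = "nearest_neighbor") {
  stopifnot(inherits(primers, "kasp_primer_set"))
  bodies <- list(fam_body = primers$fam_body, hex_body = primers$hex_body,
                 common_reverse = primers$common_reverse)
  checks <- list()
  add <- function(primer, criterion, value, pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      primer = primer, criterion = criterion, value = value, pass = pass,
      stringsAsFactors = FALSE)
  }
  for (nm in names(bodies)) {
    s <- bodies[[nm]]
    if (!is.null(criteria$gc_min)) {
      gc <- gc_content(s)
      add(nm, "gc_content", gc, gc >= criteria$gc_min & gc <= criteria$gc_max)
    }
    if (!is.null(criteria$tm_min)) {
      tm <- melting_temperature(s, tm_method)
      add(nm, "tm", tm, tm >= criteria$tm_min & tm <= criteria$tm_max)
    }
    if (!is.null(criteria$len_min)) {
      len <- nchar(s)
      add(nm, "length", len, len >= criteria$len_min & len <= criteria$len_max)
    }
    motifs <- sequence_motifs(s)
    if (!is.null(criteria$max_homopolymer))
      add(nm, "max_homopolymer", motifs$max_homopolymer,
          motifs$max_homopolymer <= criteria$max_homopolymer)
    if (!is.null(criteria$max_dinucleotide_repeats))
      add(nm, "max_dinucleotide_repeats", motifs$max_dinucleotide_repeats,
          motifs$max_dinucleotide_repeats <= criteria$max_dinucleotide_repeats)
    if (!is.null(criteria$max_gc_last5))
      add(nm, "gc_in_last5", motifs$gc_in_last5,
          motifs$gc_in_last5 <= criteria$max_gc_last5)
    if (!is.null(criteria$structure_dg_min)) {
      dg <- self_structure_dg(s)
      add(nm, "structure_dg", dg, dg >= criteria$structure_dg_min)
    }
  }
  if (!is.null(template) && !is.null(criteria$product_min)) {
    tpl <- check_dna(template, "template")
    fwd <- primers$fam_body
    rev_rc <- reverse_complement(primers$common_reverse)
    fpos <- gregexpr(fwd, tpl, fixed = TRUE)[[1L]]
    rpos <- gregexpr(rev_rc, tpl, fixed = TRUE)[[1L]]
    if (fpos[1L] == -1L) stopf("forward primer body not found in template")
    if (rpos[1L] == -1L)
      stopf("reverse primer (reverse complement) not found in template")
    if (length(fpos) > 1L || length(rpos) > 1L)
      stopf("primer maps to multiple template positions")
    product <- rpos + nchar(rev_rc) - fpos
    add("pair", "product_size", product,
        product >= criteria$product_min & product <= criteria$product_max)
  }
  checks <- if (length(checks)) do.call(rbind, checks)
            else data.frame(primer = character(), criterion = character(),
                            value = numeric(), pass = logical())
  structure(list(assay_id = primers$assay_id, checks = checks,
                 pass = all(checks$pass)),
            class = "primer_report")
}

#' @export
print.primer_report <- function(x, ...) {
  cat(sprintf("primer QC for %s: %s\n", x$assay_id,
              if (x$pass) "PASS" else "FAIL"))
  c <- x$checks
  for (i in seq_len(nrow(c)))
    cat(sprintf("  %-15s %-26s %8.2f  %s\n", c$primer[i], c$criterion[i],
                c$value[i], if (c$pass[i]) "ok" else "FAIL"))
  invisible(x)
}
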