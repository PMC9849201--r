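test_that("GC content matches hand counts on the built-in reverse primers", {
  # manual G+C tallies over the published common reverse primers
  expect_equal(gc_content("GACCAAGAAATCAGCTTCAACTGTG"), 44)            # 11/25
  expect_equal(gc_content("CCTCTGAAGAAGATTAACAAATATGTGAC"), 100 * 10 / 29)
  expect_equal(gc_content("TCTGTAGTGGAGATATCATATTTCTCAC"), 100 * 10 / 28)
  expect_equal(gc_content("CTGAGAATGCCCGTATAGGAGTAC"), 50)             # 12/24
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("gcat"), 50)  # case-insensitive
  expect_error(gc_content("ACGU"), "non-ACGT")
  expect_error(gc_content(""), "non-empty")
})

test_that("Wallace melting temperature is the 2AT + 4GC composition rule", {
  expect_equal(melting_temperature("ATGC", method = "wallace"), 12)
  expect_equal(melting_temperature("AT", method = "wallace"), 4)
  s <- "GATTACAGGT"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(melting_temperature(s, "wallace"),
               melting_temperature(rev_s, "wallace"))
  # additive over concatenation (composition-only formula)
  expect_equal(melting_temperature("ATGCATGC", "wallace"),
               2 * melting_temperature("ATGC", "wallace"))
})

test_that("nearest-neighbor Tm reproduces independent reference values", {
  # frozen from an independent SantaLucia-1998 implementation at the same
  # conditions (50 mM Na+, 250 nM total oligo)
  expect_equal(melting_temperature("TTTGCACAAATTCCCATGAAAGAA"), 54.241,
               tolerance = 1e-3)
  expect_equal(melting_temperature("GACCAAGAAATCAGCTTCAACTGTG"), 56.695,
               tolerance = 1e-3)
  expect_equal(melting_temperature("ATGCATGCATGCATGCATGCA"), 59.106,
               tolerance = 1e-3)
  expect_equal(melting_temperature("CCTCTGAAGAAGATTAACAAATATGTGAC"), 54.526,
               tolerance = 1e-3)
  expect_error(melting_temperature("ATGC", method = "banana"))
})

test_that("sequence motifs report runs, repeats and the 3' GC count", {
  m <- sequence_motifs("GGAAAAAT")
  expect_equal(m$max_homopolymer, 5L)
  m2 <- sequence_motifs("ATATATATAT")
  expect_equal(m2$max_dinucleotide_repeats, 5L)
  m3 <- sequence_motifs("TTTGGGCC")
  expect_equal(m3$gc_in_last5, 5L)
  # dinucleotide repeats are found in either frame
  expect_equal(sequence_motifs("CGCGCGCG")$max_dinucleotide_repeats, 4L)
  expect_equal(sequence_motifs("TCGCGCGCG")$max_dinucleotide_repeats, 4L)
  expect_equal(sequence_motifs("A")$max_homopolymer, 1L)
})

test_that("self-structure screen is non-positive and finds inverted repeats", {
  expect_equal(self_structure_dg("AAAAAAAAAA"), 0)
  # strong inverted repeat folds back on itself
  expect_lt(self_structure_dg("GCGCGCAAAAAAGCGCGC"), 0)
  set.seed(99)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
               collapse = "")
    expect_lte(self_structure_dg(s), 0)
  }
})

test_that("built-in primer sets strip to bodies differing only at the SNP", {
  tails <- kasp_tails()
  for (ps in builtin_primers()) {
    expect_true(startsWith(ps$fam_forward, tails[["FAM"]]))
    expect_true(startsWith(ps$hex_forward, tails[["HEX"]]))
    nb <- nchar(ps$fam_body)
    expect_equal(nchar(ps$hex_body), nb)
    expect_equal(substr(ps$fam_body, 1, nb - 1), substr(ps$hex_body, 1, nb - 1))
    expect_false(substr(ps$fam_body, nb, nb) == substr(ps$hex_body, nb, nb))
    # body lengths inside the design window once the tail is removed
    for (s in c(ps$fam_body, ps$hex_body, ps$common_reverse))
      expect_true(nchar(s) >= 21 && nchar(s) <= 30)
  }
  expect_error(
    kasp_primer_set("x", "AAAATTTT", "AAAATTTT", "ACGT"), "FAM tail")
  expect_error(
    kasp_primer_set("x",
                    paste0(tails[["FAM"]], "ACGTACGTACGTA"),
                    paste0(tails[["HEX"]], "TTTTACGTACGTC"),
                    "ACGTACGT"),
    "3' SNP base")
})

test_that("assay checks evaluate criteria on bodies and report measurements", {
  ps <- builtin_primers()[["Ppe.CR.1-1"]]
  rep1 <- check_assay(ps)
  expect_s3_class(rep1, "primer_report")
  lens <- rep1$checks[rep1$checks$criterion == "length", ]
  expect_true(all(lens$pass))
  expect_equal(sort(lens$value), c(24, 24, 25))
  gcs <- rep1$checks[rep1$checks$criterion == "gc_content", ]
  expect_true(all(gcs$pass))
  # the published primers sit below the 62-66 C window under this Tm
  # convention; the report must say so rather than pass silently
  tms <- rep1$checks[rep1$checks$criterion == "tm", ]
  expect_true(all(!tms$pass))

  # every criterion disabled: nothing to fail
  off <- design_criteria(gc_min = NULL, tm_min = NULL, len_min = NULL,
                         product_min = NULL, structure_dg_min = NULL,
                         max_dinucleotide_repeats = NULL,
                         max_homopolymer = NULL, max_gc_last5 = NULL)
  expect_true(check_assay(ps, off)$pass)

  # the A-run in the second assay's forward body trips the strict
  # homopolymer cap but passes the relaxed one
  ps2 <- builtin_primers()[["Ppe.CR.1-2"]]
  strict <- check_assay(ps2, design_criteria(max_homopolymer = 4))
  hp <- strict$checks[strict$checks$criterion == "max_homopolymer" &
                        strict$checks$primer == "fam_body", ]
  expect_equal(hp$value, 5)
  expect_false(hp$pass)
  relaxed <- check_assay(ps2, design_criteria(max_homopolymer = 5))
  hp5 <- relaxed$checks[relaxed$checks$criterion == "max_homopolymer" &
                          relaxed$checks$primer == "fam_body", ]
  expect_true(hp5$pass)
})

test_that("product size is measured against a supplied template", {
  ps <- builtin_primers()[["Ppe.CR.1-1"]]
  # build an 80 bp template: forward body at the 5' end, then filler,
  # then the reverse complement of the reverse primer at the 3' end
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  filler_n <- 80 - nchar(ps$fam_body) - nchar(ps$common_reverse)
  template <- paste0(ps$fam_body,
                     paste(rep("T", filler_n), collapse = ""),
                     rc(ps$common_reverse))
  rep_t <- check_assay(ps, template = template)
  prod <- rep_t$checks[rep_t$checks$criterion == "product_size", ]
  expect_equal(prod$value, 80)
  expect_true(prod$pass)
  # primer absent from template is an error
  expect_error(check_assay(ps, template = paste(rep("A", 60), collapse = "")),
               "not found in template")
})
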