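panel <- builtin_ppecr1()

test_that("enumeration agrees with the brute-force oracle on all 81 genotypes", {
  for (g in all_genotype_vectors()) {
    got <- enumerate_diplotypes(g, panel)
    want <- oracle_enumerate(g, panel)
    expect_equal(pair_keys(got), pair_keys(want),
                 info = paste(g, collapse = ","))
  }
})

test_that("every candidate recombines into its source genotype", {
  a <- panel$alleles
  for (g in all_genotype_vectors()) {
    cand <- enumerate_diplotypes(g, panel)
    for (k in seq_len(nrow(cand))) {
      px <- a$pattern[a$allele_id == cand$allele_x[k]]
      py <- a$pattern[a$allele_id == cand$allele_y[k]]
      expect_equal(combine_patterns(px, py), g)
    }
  }
})

test_that("worked inference examples resolve as expected", {
  # all-A genotype: only the all-A haplotype paired with itself
  c1 <- enumerate_diplotypes(c("AA", "AA", "AA", "AA"), panel)
  expect_equal(pair_keys(c1), "1-1")
  # quadruple heterozygote: allele 4 is the only B carrier at the third
  # SNP, forcing the all-A partner
  c2 <- enumerate_diplotypes(c("AB", "AB", "AB", "AB"), panel)
  expect_equal(pair_keys(c2), "1-4")
  # ambiguous double explanation, weights from carrier counts
  c3 <- enumerate_diplotypes(c("AB", "AB", "AA", "AB"), panel)
  expect_setequal(pair_keys(c3), c("1-5", "2-3"))
  expect_equal(c3$weight[c3$allele_x == 1], 13 * 61 * 2)
  expect_equal(c3$weight[c3$allele_x == 2], 27 * 7 * 2)
  r3 <- resolve_diplotype(c3, panel)
  expect_equal(r3$selected$allele_x, 1)
  expect_equal(r3$selected$allele_y, 5)
  expect_equal(r3$label, "H|M")
  expect_true(r3$ambiguity)
  # impossible genotype: BB at the first SNP forces B alleles which all
  # carry B somewhere the genotype says AA
  c4 <- enumerate_diplotypes(c("BB", "AA", "AA", "AA"), panel)
  expect_equal(nrow(c4), 0L)
  expect_error(resolve_diplotype(c4, panel), "inconsistent with panel")
})

test_that("selection policies and phenotype-level ambiguity behave", {
  # homozygous moderate: unique candidate, published range
  r <- resolve_diplotype(enumerate_diplotypes(c("BB", "BB", "AA", "BB"),
                                              panel), panel)
  expect_equal(r$label, "M|M")
  expect_equal(format(r$expected_range), "600-850")
  expect_false(r$ambiguity)
  # two candidate pairs mapping to the same class pair are not a
  # phenotype ambiguity
  g <- combine_patterns("AAAA", "ABAB")  # {1,7}; also explained by {2,6}
  cand <- enumerate_diplotypes(g, panel)
  expect_setequal(pair_keys(cand), c("1-7", "2-6"))
  r2 <- resolve_diplotype(cand, panel)
  expect_equal(r2$label, "H|H")
  expect_false(r2$ambiguity)
  # strict policy refuses to choose among several candidates
  c3 <- enumerate_diplotypes(c("AB", "AB", "AA", "AB"), panel)
  rs <- resolve_diplotype(c3, panel, policy = "strict")
  expect_null(rs$selected)
  expect_true(is.na(rs$label))
})

test_that("missing markers widen the candidate set by union", {
  g_full <- c("AB", "AB", "AA", "AB")
  g_miss <- c("AB", "AB", NA, "AB")
  got <- enumerate_diplotypes(g_miss, panel)
  # oracle: union of candidates over the three possible genotypes there
  want <- unique(do.call(c, lapply(c("AA", "AB", "BB"), function(m)
    pair_keys(oracle_enumerate(replace(g_miss, 3, m), panel)))))
  expect_setequal(pair_keys(got), want)
  expect_true(all(pair_keys(enumerate_diplotypes(g_full, panel)) %in%
                    pair_keys(got)))
  # NOAMP is treated as missing
  g_noamp <- c("AB", "AB", "NOAMP", "AB")
  expect_equal(pair_keys(enumerate_diplotypes(g_noamp, panel)),
               pair_keys(got))
})

test_that("all published diplotype groups are reachable from genotypes", {
  labels <- character(0)
  for (g in all_genotype_vectors()) {
    cand <- enumerate_diplotypes(g, panel)
    if (nrow(cand)) labels <- c(labels, resolve_diplotype(cand, panel)$label)
  }
  expect_true(all(c("L|L", "L|LM", "LM|LM", "M|LM", "M|M",
                    "H|LM", "H|M", "H|H") %in% labels))
})

test_that("one-assay screen splits haplotypes at 800 chill hours", {
  expect_equal(step1_classify("BB"), "both_below_800")
  expect_equal(step1_classify("AA"), "both_above_800")
  expect_equal(step1_classify("AB"), "one_below_one_above_800")
  expect_true(is.na(step1_classify("NOAMP")))
  expect_error(step1_classify("ZZ"), "invalid genotype")

  # agreement with the full pipeline wherever the candidate is unique:
  # the selected pair's allele means straddle 800 exactly as the single
  # first-assay call predicts
  a <- panel$alleles
  for (g in all_genotype_vectors()) {
    cand <- enumerate_diplotypes(g, panel)
    if (nrow(cand) != 1L) next
    means <- a$mean_ch[match(c(cand$allele_x, cand$allele_y), a$allele_id)]
    verdict <- step1_classify(g[1])
    if (verdict == "both_below_800") expect_true(all(means < 800))
    if (verdict == "both_above_800") expect_true(all(means > 800))
    if (verdict == "one_below_one_above_800")
      expect_true(sum(means > 800) == 1L)
  }
})

test_that("two-assay step classifier separates low, moderate and high", {
  expect_equal(step2_classify("AA", "AA")$label, "H|H")
  expect_equal(step2_classify("BB", "BB")$label, "M|M")
  # double heterozygote: H+M and H+L both explain it; pooled carrier
  # frequencies favour H|M
  r <- step2_classify("AB", "AB")
  expect_equal(r$label, "H|M")
  expect_true(r$ambiguity)
  expect_setequal(unique(r$candidates$label), c("H|M", "L|H"))
  # low haplotype: B at assay 1 with A at assay 4
  expect_equal(step2_classify("BB", "AA")$label, "L|L")
  expect_equal(step2_classify("BB", "AB")$label, "L|M")
  expect_error(step2_classify("NOAMP", "AA"), "non-missing")
})

test_that("per-sample inference pivots call tables correctly", {
  genos <- rbind(combine_patterns("BBAB", "BBAB"),   # M|M
                 combine_patterns("AAAA", "BBAB"),   # H|M
                 combine_patterns("BBAA", "BBAA"))   # L|L
  colnames(genos) <- panel$markers$assay_id
  calls <- calls_from_genotypes(genos, c("mm", "hm", "ll"))
  d <- infer_diplotypes(calls, panel)
  expect_equal(d$label[match(c("mm", "hm", "ll"), d$sample)],
               c("M|M", "H|M", "L|L"))
  expect_equal(d$expected[d$sample == "mm"], "600-850")
  # an inconsistent genotype is reported, not an error
  bad <- matrix(c("BB", "AA", "AA", "AA"), nrow = 1,
                dimnames = list(NULL, panel$markers$assay_id))
  db <- infer_diplotypes(calls_from_genotypes(bad, "x"), panel)
  expect_equal(db$label, "inconsistent")
  expect_equal(db$n_candidates, 0L)
})

test_that("class-pair labels follow the published table style", {
  expect_equal(expand_diplotype("M|M", panel), c("BB", "BB", "AA", "BB"))
  # most frequent H allele (id 2, pattern AAAB) represents class H
  expect_equal(expand_diplotype("H|M", panel),
               combine_patterns("AAAB", "BBAB"))
  expect_error(expand_diplotype("H|M|L", panel), "X|Y")
})
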