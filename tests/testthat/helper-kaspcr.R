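# Shared fixtures and independent oracles.

# All 3^4 = 81 genotype vectors over a four-marker panel
all_genotype_vectors <- function() {
  g <- expand.grid(m1 = c("AA", "AB", "BB"), m2 = c("AA", "AB", "BB"),
                   m3 = c("AA", "AB", "BB"), m4 = c("AA", "AB", "BB"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
}

# Brute-force diplotype oracle: walk every unordered allele pair, combine
# pattern letters as sorted multisets, keep exact matches.  Kept verbose
# and string-based on purpose so it shares no code with the package path.
oracle_enumerate <- function(genotype, panel) {
  a <- panel$alleles
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in i:nrow(a)) {
      pi <- strsplit(a$pattern[i], "")[[1]]
      pj <- strsplit(a$pattern[j], "")[[1]]
      implied <- vapply(seq_along(pi), function(k)
        paste(sort(c(pi[k], pj[k])), collapse = ""), "")
      if (all(implied == genotype)) {
        ids <- sort(c(a$allele_id[i], a$allele_id[j]))
        hits[[length(hits) + 1]] <- ids
      }
    }
  }
  hits
}

# Canonical "x-y" strings for a candidate table / oracle hit list
pair_keys <- function(x) {
  if (is.data.frame(x)) sort(paste(x$allele_x, x$allele_y, sep = "-"))
  else sort(vapply(x, function(p) paste(p, collapse = "-"), ""))
}

# Long call table (sample x assay) from a genotype matrix, as produced by
# the calling stage
calls_from_genotypes <- function(genotypes, samples = NULL) {
  samples <- samples %||% sprintf("S%03d", seq_len(nrow(genotypes)))
  do.call(rbind, lapply(seq_len(nrow(genotypes)), function(i)
    data.frame(sample = samples[i], assay = colnames(genotypes),
               call = unname(genotypes[i, ]), stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small plate with one well at known percent coordinates per assay.
# rfu values are chosen so the plate maxima are exactly 1000 in each
# channel, making pct equal to rfu/10.
plate_at_pct <- function(assay, pct_fam, pct_hex) {
  data.frame(
    assay = assay,
    well = paste0("A", seq_len(length(pct_fam) + 2L)),
    sample = c(sprintf("s%d", seq_along(pct_fam)), "anchor_fam", "anchor_hex"),
    role = "unknown", expected_genotype = NA_character_,
    rfu_fam = c(pct_fam * 10, 1000, 0),
    rfu_hex = c(pct_hex * 10, 0, 1000),
    stringsAsFactors = FALSE)
}
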