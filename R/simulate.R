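# Synthetic data with known truth: fluorescence plates for the caller and
# genotype/phenotype cohorts for the diplotype + prediction pipeline.

default_cluster_means <- function() {
  # raw RFU centroids of the four endpoint clusters
  rbind(AA  = c(rfu_fam = 1800, rfu_hex = 150),
        AB  = c(rfu_fam = 1000, rfu_hex = 1000),
        BB  = c(rfu_fam = 150,  rfu_hex = 1800),
        NTC = c(rfu_fam = 60,   rfu_hex = 60))
}

#' Fluorescence cluster model for plate simulation
#'
#' Wells are drawn from isotropic Gaussian clusters in raw RFU space, one
#' cluster per genotype class plus a no-template background cluster, and
#' truncated at zero.  Real KASP scatterplots are arc-shaped rather than
#' Gaussian, but cluster geometry is irrelevant to threshold-based
#' calling; what matters is how far cluster centres sit from the decision
#' boundaries.
#'
#' `separation` expresses exactly that: the spread is set so that every
#' cluster centre lies at least `separation` standard deviations from its
#' nearest calling boundary (heterozygous delta bounds and the NTC box,
#' checked across all supplied assay thresholds).  At `separation = 10`
#' miscalls are then vanishingly improbable; shrinking it degrades
#' calling accuracy.  Alternatively pass an explicit `sd` in RFU.
#'
#' @param means 4 x 2 matrix of cluster centres (rows AA, AB, BB, NTC)
#' @param sd isotropic cluster standard deviation in RFU
#' @param separation boundary distance in sd units (used when `sd` is
#'   `NULL`)
#' @param thresholds thresholds the separation is computed against
#' @return a `cluster_model` list: `means`, `sd`
#' @export
cluster_model <- function(means = default_cluster_means(), sd = NULL,
                          separation = 10,
                          thresholds = default_thresholds()) {
  stopifnot(is.matrix(means), nrow(means) == 4L,
            all(c("AA", "AB", "BB", "NTC") %in% rownames(means)),
            all(means >= 0))
  if (is.null(sd)) {
    # percent-of-max coordinates assuming the plate maximum sits at the
    # brightest cluster centre (accurate for tight clusters)
    pct <- 100 * sweep(means, 2, apply(means, 2, max), "/")
    delta <- pct[, 1] - pct[, 2]
    th_list <- if (inherits(thresholds, "call_thresholds")) list(thresholds)
               else thresholds
    margin_delta <- Inf
    ntc_cut <- 20
    for (th in th_list) {
      margin_delta <- min(margin_delta,
                          delta[["AA"]] - th$het_upper,
                          th$het_lower - delta[["BB"]],
                          delta[["AB"]] - th$het_lower,
                          th$het_upper - delta[["AB"]])
      ntc_cut <- th$ntc
    }
    margin_ntc <- ntc_cut - max(pct["NTC", ])
    if (margin_delta <= 0 || margin_ntc <= 0)
      stopf("cluster means sit on the wrong side of a calling boundary")
    # channel-pct sd s gives delta sd s*sqrt(2); convert back to RFU
    s_pct <- min(margin_delta / (separation * sqrt(2)),
                 margin_ntc / separation)
    sd <- s_pct * max(means) / 100
  }
  structure(list(means = means, sd = sd), class = "cluster_model")
}

#' Lay out a simulation plate
#'
#' Builds a well table with the conventional control row (three NTCs and
#' three positive controls, one per genotype) followed by unknown wells
#' with the requested true genotypes.
#'
#' @param genotypes character vector of true genotypes (AA/AB/BB) for the
#'   unknown wells
#' @return layout `data.frame`: `well`, `sample`, `role`,
#'   `expected_genotype`, `genotype` (simulation truth)
#' @export
plate_layout <- function(genotypes) {
  stopifnot(all(genotypes %in% c("AA", "AB", "BB")))
  ctrl <- data.frame(
    well = paste0("A", 1:6),
    sample = c(paste0("NTC", 1:3), "ctrl_AA", "ctrl_AB", "ctrl_BB"),
    role = c(rep("ntc", 3), rep("positive_control", 3)),
    expected_genotype = c(rep(NA_character_, 3), "AA", "AB", "BB"),
    genotype = c(rep("NTC", 3), "AA", "AB", "BB"),
    stringsAsFactors = FALSE)
  n <- length(genotypes)
  if (n > 378L) stopf("at most 378 unknown wells fit a 384-well layout")
  rows <- LETTERS[1:16]  # 384-well geometry: 16 rows x 24 columns
  idx <- seq_len(n) + 6L  # continue after the control row
  unk <- data.frame(
    well = paste0(rows[(idx - 1L) %/% 24L + 1L], (idx - 1L) %% 24L + 1L),
    sample = sprintf("S%03d", seq_len(n)),
    role = "unknown",
    expected_genotype = NA_character_,
    genotype = genotypes,
    stringsAsFactors = FALSE)
  rbind(ctrl, unk)
}

#' Simulate a fluorescence plate from known genotypes
#'
#' Draws each well's FAM/HEX RFU pair from its class cluster (NTC wells
#' from the background cluster), truncated at zero.  The unit normal
#' deviates depend only on the seed and the number of wells, so plates
#' simulated with the same seed but different spreads use coupled noise:
#' widening `sd` moves every well along a fixed ray from its centre,
#' which makes accuracy-versus-noise sweeps monotone rather than jittery.
#'
#' @param layout a layout `data.frame` (see [plate_layout()]) with
#'   columns `well`, `sample`, `role`, `genotype`
#' @param model a [cluster_model()]
#' @param assay assay id stamped on the plate
#' @param seed integer seed; identical seeds give identical plates
#' @return list with `plate` (ready for [normalize_plate()]) and `truth`
#'   (the layout)
#' @export
simulate_plate <- function(layout, model, assay = "Ppe.CR.1-1", seed = 1) {
  stopifnot(inherits(model, "cluster_model"))
  need <- c("well", "sample", "role", "genotype")
  if (!all(need %in% names(layout)))
    stopf("layout needs columns: %s", paste(need, collapse = ", "))
  cls <- ifelse(layout$role == "ntc", "NTC", layout$genotype)
  if (any(!cls %in% rownames(model$means)))
    stopf("layout genotype outside the cluster model classes")
  n <- nrow(layout)
  set.seed(seed)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  mu <- model$means[cls, , drop = FALSE]
  rfu <- mu + model$sd * z
  rfu[rfu < 0] <- 0  # fluorescence cannot go negative
  plate <- data.frame(
    assay = assay, well = layout$well, sample = layout$sample,
    role = layout$role,
    expected_genotype = layout$expected_genotype %||% NA_character_,
    rfu_fam = rfu[, 1L], rfu_hex = rfu[, 2L], stringsAsFactors = FALSE)
  list(plate = plate, truth = layout)
}

#' Simulate a breeding cohort with known diplotypes and phenotypes
#'
#' Draws each individual's two haplotypes independently from the allele
#' frequencies (Hardy-Weinberg pairing; default frequencies proportional
#' to the panel's carrier counts), derives the unphased four-marker
#' genotype vector, and assigns a chill-hour phenotype centred on the
#' true diplotype's expected range: the midpoint for two-sided ranges,
#' the bound offset inward by 100 CH for open ranges (the granularity of
#' the forcing design), plus Gaussian noise, floored at 100 CH.  Class
#' pairs without a published range use the fallback band of
#' [resolve_diplotype()].  Missing calls are injected at the requested
#' rate.
#'
#' The unit noise deviates depend only on the seed and `n`, so cohorts
#' with the same seed and growing `noise_sd` share their draws: each
#' phenotype moves monotonically away from its range centre, and
#' prediction accuracy degrades monotonically in `noise_sd`.
#'
#' @param n number of individuals
#' @param panel a `cr_panel`
#' @param freqs allele frequencies (named by allele id, summing to 1);
#'   default proportional to carrier counts
#' @param noise_sd phenotype noise standard deviation in CH (default 100,
#'   matching the 100-CH resolution of forcing phenotyping)
#' @param missing_rate per-call probability of a missing genotype
#' @param seed integer seed
#' @return list with `truth` (per individual: alleles, label, expected
#'   range bounds, `true_ch`) and `genotypes` (n x markers matrix of
#'   calls, `NA` where missing)
#' @export
simulate_cohort <- function(n, panel = builtin_ppecr1(), freqs = NULL,
                            noise_sd = 100, missing_rate = 0, seed = 1) {
  stopifnot(n >= 1)
  a <- panel$alleles
  if (is.null(freqs)) {
    freqs <- a$carrier_count / sum(a$carrier_count)
    names(freqs) <- a$allele_id
  }
  if (is.null(names(freqs)) || !setequal(names(freqs), as.character(a$allele_id)))
    stopf("freqs must be named by the panel allele ids")
  freqs <- freqs[as.character(a$allele_id)]
  if (abs(sum(freqs) - 1) > 1e-8) stopf("allele frequencies must sum to 1")
  if (any(freqs < 0)) stopf("allele frequencies must be non-negative")
  set.seed(seed)
  pick <- matrix(sample.int(nrow(a), 2L * n, replace = TRUE, prob = freqs),
                 ncol = 2L)
  z <- stats::rnorm(n)
  miss <- matrix(stats::runif(n * nrow(panel$markers)) < missing_rate,
                 nrow = n)
  i <- pmin(pick[, 1L], pick[, 2L])
  j <- pmax(pick[, 1L], pick[, 2L])
  label <- character(n); low <- numeric(n); high <- numeric(n)
  kind <- character(n); mid <- numeric(n); fallback <- logical(n)
  geno <- matrix(NA_character_, nrow = n, ncol = nrow(panel$markers),
                 dimnames = list(NULL, panel$markers$assay_id))
  for (k in seq_len(n)) {
    label[k] <- class_pair_label(a$cr_class[i[k]], a$cr_class[j[k]])
    lr <- label_range(label[k], panel, a$allele_id[i[k]], a$allele_id[j[k]])
    kind[k] <- lr$range$kind
    low[k] <- lr$range$low %||% NA_real_
    high[k] <- lr$range$high %||% NA_real_
    fallback[k] <- lr$fallback
    mid[k] <- range_midpoint(lr$range)
    geno[k, ] <- combine_patterns(a$pattern[i[k]], a$pattern[j[k]])
  }
  geno[miss] <- NA_character_
  truth <- data.frame(
    sample = sprintf("S%04d", seq_len(n)),
    allele_x = a$allele_id[i], allele_y = a$allele_id[j],
    label = label, expected_kind = kind, expected_low = low,
    expected_high = high, range_fallback = fallback,
    true_ch = pmax(100, mid + noise_sd * z),
    stringsAsFactors = FALSE)
  list(truth = truth, genotypes = geno)
}
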