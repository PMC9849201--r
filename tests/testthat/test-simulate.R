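test_that("zero spread puts every well exactly at its cluster centre", {
  model <- cluster_model(sd = 0)
  lay <- plate_layout(c("AA", "AB", "BB"))
  sim <- simulate_plate(lay, model, seed = 1)
  mu <- model$means
  cls <- ifelse(sim$truth$role == "ntc", "NTC", sim$truth$genotype)
  expect_equal(sim$plate$rfu_fam, unname(mu[cls, 1]))
  expect_equal(sim$plate$rfu_hex, unname(mu[cls, 2]))
})

test_that("plates are reproducible under a fixed seed", {
  model <- cluster_model(separation = 8)
  lay <- plate_layout(rep(c("AA", "AB", "BB"), 10))
  s1 <- simulate_plate(lay, model, seed = 42)
  s2 <- simulate_plate(lay, model, seed = 42)
  expect_identical(s1$plate, s2$plate)
  s3 <- simulate_plate(lay, model, seed = 43)
  expect_false(identical(s1$plate, s3$plate))
})

test_that("well-separated clusters are called perfectly", {
  model <- cluster_model(separation = 10)
  lay <- plate_layout(rep(c("AA", "AB", "BB"), 30))
  for (assay in names(default_thresholds())) {
    sim <- simulate_plate(lay, model, assay = assay, seed = 5)
    calls <- call_genotypes(normalize_plate(sim$plate))
    truth <- ifelse(sim$truth$role == "ntc", "NOAMP", sim$truth$genotype)
    expect_equal(mean(calls$call == truth), 1, info = assay)
  }
})

test_that("calling accuracy degrades monotonically as clusters widen", {
  lay <- plate_layout(rep(c("AA", "AB", "BB"), 40))
  acc_at <- function(sd) {
    model <- cluster_model(sd = sd)
    mean(sapply(1:5, function(s) {
      sim <- simulate_plate(lay, model, assay = "Ppe.CR.1-4", seed = s)
      calls <- call_genotypes(normalize_plate(sim$plate))
      truth <- ifelse(sim$truth$role == "ntc", "NOAMP", sim$truth$genotype)
      mean(calls$call == truth)
    }))
  }
  accs <- vapply(c(25, 100, 200, 400), acc_at, 0)
  expect_true(all(diff(accs) <= 0))
  expect_equal(accs[1], 1)
})

test_that("cohorts honour frequencies, noise and missingness settings", {
  panel <- builtin_ppecr1()
  # single-allele population: everyone is M|M
  f <- setNames(c(0, 0, 1, 0, 0, 0, 0),
                panel$alleles$allele_id[order(panel$alleles$allele_id)])
  f <- f[as.character(panel$alleles$allele_id)]
  f[] <- 0; f["5"] <- 1
  co <- simulate_cohort(50, panel, freqs = f, noise_sd = 0, seed = 2)
  expect_true(all(co$truth$label == "M|M"))
  expect_true(all(co$genotypes == rep(c("BB", "BB", "AA", "BB"),
                                      each = 50)))
  # frequencies must be valid
  expect_error(simulate_cohort(10, panel, freqs = f * 2), "sum to 1")
  expect_error(simulate_cohort(10, panel, freqs = c(a = 1)), "allele ids")

  # carrier proportions track the default frequencies (binomial 3 sd)
  co2 <- simulate_cohort(1000, panel, seed = 9)
  draws <- c(co2$truth$allele_x, co2$truth$allele_y)
  p <- panel$alleles$carrier_count / sum(panel$alleles$carrier_count)
  names(p) <- panel$alleles$allele_id
  for (id in names(p)) {
    obs <- mean(draws == as.integer(id))
    se <- sqrt(p[[id]] * (1 - p[[id]]) / length(draws))
    expect_lt(abs(obs - p[[id]]), 3 * se + 1e-9)
  }

  # missing calls appear at roughly the requested rate
  co3 <- simulate_cohort(500, panel, missing_rate = 0.1, seed = 4)
  expect_gt(mean(is.na(co3$genotypes)), 0.07)
  expect_lt(mean(is.na(co3$genotypes)), 0.13)
  expect_true(all(!is.na(simulate_cohort(100, panel, seed = 4)$genotypes)))
})

test_that("noise-free cohorts evaluate perfectly in every diplotype group", {
  co <- simulate_cohort(400, noise_sd = 0, seed = 6)
  acc <- evaluate_predictions(data.frame(sample = co$truth$sample,
                                         label = co$truth$label,
                                         actual_ch = co$truth$true_ch))
  expect_true(all(acc$by_group$accuracy_pct == 100))
  expect_equal(acc$overall$accuracy_pct, 100)
})

test_that("phenotype accuracy degrades monotonically with noise", {
  acc_at <- function(noise_sd) {
    mean(sapply(1:5, function(s) {
      co <- simulate_cohort(300, noise_sd = noise_sd, seed = s)
      evaluate_predictions(
        data.frame(label = co$truth$label,
                   actual_ch = co$truth$true_ch))$overall$accuracy_pct
    }))
  }
  accs <- vapply(c(0, 100, 300, 600), acc_at, 0)
  expect_equal(accs[1], 100)
  expect_true(all(diff(accs) <= 0))
})

test_that("simulated plates survive the whole pipeline", {
  panel <- builtin_ppecr1()
  co <- simulate_cohort(40, noise_sd = 0, seed = 21)
  model <- cluster_model(separation = 10)
  plates <- lapply(seq_along(panel$markers$assay_id), function(k) {
    assay <- panel$markers$assay_id[k]
    lay <- plate_layout(co$genotypes[, k])
    lay$sample[lay$role == "unknown"] <- co$truth$sample
    simulate_plate(lay, model, assay = assay, seed = 30 + k)$plate
  })
  res <- run_pipeline(plates, panel,
                      phenotypes = data.frame(sample = co$truth$sample,
                                              actual_ch = co$truth$true_ch))
  # the calling stage is lossless at this separation, so the pipeline
  # must land exactly where direct inference from the true genotypes does
  direct <- infer_diplotypes(calls_from_genotypes(co$genotypes,
                                                  co$truth$sample), panel)
  d <- res$diplotypes
  ord <- match(direct$sample, d$sample)
  expect_equal(d$label[ord], direct$label)
  expect_equal(d$allele_x[ord], direct$allele_x)
  # frequency policy may overrule a rare true diplotype whose genotype is
  # also explained by a commoner pair; everywhere it agrees with the
  # truth the prediction must score correct
  agree <- d$label[match(co$truth$sample, d$sample)] == co$truth$label
  expect_true(all(res$predictions$correct[
    match(co$truth$sample[agree], res$predictions$sample)]))
  expect_gt(mean(agree), 0.9)
})
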