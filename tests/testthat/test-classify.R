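test_that("max_credible_af evaluates prevalence * allelic_contribution / penetrance", {
  expect_identical(max_credible_af(0.0012, 0.01, 0.16), 0.0012 * 0.01 / 0.16)
  expect_equal(max_credible_af(0.0012, 0.01, 0.16), 7.5e-5)
  # identity limit: full contribution, full penetrance
  for (p in c(0.001, 0.25, 1)) expect_equal(max_credible_af(p, 1, 1), p)
  expect_equal(max_credible_af(0.0012, 0.01, 0.327), 0.0012 * 0.01 / 0.327)
})

test_that("credible_af_params enforces ranges and the cutoff-only-relaxes invariant", {
  expect_error(credible_af_params(0.0012, 0.01, 0), class = "af_domain_error")
  expect_error(credible_af_params(1.5, 0.01, 0.16), class = "af_validation_error")
  expect_error(credible_af_params(0.0012, 0.01, 0.16, applied_cutoff = 1e-6),
               class = "af_validation_error")  # stricter than the bound
  p <- credible_af_params(0.0012, 0.01, 0.16, applied_cutoff = 0.001)
  expect_equal(p$applied_cutoff, 0.001)
  expect_true(p$applied_cutoff >= max_credible_af(p))
})

test_that("max_credible_af is monotone in each parameter", {
  set.seed(7)
  for (i in 1:50) {
    prev <- runif(1, 1e-5, 0.01)
    ac <- runif(1, 0.001, 1)
    pen <- runif(1, 0.05, 1)
    eps <- 1.1
    expect_gt(max_credible_af(min(prev * eps, 1), ac, pen),
              max_credible_af(prev, ac, pen))
    expect_gt(max_credible_af(prev, min(ac * eps, 1), pen),
              max_credible_af(prev, ac, pen))
    expect_lt(max_credible_af(prev, ac, min(pen * eps, 1)),
              max_credible_af(prev, ac, pen))
  }
})

test_that("flag_variants flags inclusively per population", {
  cls <- brs_classified()
  a226v <- cls[cls$protein_change == "A226V", ]
  expect_true(a226v$flagged)
  expect_equal(sort(strsplit(a226v$flagged_populations, ",")[[1]]),
               c("EAS", "TWB"))
  fm <- per_population_flags(cls)
  expect_equal(sum(fm[cls$protein_change == "A226V", ]), 2L)

  # boundary: a frequency exactly at the cutoff flags (>= is inclusive);
  # the SCNN1A row sits exactly at 0.001 in the Japanese reference panel
  scnn1a <- cls[cls$gene == "SCNN1A", ]
  expect_true(grepl("JPN3K", scnn1a$flagged_populations))

  # all-absent frequency map never flags
  reg <- brs_registry()[1, ]
  empty <- annotate(reg, frequency_table(data.frame(
    variant = "none", population = "EAS", frequency = 0.5)))
  flagged <- flag_variants(empty, 0.001)
  expect_false(flagged$flagged)
  expect_identical(flagged$flagged_populations, "")
})

test_that("flagging is monotone in the cutoff", {
  sim <- simulate_variant_data(sim_config(seed = 11L, n_variants = 150L))
  reg <- sim$registry_a
  reg$sources <- "A"
  reg$key <- variant_key(reg$gene, reg$transcript, reg$cdna_change, reg$dbsnp_id)
  ann <- annotate(reg, sim$frequencies)
  cutoffs <- c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2)
  flagged_sets <- lapply(cutoffs, function(ct) {
    cls <- flag_variants(ann, ct)
    cls$key[cls$flagged]
  })
  for (i in seq_along(cutoffs)[-1]) {
    expect_true(all(flagged_sets[[i]] %in% flagged_sets[[i - 1]]),
                info = sprintf("cutoff %g vs %g", cutoffs[i], cutoffs[i - 1]))
  }
})

test_that("restricted_to_group tests containment of the flagged populations", {
  cls <- brs_classified()
  grouping <- brs_grouping()
  asian <- restricted_to_group(cls, grouping, "Asian")
  expect_true(asian[cls$protein_change == "A226V"])
  expect_false(asian[cls$protein_change == "R27H"])   # American only
  expect_false(asian[cls$protein_change == "E61*"])   # spans ancestries
  expect_error(restricted_to_group(cls, grouping, "Martian"),
               class = "af_config_error")

  labels <- restriction_label(cls, grouping)
  expect_equal(labels[cls$protein_change == "R27H"], "American")
  expect_true(is.na(labels[cls$protein_change == "E61*"]))
})

test_that("classification_report tallies rows and totals", {
  cls <- brs_classified()
  rep <- classification_report(cls, brs_grouping())
  expect_equal(nrow(rep$table), 18L)
  expect_equal(rep$totals$n_flagged, 18L)
  expect_equal(unname(rep$totals$flagged_by_gene["SCN5A"]), 6L)
  expect_output(print(rep), "18 flagged")

  empty <- cls[0, , drop = FALSE]
  attr(empty, "populations") <- attr(cls, "populations")
  rep0 <- classification_report(empty)
  expect_equal(nrow(rep0$table), 0L)
  expect_equal(rep0$totals$n, 0L)
})

test_that("synthetic plants drive the totals reported for a classified run", {
  sim <- simulate_variant_data(sim_config(seed = 5L, n_variants = 120L))
  reg <- merge_registries(
    transform(sim$registry_a, sources = "A",
              key = variant_key(gene, transcript, cdna_change, dbsnp_id)),
    transform(sim$registry_b, sources = "B",
              key = variant_key(gene, transcript, cdna_change, dbsnp_id))
  )$registry
  cls <- flag_variants(annotate(reg, sim$frequencies), 0.001)
  rep <- classification_report(cls)
  expect_equal(rep$totals$n_flagged, sum(sim$truth$flagged))
})
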