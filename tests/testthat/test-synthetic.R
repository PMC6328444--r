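sim_registry_pair <- function(sim) {
  list(a = transform(sim$registry_a, sources = "A",
                     key = variant_key(gene, transcript, cdna_change, dbsnp_id)),
       b = transform(sim$registry_b, sources = "B",
                     key = variant_key(gene, transcript, cdna_change, dbsnp_id)))
}

test_that("simulation is deterministic given the seed, including written files", {
  cfg <- sim_config(seed = 123L, n_variants = 80L)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_variant_data(cfg, outdir = d1)
  s2 <- simulate_variant_data(cfg, outdir = d2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$frequencies$entries, s2$frequencies$entries)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
  s3 <- simulate_variant_data(sim_config(seed = 124L, n_variants = 80L))
  expect_false(identical(s1$truth$flagged, s3$truth$flagged))
})

test_that("default configuration reproduces the worked-example source sizes", {
  sim <- simulate_variant_data(sim_config(seed = 2L))
  expect_equal(nrow(sim$registry_a), 405L)
  expect_equal(nrow(sim$registry_b), 68L)
  expect_equal(sum(sim$truth$in_a & sim$truth$in_b), 33L)
  r <- sim_registry_pair(sim)
  m <- merge_registries(r$a, r$b)
  expect_equal(m$summary$n_total, 440L)
  expect_equal(m$summary$n_overlap, 33L)
})

test_that("zero flag rates plant nothing and the pipeline flags nothing", {
  rates <- sim_config()$flag_rates
  rates$rate <- 0
  sim <- simulate_variant_data(sim_config(seed = 3L, n_variants = 100L,
                                          flag_rates = rates))
  expect_false(any(sim$truth$flagged))
  r <- sim_registry_pair(sim)
  cls <- flag_variants(annotate(merge_registries(r$a, r$b)$registry,
                                sim$frequencies), 0.001)
  expect_false(any(cls$flagged))
})

test_that("generated HGVS strings all classify to the ground-truth mutation type", {
  sim <- simulate_variant_data(sim_config(seed = 9L, n_variants = 250L))
  r <- sim_registry_pair(sim)
  m <- merge_registries(r$a, r$b)$registry
  types <- classify_mutation_types(m)
  truth_types <- sim$truth$mutation_type[match(m$key, sim$truth$key)]
  expect_identical(types, truth_types)
})

test_that("recovery of planted flags, populations and types is exact", {
  for (seed in c(4L, 21L)) {
    sim <- simulate_variant_data(sim_config(seed = seed, n_variants = 200L))
    r <- sim_registry_pair(sim)
    cls <- flag_variants(annotate(merge_registries(r$a, r$b)$registry,
                                  sim$frequencies), 0.001)
    rec <- recover_truth(sim$truth, cls)
    expect_true(rec$perfect)
    expect_equal(rec$flag_agreement, 1)
    expect_equal(rec$type_agreement, 1)
  }
})

test_that("planted Asian-only scenarios are exactly the Asian-restricted variants", {
  sim <- simulate_variant_data(sim_config(seed = 14L, n_variants = 300L))
  r <- sim_registry_pair(sim)
  cls <- flag_variants(annotate(merge_registries(r$a, r$b)$registry,
                                sim$frequencies), 0.001)
  grouping <- population_grouping(list(Asian = c("EAS", "SAS", "JEW",
                                                 "JPN3K", "TWB")))
  got <- restricted_to_group(cls, grouping, "Asian")
  truth <- sim$truth[match(cls$key, sim$truth$key), ]
  # every asian-scenario plant is restricted; other scenarios never are
  # (the european/american/broad population sets are disjoint from Asian
  # except SAS, which only the broad scenario can pick)
  asian_plants <- !is.na(truth$scenario) & truth$scenario == "asian"
  expect_true(all(got[asian_plants]))
  broad_asian <- !is.na(truth$scenario) & truth$scenario == "broad" &
    truth$flagged_populations == "SAS"
  expect_true(all(!got[truth$flagged & !asian_plants & !broad_asian]))
})

test_that("realized per-stratum flag rates sit within 3 binomial standard errors", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = 100L + seed, n_variants = 300L)
    sim <- simulate_variant_data(cfg)
    truth <- sim$truth
    gc <- ifelse(truth$gene == "SCN5A", "SCN5A", "other")
    for (i in seq_len(nrow(cfg$flag_rates))) {
      rate <- cfg$flag_rates$rate[i]
      sel <- gc == cfg$flag_rates$gene_class[i] &
        truth$mutation_type == cfg$flag_rates$mutation_type[i]
      n <- sum(sel)
      if (n == 0L) next
      realized <- mean(truth$flagged[sel])
      se <- sqrt(rate * (1 - rate) / n)
      expect_lte(abs(realized - rate), 3 * se + 1e-12,
                 label = sprintf("seed %d stratum %s/%s", seed,
                                 cfg$flag_rates$gene_class[i],
                                 cfg$flag_rates$mutation_type[i]))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gene_mix = c(SCN5A = 0.5, KCNH2 = 0.4)),
               class = "af_config_error")
  expect_error(sim_config(overlap_fraction = 0.9, b_exclusive_fraction = 0.2),
               class = "af_config_error")
  bad_rates <- sim_config()$flag_rates
  bad_rates$rate[1] <- 1.5
  expect_error(sim_config(flag_rates = bad_rates), class = "af_config_error")
})

test_that("misaligned keys raise an alignment error in recovery", {
  sim <- simulate_variant_data(sim_config(seed = 6L, n_variants = 50L))
  r <- sim_registry_pair(sim)
  cls <- flag_variants(annotate(merge_registries(r$a, r$b)$registry,
                                sim$frequencies), 0.001)
  expect_error(recover_truth(sim$truth, cls[-1, ]),
               class = "af_alignment_error")
})
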