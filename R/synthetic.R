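# Seeded synthetic registries and frequency tables with known ground
# truth, for end-to-end testing without any database download.

default_populations <- c("NFE", "FIN", "AMR", "AFR", "JEW", "EAS", "SAS",
                         "JPN3K", "TWB")

# Flagged variants are planted into one of these ancestry scenarios.
default_scenarios <- list(
  asian = c("EAS", "SAS", "JEW", "JPN3K", "TWB"),
  european = c("NFE", "FIN"),
  american = c("AMR"),
  broad = c("NFE", "FIN", "AMR", "SAS")
)

default_flag_rates <- function() {
  data.frame(
    gene_class = rep(c("SCN5A", "other"), each = 4L),
    mutation_type = rep(c("missense", "nonsense", "frameshift", "splice"), 2L),
    rate = c(0.02, 0.025, 0, 0,   # SCN5A
             0.22, 0.025, 0, 0),  # non-SCN5A
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic variant-data generator
#'
#' Defaults emulate the composition of the worked BrS registry: 440
#' variants, 87.5% in SCN5A, the published mutation-type mix
#' (304 missense, 40 nonsense, 73 frameshift, 23 splice), two partially
#' overlapping source databases sized 405 and 68 with 33 shared records,
#' and per-stratum flagging rates close to the observed ones (higher for
#' non-SCN5A missense variants, zero for frameshift and splice).
#'
#' @param seed Integer RNG seed; all randomness flows from it.
#' @param n_variants Number of distinct variants to generate.
#' @param gene_mix Named proportions per gene (must sum to 1).
#' @param type_mix Named proportions over mutation types missense /
#'   nonsense / frameshift / splice (must sum to 1).
#' @param overlap_fraction Fraction of variants present in both sources.
#' @param b_exclusive_fraction Fraction present only in source B.
#' @param flag_rates `data.frame` with columns `gene_class`
#'   (`"SCN5A"`/`"other"`), `mutation_type` and `rate`: probability a
#'   variant of that stratum is planted above the cutoff.
#' @param scenarios Named list of population-code sets a planted variant's
#'   above-cutoff frequencies are confined to.
#' @param scenario_probs Named probabilities over `scenarios`.
#' @param populations All population codes emitted.
#' @param cutoff Allele-frequency cutoff the plants are placed above.
#' @return A `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 440L,
                       gene_mix = c(SCN5A = 385, CACNA1C = 12, SCN10A = 11,
                                    TRPM4 = 8, KCNB2 = 5, KCNT1 = 5,
                                    RANGRF = 4, SCN3B = 4, HCN4 = 3,
                                    PKP2 = 3) / 440,
                       type_mix = c(missense = 304, nonsense = 40,
                                    frameshift = 73, splice = 23) / 440,
                       overlap_fraction = 33 / 440,
                       b_exclusive_fraction = 35 / 440,
                       flag_rates = default_flag_rates(),
                       scenarios = default_scenarios,
                       scenario_probs = c(asian = 14, european = 2,
                                          american = 1, broad = 1) / 18,
                       populations = default_populations,
                       cutoff = 0.001) {
  if (abs(sum(gene_mix) - 1) > 1e-9 || abs(sum(type_mix) - 1) > 1e-9) {
    af_stop("gene_mix and type_mix must each sum to 1", "af_config_error")
  }
  if (abs(sum(scenario_probs) - 1) > 1e-9) {
    af_stop("scenario_probs must sum to 1", "af_config_error")
  }
  stopifnot(setequal(names(scenario_probs), names(scenarios)),
            all(unlist(scenarios) %in% populations))
  if (any(flag_rates$rate < 0 | flag_rates$rate > 1)) {
    af_stop("flag rates must be probabilities in [0,1]", "af_config_error")
  }
  if (overlap_fraction < 0 || b_exclusive_fraction < 0 ||
      overlap_fraction + b_exclusive_fraction > 1) {
    af_stop("source fractions must be proportions with overlap + B-exclusive <= 1",
            "af_config_error")
  }
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 gene_mix = gene_mix, type_mix = type_mix,
                 overlap_fraction = overlap_fraction,
                 b_exclusive_fraction = b_exclusive_fraction,
                 flag_rates = flag_rates, scenarios = scenarios,
                 scenario_probs = scenario_probs, populations = populations,
                 cutoff = cutoff),
            class = "sim_config")
}

# deterministic pseudo-RefSeq id per gene (no RNG involved)
pseudo_transcript <- function(gene) {
  if (gene == "SCN5A") return("NM_198056.2")
  digits <- sum(utf8ToInt(gene) * seq_along(utf8ToInt(gene))) %% 1000000L
  sprintf("NM_%06d.2", digits)
}

lookup_flag_rate <- function(flag_rates, gene, type) {
  gc <- ifelse(gene == "SCN5A", "SCN5A", "other")
  i <- match(paste(gc, type), paste(flag_rates$gene_class, flag_rates$mutation_type))
  r <- flag_rates$rate[i]
  r[is.na(r)] <- 0
  r
}

#' Generate a seeded synthetic dataset with known ground truth
#'
#' Produces two partially overlapping registries (sources `"A"` and
#' `"B"`), a per-population frequency table, and the ground truth of
#' which variants were planted above the cutoff and in which
#' populations. Planted frequencies are drawn uniformly in
#' `[cutoff, 10 * cutoff]` within the planted populations; all other
#' frequencies are drawn uniformly in `[0, cutoff)` or left absent with
#' probability 0.5. HGVS strings are generated from a grammar covering
#' missense, nonsense, frameshift and splice variants. Output is
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory: when given, `registry_a.tsv`,
#'   `registry_b.tsv` and `frequencies.tsv` are written there in the
#'   formats the pipeline readers consume.
#' @return A list with `registry_a`, `registry_b` (data frames in
#'   registry-file column layout), `frequencies` (a `frequency_table`),
#'   `truth` (per-variant: `key`, `gene`, `mutation_type`, `in_a`,
#'   `in_b`, `flagged`, `flagged_populations`, `scenario`) and `files`
#'   (paths, when `outdir` was given).
#' @export
simulate_variant_data <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_variants
  pops <- config$populations
  nt <- c("A", "C", "G", "T")

  genes <- sample(names(config$gene_mix), n, replace = TRUE,
                  prob = config$gene_mix)
  types <- sample(names(config$type_mix), n, replace = TRUE,
                  prob = config$type_mix)

  # unique cDNA positions per gene so keys never collide
  cpos <- integer(n)
  for (g in unique(genes)) {
    i <- which(genes == g)
    cpos[i] <- sample.int(6000L, length(i))
  }
  ppos <- pmax(1L, ceiling(cpos / 3))
  ref_nt <- sample(nt, n, replace = TRUE)
  alt_nt <- vapply(ref_nt, function(r) sample(setdiff(nt, r), 1L), character(1))
  ref_aa <- sample(aa_letters, n, replace = TRUE)
  alt_aa <- vapply(ref_aa, function(r) sample(setdiff(aa_letters, r), 1L),
                   character(1))

  cdna <- character(n)
  protein <- character(n)
  for (i in seq_len(n)) {
    cdna[i] <- switch(types[i],
      missense = ,
      nonsense = paste0(cpos[i], ref_nt[i], ">", alt_nt[i]),
      frameshift = paste0(cpos[i], "del", ref_nt[i]),
      splice = paste0(cpos[i], sample(c("+1", "+2", "-1", "-2"), 1L),
                      ref_nt[i], ">", alt_nt[i]))
    protein[i] <- switch(types[i],
      missense = paste0(ref_aa[i], ppos[i], alt_aa[i]),
      nonsense = paste0(ref_aa[i], ppos[i], "*"),
      frameshift = paste0(ref_aa[i], ppos[i], "fs"),
      splice = "")
  }
  transcript <- vapply(genes, pseudo_transcript, character(1))
  dbsnp <- sprintf("rs%08d", sample.int(99999999L, n))
  key <- variant_key(genes, transcript, cdna, dbsnp)

  # source membership: first n_overlap in both, next n_b_only in B only
  n_overlap <- round(config$overlap_fraction * n)
  n_b_only <- round(config$b_exclusive_fraction * n)
  perm <- sample.int(n)
  in_b <- seq_len(n) %in% perm[seq_len(n_overlap + n_b_only)]
  in_a <- !(seq_len(n) %in% perm[n_overlap + seq_len(n_b_only)])

  # plants
  rate <- lookup_flag_rate(config$flag_rates, genes, types)
  planted <- stats::runif(n) < rate
  scen <- rep(NA_character_, n)
  flagged_pops <- character(n)
  entries <- list()
  for (i in seq_len(n)) {
    if (planted[i]) {
      scen[i] <- sample(names(config$scenario_probs), 1L,
                        prob = config$scenario_probs)
      set <- config$scenarios[[scen[i]]]
      k <- sample.int(min(3L, length(set)), 1L)
      chosen <- sort(sample(set, k))
      flagged_pops[i] <- paste(chosen, collapse = ",")
    } else {
      chosen <- character(0)
    }
    f <- stats::runif(length(chosen), config$cutoff, 10 * config$cutoff)
    other <- setdiff(pops, chosen)
    present <- stats::runif(length(other)) < 0.5
    bg <- stats::runif(sum(present), 0, config$cutoff)
    # background draws sit strictly below the cutoff (P(== cutoff) = 0)
    pop_i <- c(chosen, other[present])
    val_i <- c(f, bg)
    if (length(pop_i)) {
      entries[[length(entries) + 1L]] <- data.frame(
        variant = key[i], population = pop_i, frequency = val_i,
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(variant = character(), population = character(),
               frequency = numeric(), stringsAsFactors = FALSE)

  reg_cols <- function(idx, cls) {
    data.frame(gene = genes[idx], transcript = transcript[idx],
               cdna_change = cdna[idx], protein_change = protein[idx],
               dbsnp_id = dbsnp[idx], reported_class = cls,
               stringsAsFactors = FALSE)
  }
  registry_a <- reg_cols(which(in_a), "disease-causing")
  registry_b <- reg_cols(which(in_b), "pathogenic")
  truth <- data.frame(key = key, gene = genes, mutation_type = types,
                      in_a = in_a, in_b = in_b, flagged = planted,
                      flagged_populations = flagged_pops, scenario = scen,
                      stringsAsFactors = FALSE)
  ft <- frequency_table(entries)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- list(registry_a = file.path(outdir, "registry_a.tsv"),
                  registry_b = file.path(outdir, "registry_b.tsv"),
                  frequencies = file.path(outdir, "frequencies.tsv"))
    utils::write.table(registry_a, files$registry_a, sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.table(registry_b, files$registry_b, sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    write_frequency_tsv(ft, files$frequencies)
  }
  list(registry_a = registry_a, registry_b = registry_b, frequencies = ft,
       truth = truth, files = files)
}

#' Check pipeline output against synthetic ground truth
#'
#' The flagging rule is deterministic, so recovery must be perfect: every
#' planted variant flagged in exactly the planted populations, every
#' unplanted variant unflagged, and every mutation type recovered.
#'
#' @param truth The `truth` component of [simulate_variant_data()].
#' @param classified Output of [flag_variants()] run on the simulated
#'   files; must carry a `key` column aligned with the truth keys.
#' @return A list with `n`, `n_flag_mismatch`, `n_population_mismatch`,
#'   `n_type_mismatch`, `flag_agreement`, `type_agreement` and `perfect`.
#' @export
recover_truth <- function(truth, classified) {
  idx <- match(truth$key, classified$key)
  if (anyNA(idx) || nrow(classified) != nrow(truth)) {
    af_stop("variant keys of truth and pipeline output do not align",
            "af_alignment_error")
  }
  cls <- classified[idx, , drop = FALSE]
  flag_ok <- cls$flagged == truth$flagged
  pop_ok <- mapply(function(a, b) {
    setequal(strsplit(a, ",")[[1]], strsplit(b, ",")[[1]])
  }, cls$flagged_populations, truth$flagged_populations, USE.NAMES = FALSE)
  type_ok <- cls$mutation_type == truth$mutation_type
  res <- list(n = nrow(truth),
              n_flag_mismatch = sum(!flag_ok),
              n_population_mismatch = sum(!pop_ok),
              n_type_mismatch = sum(!type_ok),
              flag_agreement = if (nrow(truth)) mean(flag_ok) else 1,
              type_agreement = if (nrow(truth)) mean(type_ok) else 1)
  res$perfect <- res$n_flag_mismatch == 0L && res$n_population_mismatch == 0L &&
    res$n_type_mismatch == 0L
  res
}
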