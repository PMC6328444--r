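# Shared fixture builders. The packaged BrS tables are loaded once and
# cached; synthetic registries are built in code.

.fixture_cache <- new.env(parent = emptyenv())

brs_registry <- function() {
  if (is.null(.fixture_cache$registry)) {
    a <- read_registry(afreclass_example("brs_hgmd_flagged.tsv"), "HGMD")
    b <- read_registry(afreclass_example("brs_clinvar_flagged.tsv"), "ClinVar")
    .fixture_cache$registry <- merge_registries(a, b)$registry
  }
  .fixture_cache$registry
}

brs_frequencies <- function() {
  if (is.null(.fixture_cache$freq)) {
    .fixture_cache$freq <-
      read_frequency_tsv(afreclass_example("brs_flagged_frequencies.tsv"))
  }
  .fixture_cache$freq
}

brs_classified <- function(cutoff = 0.001) {
  key <- paste0("classified_", cutoff)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      flag_variants(annotate(brs_registry(), brs_frequencies()), cutoff)
  }
  .fixture_cache[[key]]
}

brs_grouping <- function() {
  if (is.null(.fixture_cache$grouping)) {
    .fixture_cache$grouping <-
      read_params(afreclass_example("brs_params.yaml"))$grouping
  }
  .fixture_cache$grouping
}

# n distinct records with deterministic keys key_<prefix><i>
toy_registry <- function(n, source = "SRC", prefix = "v") {
  if (n == 0L) {
    df <- data.frame(gene = character(), transcript = character(),
                     cdna_change = character(), protein_change = character(),
                     dbsnp_id = character(), reported_class = character(),
                     sources = character(), key = character(),
                     stringsAsFactors = FALSE)
    return(df)
  }
  ids <- paste0(prefix, seq_len(n))
  df <- data.frame(
    gene = "SCN5A", transcript = "NM_198056.2",
    cdna_change = paste0(seq_len(n), "00A>G"),
    protein_change = paste0("A", seq_len(n), "V"),
    dbsnp_id = paste0("rs", prefix, seq_len(n)),
    reported_class = "pathogenic", sources = source,
    stringsAsFactors = FALSE
  )
  df$cdna_change <- paste0(ids, df$cdna_change)  # make keys prefix-specific
  df$key <- variant_key(df$gene, df$transcript, df$cdna_change, df$dbsnp_id)
  df
}

write_temp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}
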