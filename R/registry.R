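# Registry ingestion, normalization, deduplication and N-way merging.

registry_required_cols <- c("gene", "transcript", "cdna_change", "protein_change")
registry_optional_cols <- c("dbsnp_id", "reported_class")

#' Normalize an HGVS change string
#'
#' Strips internal whitespace (tables often print spaced forms such as
#' `"677C > T"`) and normalizes typographic stop symbols to `*`.
#'
#' @param x Character vector of HGVS c.- or p.-style strings.
#' @return Character vector of normalized strings (`NA` preserved).
#' @examples
#' normalize_hgvs("677C > T")
#' @export
normalize_hgvs <- function(x) {
  out <- gsub("[[:space:]]+", "", x)
  out <- gsub("∗|✱|＊", "*", out)  # unicode asterisk variants
  out[is.na(x)] <- NA_character_
  out
}

#' Deduplication key for variant records
#'
#' The key is the normalized triple (gene, transcript without version,
#' whitespace-stripped cDNA change). When the cDNA change is absent the
#' dbSNP identifier substitutes for it. Registries from different source
#' databases are matched on this key when merged.
#'
#' @param gene,transcript,cdna_change,dbsnp_id Character vectors (recycled
#'   to a common length).
#' @return Character vector of keys.
#' @examples
#' variant_key("SCN5A", "NM_198056.2", "677C > T")
#' @export
variant_key <- function(gene, transcript, cdna_change, dbsnp_id = NA_character_) {
  n <- max(length(gene), length(transcript), length(cdna_change), length(dbsnp_id))
  gene <- rep_len(toupper(trimws(gene)), n)
  tx <- rep_len(sub("\\.[0-9]+$", "", trimws(transcript)), n)
  cdna <- rep_len(normalize_hgvs(cdna_change), n)
  rsid <- rep_len(trimws(as.character(dbsnp_id)), n)
  anchor <- ifelse(!is.na(cdna) & nzchar(cdna), cdna, paste0("rs:", rsid))
  paste(gene, tx, anchor, sep = "|")
}

#' Read a variant registry table
#'
#' Reads a tab-delimited registry extract with header columns
#' `gene`, `transcript`, `cdna_change`, `protein_change` and optionally
#' `dbsnp_id` and `reported_class`. HGVS strings are normalized, a
#' deduplication key is attached (see [variant_key()]), and the given
#' source label is recorded on every record. Rows with an empty gene
#' symbol, or with neither a cDNA nor a protein change, are rejected with
#' a warning; duplicate keys within one file are collapsed to the first
#' occurrence.
#'
#' @param path Path to a tab-delimited UTF-8 file with a header row.
#' @param source_label Label of the source database (e.g., `"HGMD"`).
#' @return A `data.frame` with columns `gene`, `transcript`,
#'   `cdna_change`, `protein_change`, `dbsnp_id`, `reported_class`,
#'   `sources` (`;`-separated labels) and `key`.
#' @export
read_registry <- function(path, source_label) {
  if (!file.exists(path)) {
    af_stop(sprintf("registry file not found: %s", path), "af_file_error")
  }
  stopifnot(is.character(source_label), length(source_label) == 1L, nzchar(source_label))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(registry_required_cols, names(raw))
  if (length(missing_cols)) {
    af_stop(sprintf("registry %s lacks required column(s): %s",
                    path, paste(missing_cols, collapse = ", ")),
            "af_format_error")
  }
  for (col in registry_optional_cols) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  if (nrow(raw) == 0L) {
    af_warn(sprintf("registry %s has no data rows", path), "af_empty_input")
    return(empty_registry())
  }
  df <- data.frame(
    gene = toupper(blank_to_na(raw$gene)),
    transcript = blank_to_na(raw$transcript),
    cdna_change = normalize_hgvs(blank_to_na(raw$cdna_change)),
    protein_change = normalize_hgvs(blank_to_na(raw$protein_change)),
    dbsnp_id = blank_to_na(raw$dbsnp_id),
    reported_class = blank_to_na(raw$reported_class),
    stringsAsFactors = FALSE
  )
  bad_gene <- is.na(df$gene)
  bad_change <- is.na(df$cdna_change) & is.na(df$protein_change)
  drop <- bad_gene | bad_change
  if (any(drop)) {
    af_warn(sprintf("registry %s: rejected %d row(s) with empty gene or no HGVS change",
                    path, sum(drop)), "af_rejected_rows")
    df <- df[!drop, , drop = FALSE]
  }
  df$sources <- source_label
  df$key <- variant_key(df$gene, df$transcript, df$cdna_change, df$dbsnp_id)
  dup <- duplicated(df$key)
  if (any(dup)) {
    af_warn(sprintf("registry %s: collapsed %d duplicate key(s)", path, sum(dup)),
            "af_duplicate_keys")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

empty_registry <- function() {
  data.frame(gene = character(), transcript = character(),
             cdna_change = character(), protein_change = character(),
             dbsnp_id = character(), reported_class = character(),
             sources = character(), key = character(),
             stringsAsFactors = FALSE)
}

#' Merge two deduplicated variant registries
#'
#' Records sharing a deduplication key are merged into one record whose
#' `sources` field is the union of the source labels. A record carrying a
#' dbSNP identifier that appears in the other registry under a different
#' gene raises a merge-conflict error listing both records.
#'
#' @param a,b Registries as returned by [read_registry()].
#' @return A list with elements `registry` (the merged `data.frame`) and
#'   `summary`, a `merge_summary` with counts `n_source_a`, `n_source_b`,
#'   `n_overlap` and `n_total` satisfying
#'   `n_total == n_source_a + n_source_b - n_overlap`.
#' @examples
#' a <- data.frame(gene = "SCN5A", transcript = "NM_198056.2",
#'                 cdna_change = "677C>T", protein_change = "A226V",
#'                 dbsnp_id = "rs199473561", reported_class = "disease-causing",
#'                 sources = "HGMD")
#' a$key <- variant_key(a$gene, a$transcript, a$cdna_change)
#' merge_registries(a, a)$summary
#' @export
merge_registries <- function(a, b) {
  for (r in list(a, b)) {
    if (anyDuplicated(r$key)) {
      af_stop("input registry contains duplicate deduplication keys",
              "af_precondition_error")
    }
  }
  check_dbsnp_conflicts(a, b)
  shared <- intersect(a$key, b$key)
  merged <- a
  if (length(shared)) {
    ia <- match(shared, a$key)
    ib <- match(shared, b$key)
    merged$sources[ia] <- mapply(union_sources, a$sources[ia], b$sources[ib])
    # prefer a's metadata; fill gaps from b
    for (col in c("protein_change", "dbsnp_id", "reported_class")) {
      fill <- is.na(merged[[col]][ia]) & !is.na(b[[col]][ib])
      merged[[col]][ia[fill]] <- b[[col]][ib[fill]]
    }
  }
  merged <- rbind(merged, b[!(b$key %in% shared), , drop = FALSE])
  rownames(merged) <- NULL
  summary <- structure(
    list(n_source_a = nrow(a), n_source_b = nrow(b),
         n_overlap = length(shared), n_total = nrow(merged)),
    class = "merge_summary"
  )
  list(registry = merged, summary = summary)
}

union_sources <- function(x, y) {
  paste(sort(unique(c(strsplit(x, ";", fixed = TRUE)[[1]],
                      strsplit(y, ";", fixed = TRUE)[[1]]))), collapse = ";")
}

check_dbsnp_conflicts <- function(a, b) {
  ia <- !is.na(a$dbsnp_id)
  ib <- !is.na(b$dbsnp_id)
  common <- intersect(a$dbsnp_id[ia], b$dbsnp_id[ib])
  for (rs in common) {
    ga <- unique(a$gene[ia & a$dbsnp_id == rs])
    gb <- unique(b$gene[ib & b$dbsnp_id == rs])
    if (!setequal(ga, gb)) {
      af_stop(sprintf("merge conflict: %s maps to gene(s) %s in one registry and %s in the other",
                      rs, paste(ga, collapse = "/"), paste(gb, collapse = "/")),
              "af_merge_conflict")
    }
  }
  invisible(TRUE)
}

#' Merge any number of registries by pairwise folding
#'
#' @param ... Registries, or a single list of registries.
#' @return The merged `data.frame` (summaries of the intermediate pairwise
#'   merges are attached as attribute `"merge_summaries"`).
#' @export
merge_all <- function(...) {
  regs <- list(...)
  if (length(regs) == 1L && is.list(regs[[1]]) && !is.data.frame(regs[[1]])) {
    regs <- regs[[1]]
  }
  if (!length(regs)) return(empty_registry())
  out <- regs[[1]]
  summaries <- list()
  for (r in regs[-1]) {
    m <- merge_registries(out, r)
    out <- m$registry
    summaries[[length(summaries) + 1L]] <- m$summary
  }
  attr(out, "merge_summaries") <- summaries
  out
}

#' @export
print.merge_summary <- function(x, ...) {
  cat(sprintf("merge: %d + %d records, %d overlapping -> %d total\n",
              x$n_source_a, x$n_source_b, x$n_overlap, x$n_total))
  invisible(x)
}

#' Count registry records per gene
#'
#' @param registry A registry `data.frame`.
#' @return Named integer vector of per-gene counts, decreasing; sums to
#'   the registry size.
#' @export
gene_distribution <- function(registry) {
  if (!nrow(registry)) return(integer(0))
  counts <- table(registry$gene)
  out <- as.integer(counts)
  names(out) <- names(counts)
  sort(out, decreasing = TRUE)
}
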