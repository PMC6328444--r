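# Per-population allele-frequency resources: tabular and VCF readers,
# and annotation of registry records.

#' Construct a frequency table
#'
#' @param entries A `data.frame` with columns `variant` (key), `population`
#'   (short code, upper-cased internally) and `frequency` (in `[0, 1]`).
#' @param panels Optional `data.frame` of panel metadata with columns
#'   `code`, `n_samples`, `resource`. Panel sizes are metadata only and
#'   never enter any computation.
#' @return A `frequency_table`.
#' @export
frequency_table <- function(entries, panels = NULL) {
  stopifnot(is.data.frame(entries),
            all(c("variant", "population", "frequency") %in% names(entries)))
  entries$population <- toupper(entries$population)
  bad <- !is.na(entries$frequency) &
    (entries$frequency < 0 | entries$frequency > 1)
  if (any(bad)) {
    i <- which(bad)[1]
    af_stop(sprintf("allele frequency outside [0,1]: %s / %s = %g",
                    entries$variant[i], entries$population[i],
                    entries$frequency[i]),
            "af_validation_error")
  }
  entries <- entries[!is.na(entries$frequency), , drop = FALSE]
  rownames(entries) <- NULL
  if (!is.null(panels)) {
    stopifnot(all(c("code", "n_samples") %in% names(panels)))
    panels$code <- toupper(panels$code)
    if (anyDuplicated(paste(panels$code, panels$resource %||% ""))) {
      af_stop("duplicate population code within a resource", "af_validation_error")
    }
    if (any(panels$n_samples <= 0)) {
      af_stop("panel sample sizes must be positive", "af_validation_error")
    }
  }
  structure(list(entries = entries, panels = panels), class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("frequency table: %d entries, %d variants, %d populations\n",
              nrow(x$entries), length(unique(x$entries$variant)),
              length(unique(x$entries$population))))
  invisible(x)
}

#' Populations present in a frequency table
#' @param x A `frequency_table`.
#' @return Character vector of population codes.
#' @export
populations <- function(x) {
  sort(unique(x$entries$population))
}

#' Read a tab-delimited per-population frequency table
#'
#' First column holds the variant key (deduplication key or rsID);
#' remaining columns are population codes. Blank cells are recorded as
#' absent — distinct from an explicit 0, which is kept as the number 0.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @return A `frequency_table`.
#' @export
read_frequency_tsv <- function(path) {
  if (!file.exists(path)) {
    af_stop(sprintf("frequency table not found: %s", path), "af_file_error")
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) {
    af_stop(sprintf("frequency table %s needs a key column plus >=1 population column", path),
            "af_format_error")
  }
  pops <- names(raw)[-1]
  keys <- trimws(raw[[1]])
  rows <- list()
  for (j in seq_along(pops)) {
    cell <- blank_to_na(raw[[j + 1L]])
    val <- suppressWarnings(as.numeric(cell))
    bad_num <- !is.na(cell) & is.na(val)
    if (any(bad_num)) {
      i <- which(bad_num)[1]
      af_stop(sprintf("%s: non-numeric frequency '%s' at row %d, column %s",
                      path, cell[i], i, pops[j]), "af_validation_error")
    }
    out_of_range <- !is.na(val) & (val < 0 | val > 1)
    if (any(out_of_range)) {
      i <- which(out_of_range)[1]
      af_stop(sprintf("%s: frequency %g outside [0,1] at row %d, column %s",
                      path, val[i], i, pops[j]), "af_validation_error")
    }
    rows[[j]] <- data.frame(variant = keys, population = pops[j],
                            frequency = val, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  entries <- entries[!is.na(entries$frequency), , drop = FALSE]
  frequency_table(entries)
}

#' Write a frequency table in the tabular format read_frequency_tsv() reads
#'
#' Absent (variant, population) pairs are written as blank cells, so the
#' read/write pair round-trips entries exactly.
#'
#' @param x A `frequency_table`.
#' @param path Output path.
#' @param key_name Header name of the key column.
#' @return `path`, invisibly.
#' @export
write_frequency_tsv <- function(x, path, key_name = "variant") {
  stopifnot(inherits(x, "frequency_table"))
  e <- x$entries
  pops <- sort(unique(e$population))
  keys <- unique(e$variant)
  wide <- matrix("", nrow = length(keys), ncol = length(pops),
                 dimnames = list(keys, pops))
  wide[cbind(match(e$variant, keys), match(e$population, pops))] <-
    format(e$frequency, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  out <- data.frame(key = keys, wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[1] <- key_name
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-population allele frequencies from a VCF
#'
#' Extracts INFO fields named `<field_prefix><popcode>` (e.g. `AF_eas`,
#' `AF_nfe`) from a VCF 4.x file. Variant keys are `CHROM-POS-REF-ALT`;
#' multi-allelic records with comma-separated per-allele frequency lists
#' yield one entry per alternate allele.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param field_prefix INFO field prefix in front of the population code.
#' @return A `frequency_table`.
#' @export
read_frequency_vcf <- function(path, field_prefix = "AF_") {
  if (!file.exists(path)) {
    af_stop(sprintf("VCF not found: %s", path), "af_file_error")
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) {
                    af_stop(sprintf("failed to parse VCF %s: %s",
                                    path, conditionMessage(e)), "af_parse_error")
                  })
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  rows <- list()
  pat <- paste0("^", field_prefix)
  for (i in seq_len(nrow(fix))) {
    info <- fix[i, "INFO"]
    if (is.na(info)) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keys <- paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts, sep = "-")
    for (kv in strsplit(info, ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) next
      name <- substr(kv, 1, eq - 1)
      if (!grepl(pat, name)) next
      vals <- suppressWarnings(as.numeric(strsplit(substr(kv, eq + 1, nchar(kv)),
                                                   ",", fixed = TRUE)[[1]]))
      if (length(vals) != length(alts)) {
        af_stop(sprintf("%s: INFO field %s has %d values for %d alternate allele(s) at record %d",
                        path, name, length(vals), length(alts), i),
                "af_parse_error")
      }
      pop <- toupper(sub(pat, "", name))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = keys, population = pop, frequency = vals,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    af_warn(sprintf("VCF %s carries no INFO fields with prefix '%s'",
                    path, field_prefix), "af_empty_input")
    return(frequency_table(data.frame(variant = character(),
                                      population = character(),
                                      frequency = numeric())))
  }
  frequency_table(do.call(rbind, rows))
}

#' Annotate registry records with per-population allele frequencies
#'
#' Looks each record up in every supplied frequency table, by
#' deduplication key and, when present, by dbSNP identifier. Frequencies
#' from all tables are merged per variant; when the same (variant,
#' population) pair occurs in more than one table the maximum is kept
#' (the conservative choice for questionable-pathogenicity flagging) and
#' a message is emitted. A variant absent from every table gets an empty
#' frequency map (all populations `NA`).
#'
#' @param registry A registry `data.frame` (see [read_registry()]).
#' @param tables A `frequency_table` or list of them.
#' @return The registry with one numeric column per population code
#'   appended (`NA` = absent). The population codes are recorded in
#'   attribute `"populations"`.
#' @export
annotate <- function(registry, tables) {
  if (inherits(tables, "frequency_table")) tables <- list(tables)
  entries <- do.call(rbind, lapply(tables, function(t) t$entries))
  if (is.null(entries)) {
    entries <- data.frame(variant = character(), population = character(),
                          frequency = numeric(), stringsAsFactors = FALSE)
  }
  pops <- sort(unique(entries$population))
  out <- registry
  freq <- matrix(NA_real_, nrow = nrow(registry), ncol = length(pops),
                 dimnames = list(NULL, pops))
  if (nrow(entries) && nrow(registry)) {
    idx <- match(entries$variant, registry$key)
    via_rs <- is.na(idx) & !is.na(match(entries$variant, registry$dbsnp_id))
    idx[via_rs] <- match(entries$variant[via_rs], registry$dbsnp_id)
    hit <- !is.na(idx)
    n_collide <- 0L
    for (r in which(hit)) {
      i <- idx[r]
      j <- match(entries$population[r], pops)
      old <- freq[i, j]
      new <- entries$frequency[r]
      if (!is.na(old) && old != new) n_collide <- n_collide + 1L
      freq[i, j] <- if (is.na(old)) new else max(old, new)
    }
    if (n_collide > 0L) {
      message(sprintf("annotate: %d (variant, population) collision(s) across tables; kept the maximum",
                      n_collide))
    }
  }
  for (j in seq_along(pops)) out[[pops[j]]] <- freq[, j]
  attr(out, "populations") <- pops
  out
}

# Population columns of an annotated/classified data.frame.
annotated_populations <- function(x) {
  pops <- attr(x, "populations")
  if (is.null(pops)) {
    af_stop("not an annotated variant table (no 'populations' attribute)",
            "af_precondition_error")
  }
  pops
}
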