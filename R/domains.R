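# Mapping protein residues to ion-channel topological domains.

domain_labels <- c("VSD", "pore", "other-transmembrane", "extracellular",
                   "cytoplasmic")

#' Construct a protein topology map
#'
#' Segments are 1-based inclusive residue ranges labelled with one of
#' `VSD` (voltage-sensing S4 helix), `pore` (S5–P–S6 pore module),
#' `other-transmembrane`, `extracellular` or `cytoplasmic`. Segments must
#' be sorted, non-overlapping, and cover residues 1..length with no gaps.
#'
#' @param protein Gene or transcript label the residue numbering refers to.
#' @param segments `data.frame` with columns `start`, `end`, `domain`.
#' @return A `topology_map`.
#' @export
topology_map <- function(protein, segments) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "domain") %in% names(segments)))
  segments <- segments[, c("start", "end", "domain")]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$domain <- as.character(segments$domain)
  bad_domain <- setdiff(unique(segments$domain), domain_labels)
  if (length(bad_domain)) {
    af_stop(sprintf("unknown domain label(s): %s (allowed: %s)",
                    paste(bad_domain, collapse = ", "),
                    paste(domain_labels, collapse = ", ")),
            "af_validation_error")
  }
  if (!nrow(segments)) af_stop("topology map has no segments", "af_validation_error")
  if (is.unsorted(segments$start, strictly = TRUE)) {
    af_stop("topology segments must be sorted by start position", "af_validation_error")
  }
  if (any(segments$end < segments$start)) {
    af_stop("topology segment with end < start", "af_validation_error")
  }
  if (segments$start[1] != 1L) {
    af_stop("topology map must start at residue 1", "af_validation_error")
  }
  if (nrow(segments) > 1L) {
    gaps <- segments$start[-1] - segments$end[-nrow(segments)]
    if (any(gaps > 1L)) {
      af_stop("topology map has gaps between segments", "af_validation_error")
    }
    if (any(gaps < 1L)) {
      af_stop("topology map has overlapping segments", "af_validation_error")
    }
  }
  structure(list(protein = protein, segments = segments,
                 length = segments$end[nrow(segments)]),
            class = "topology_map")
}

#' @export
print.topology_map <- function(x, ...) {
  cat(sprintf("topology map for %s: %d residues, %d segments\n",
              x$protein, x$length, nrow(x$segments)))
  invisible(x)
}

#' Read a topology map from a tab-delimited file
#'
#' Expected columns: `start`, `end`, `domain` (and optionally `protein`,
#' taken from the first row when the `protein` argument is missing).
#'
#' @param path Path to the tab-delimited map.
#' @param protein Protein label; overrides any `protein` column.
#' @return A `topology_map`.
#' @export
read_topology <- function(path, protein = NULL) {
  if (!file.exists(path)) {
    af_stop(sprintf("topology map not found: %s", path), "af_file_error")
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(protein)) {
    protein <- if ("protein" %in% names(raw)) raw$protein[1] else basename(path)
  }
  topology_map(protein, raw)
}

#' Topological domain at a residue position
#'
#' @param map A [topology_map()].
#' @param position Integer vector of 1-based residue positions.
#' @return Character vector of domain labels.
#' @examples
#' seg <- data.frame(start = c(1, 11), end = c(10, 20),
#'                   domain = c("cytoplasmic", "pore"))
#' domain_of(topology_map("toy", seg), c(1, 15))
#' @export
domain_of <- function(map, position) {
  stopifnot(inherits(map, "topology_map"))
  position <- as.integer(position)
  bad <- !is.na(position) & (position < 1L | position > map$length)
  if (any(bad)) {
    af_stop(sprintf("residue position %d outside 1..%d for %s",
                    position[which(bad)[1]], map$length, map$protein),
            "af_range_error")
  }
  idx <- findInterval(position, map$segments$start)
  out <- map$segments$domain[idx]
  out[is.na(position)] <- NA_character_
  out
}

#' Tally variants per topological domain
#'
#' Variants are located by the residue position parsed from their protein
#' change; variants without a parseable protein position (e.g. splice
#' variants) are counted as unmapped and excluded from the tally.
#' Multiple variants at the same residue all count (multiset semantics).
#'
#' @param map A [topology_map()].
#' @param variants A `data.frame` with a `protein_change` column (e.g.
#'   classified variants subset to one gene).
#' @return A `domain_tally`: list with `counts` (named integer vector over
#'   all five domain labels) and `n_unmapped`.
#' @export
tally_domains <- function(map, variants) {
  pos <- protein_position(variants$protein_change)
  mapped <- !is.na(pos)
  labels <- domain_of(map, pos[mapped])
  counts <- integer(length(domain_labels))
  names(counts) <- domain_labels
  tab <- table(labels)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, n_unmapped = sum(!mapped)),
            class = "domain_tally")
}

#' @export
print.domain_tally <- function(x, ...) {
  cat("domain tally:\n")
  for (d in names(x$counts)) cat(sprintf("  %-20s %d\n", d, x$counts[[d]]))
  if (x$n_unmapped) cat(sprintf("  (unmapped: %d)\n", x$n_unmapped))
  invisible(x)
}
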