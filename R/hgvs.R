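# HGVS parsing and mutation-type classification.
#
# Scope is deliberately narrow: single amino-acid substitutions (one- or
# three-letter code), stop gains, "fs"-marked frameshifts, and the
# intron-offset heuristic for splice-site changes. Duplications, delins
# and repeat notations are out of scope.

aa_three_to_one <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)
aa_letters <- setdiff(unname(aa_three_to_one), "*")

mutation_type_levels <- c("missense", "nonsense", "frameshift", "splice", "other")

#' Parse a protein-level HGVS change
#'
#' Accepts one-letter (`"A226V"`) and three-letter (`"p.Ala226Val"`)
#' substitutions, stop gains spelled `*`, `X` or `Ter` (`"E61*"`), and
#' frameshifts marked by an `fs` suffix (`"K862fs"`, `"p.Leu123Serfs*12"`).
#' An optional `p.` prefix and surrounding parentheses are stripped.
#'
#' @param s A single HGVS p.-style string.
#' @return A `protein_change`: list with `ref_aa` (one-letter code),
#'   `position` (1-based residue index) and `alt_aa` (one-letter code,
#'   `"*"` for a stop, or `"fs"` for a frameshift).
#' @examples
#' parse_protein_change("A226V")
#' parse_protein_change("E61*")
#' parse_protein_change("p.Leu123fs")
#' @export
parse_protein_change <- function(s) {
  if (length(s) != 1L || is.na(s) || !nzchar(trimws(s))) {
    af_stop("protein change string is empty", "af_hgvs_parse_error", text = s)
  }
  orig <- s
  s <- normalize_hgvs(s)
  s <- sub("^p\\.", "", s)
  s <- gsub("^\\(|\\)$", "", s)
  s <- sub("X$", "*", s)  # legacy stop spelling

  new_pc <- function(ref, pos, alt) {
    if (!ref %in% aa_letters) {
      af_stop(sprintf("unknown reference amino acid in '%s'", orig),
              "af_hgvs_parse_error", text = orig)
    }
    structure(list(ref_aa = ref, position = as.integer(pos), alt_aa = alt),
              class = "protein_change")
  }

  # frameshift: anything after the first ref+position that contains "fs"
  m <- regmatches(s, regexec("^([A-Z][a-z]{2}|[A-Z])([0-9]+)\\S*fs(\\*?[0-9]*)$", s))[[1]]
  if (length(m)) {
    ref <- if (nchar(m[2]) == 3L) aa_three_to_one[[m[2]]] else m[2]
    return(new_pc(ref, m[3], "fs"))
  }
  # three-letter substitution / stop
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|\\*)$", s))[[1]]
  if (length(m)) {
    ref <- aa_three_to_one[match(m[2], names(aa_three_to_one))]
    alt <- if (m[4] == "*") "*" else aa_three_to_one[match(m[4], names(aa_three_to_one))]
    if (is.na(ref) || is.na(alt)) {
      af_stop(sprintf("unknown three-letter amino acid code in '%s'", orig),
              "af_hgvs_parse_error", text = orig)
    }
    return(new_pc(unname(ref), m[3], unname(alt)))
  }
  # one-letter substitution / stop
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1]]
  if (length(m)) {
    return(new_pc(m[2], m[3], m[4]))
  }
  af_stop(sprintf("cannot parse protein change '%s'", orig),
          "af_hgvs_parse_error", text = orig)
}

#' @export
format.protein_change <- function(x, ...) {
  suffix <- if (identical(x$alt_aa, "fs")) "fs" else x$alt_aa
  paste0(x$ref_aa, x$position, suffix)
}

#' @export
print.protein_change <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Extract the residue position from a protein change string
#'
#' Vectorized convenience around [parse_protein_change()]; unparseable or
#' absent strings yield `NA` rather than an error.
#'
#' @param s Character vector of HGVS p.-style strings.
#' @return Integer vector of 1-based residue positions.
#' @export
protein_position <- function(s) {
  vapply(s, function(si) {
    if (is.na(si) || !nzchar(si)) return(NA_integer_)
    pc <- tryCatch(parse_protein_change(si), af_hgvs_parse_error = function(e) NULL)
    if (is.null(pc)) NA_integer_ else pc$position
  }, integer(1), USE.NAMES = FALSE)
}

# Intron-offset notation after a coding position, e.g. 4813+1G>A, 535-2A>G.
has_intron_offset <- function(cdna) {
  !is.na(cdna) & grepl("[0-9]+[+-][0-9]+", cdna)
}

#' Classify the mutation type of a variant
#'
#' One of `missense`, `nonsense`, `frameshift`, `splice` or `other`.
#' Precedence when the cDNA and protein descriptions disagree is
#' frameshift > nonsense > splice > missense: a protein-level consequence
#' wins over the cDNA intron-offset heuristic.
#'
#' @param cdna HGVS c.-style string (or `NA`).
#' @param protein HGVS p.-style string (or `NA`).
#' @return A single mutation-type label.
#' @examples
#' classify_mutation_type("181G>T", "E61*")    # nonsense
#' classify_mutation_type(NA, "R1106Q")        # missense
#' classify_mutation_type("4813+1G>A", NA)     # splice
#' @export
classify_mutation_type <- function(cdna = NA_character_, protein = NA_character_) {
  cdna <- if (is.na(cdna) || !nzchar(trimws(cdna))) NA_character_ else normalize_hgvs(cdna)
  protein <- if (is.na(protein) || !nzchar(trimws(protein))) NA_character_ else protein
  if (is.na(cdna) && is.na(protein)) {
    af_stop("at least one of cdna/protein change must be present",
            "af_precondition_error")
  }
  pc <- NULL
  if (!is.na(protein)) {
    pc <- tryCatch(parse_protein_change(protein),
                   af_hgvs_parse_error = function(e) NULL)
  }
  if (!is.null(pc)) {
    if (identical(pc$alt_aa, "fs")) return("frameshift")
    if (identical(pc$alt_aa, "*")) return("nonsense")
  }
  if (has_intron_offset(cdna)) return("splice")
  if (!is.null(pc) && pc$alt_aa %in% aa_letters && pc$alt_aa != pc$ref_aa) {
    return("missense")
  }
  "other"
}

#' Classify mutation types for a whole registry
#'
#' @param registry A registry `data.frame` with `cdna_change` and
#'   `protein_change` columns.
#' @return Character vector of mutation-type labels, one per record.
#' @export
classify_mutation_types <- function(registry) {
  if (!nrow(registry)) return(character(0))
  mapply(classify_mutation_type, registry$cdna_change, registry$protein_change,
         USE.NAMES = FALSE)
}

#' Is a mutation type radical (protein-truncating)?
#'
#' Radical mutations are frameshift plus nonsense (stop-gain) changes;
#' splice-site changes are not counted as radical.
#'
#' @param t Character vector of mutation-type labels.
#' @return Logical vector.
#' @export
is_radical <- function(t) {
  t %in% c("frameshift", "nonsense")
}
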