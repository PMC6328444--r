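# Maximum credible allele frequency, cutoff flagging, and ancestry
# restriction of flagged variants.

#' Disease parameters for the maximum credible allele frequency
#'
#' Bundles the three quantities entering the maximum credible allele
#' frequency of a fully penetrant-model pathogenic variant —
#' disease prevalence, the maximal allelic contribution (the largest share
#' of genetic cases attributable to any single variant) and penetrance —
#' together with the applied cutoff actually used for flagging. The
#' applied cutoff may relax (exceed) the credible bound, e.g. by a safety
#' factor guarding against excluding true pathogenic variants, but never
#' tighten it.
#'
#' @param prevalence Disease prevalence, a proportion in `[0, 1]`.
#' @param allelic_contribution Maximal allelic contribution, in `(0, 1]`.
#' @param penetrance Penetrance of carriers, in `(0, 1]`.
#' @param applied_cutoff Allele-frequency cutoff used for flagging, in
#'   `(0, 1]`; defaults to the credible bound itself.
#' @return A `credible_af_params` object.
#' @examples
#' brs <- credible_af_params(0.0012, 0.01, 0.16, applied_cutoff = 0.001)
#' max_credible_af(brs)
#' @export
credible_af_params <- function(prevalence, allelic_contribution, penetrance,
                               applied_cutoff = NULL) {
  for (v in list(prevalence, allelic_contribution, penetrance)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      af_stop("prevalence, allelic contribution and penetrance must be proportions in [0,1]",
              "af_validation_error")
    }
  }
  if (penetrance == 0) {
    af_stop("penetrance must be positive (division by zero in the credible bound)",
            "af_domain_error")
  }
  if (allelic_contribution == 0) {
    af_stop("allelic contribution must be positive", "af_validation_error")
  }
  bound <- prevalence * allelic_contribution / penetrance
  if (is.null(applied_cutoff)) applied_cutoff <- bound
  if (!is.numeric(applied_cutoff) || length(applied_cutoff) != 1L ||
      is.na(applied_cutoff) || applied_cutoff <= 0 || applied_cutoff > 1) {
    af_stop("applied_cutoff must be an allele frequency in (0,1]",
            "af_validation_error")
  }
  if (applied_cutoff < bound * (1 - 1e-12)) {
    af_stop(sprintf("applied_cutoff %g is stricter than the maximum credible allele frequency %g; the cutoff may only relax the credible bound",
                    applied_cutoff, bound), "af_validation_error")
  }
  structure(list(prevalence = prevalence,
                 allelic_contribution = allelic_contribution,
                 penetrance = penetrance,
                 applied_cutoff = applied_cutoff),
            class = "credible_af_params")
}

#' @export
print.credible_af_params <- function(x, ...) {
  cat(sprintf("credible AF parameters: prevalence %g, allelic contribution %g, penetrance %g\n",
              x$prevalence, x$allelic_contribution, x$penetrance))
  cat(sprintf("  maximum credible allele frequency: %g\n", max_credible_af(x)))
  cat(sprintf("  applied cutoff: %g\n", x$applied_cutoff))
  invisible(x)
}

#' Maximum credible allele frequency
#'
#' The highest population allele frequency compatible with a variant being
#' pathogenic for the disease:
#' `prevalence * allelic_contribution / penetrance`.
#'
#' @param params A `credible_af_params` object, or the prevalence as a
#'   bare number if `allelic_contribution` and `penetrance` are also given.
#' @param allelic_contribution,penetrance Proportions, used when `params`
#'   is a bare prevalence.
#' @return The maximum credible allele frequency.
#' @examples
#' max_credible_af(0.0012, 0.01, 0.16)  # 7.5e-05
#' @export
max_credible_af <- function(params, allelic_contribution = NULL, penetrance = NULL) {
  if (!inherits(params, "credible_af_params")) {
    params <- credible_af_params(params, allelic_contribution, penetrance)
  }
  params$prevalence * params$allelic_contribution / params$penetrance
}

#' Read disease parameters and population grouping from a config file
#'
#' YAML or JSON with top-level keys `prevalence`, `allelic_contribution`,
#' `penetrance`, `applied_cutoff` and optionally `grouping` (a map of
#' group label to a list of population codes).
#'
#' @param path Path to the config file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return A list with elements `params` (`credible_af_params`) and
#'   `grouping` (`population_grouping` or `NULL`).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    af_stop(sprintf("parameter config not found: %s", path), "af_file_error")
  }
  cfg <- switch(tolower(tools::file_ext(path)),
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                af_stop(sprintf("unrecognized config extension: %s", path),
                        "af_format_error"))
  params <- credible_af_params(cfg$prevalence, cfg$allelic_contribution,
                               cfg$penetrance, cfg$applied_cutoff)
  grouping <- if (!is.null(cfg$grouping)) {
    population_grouping(lapply(cfg$grouping, unlist))
  }
  list(params = params, grouping = grouping)
}

#' Define a grouping of population codes
#'
#' @param groups Named list mapping a group label to a character vector of
#'   population codes; a code may belong to at most one group.
#' @return A `population_grouping`.
#' @examples
#' population_grouping(list(Asian = c("EAS", "SAS", "JEW", "JPN3K", "TWB")))
#' @export
population_grouping <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  groups <- lapply(groups, function(g) toupper(as.character(g)))
  all_codes <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_codes)) {
    af_stop(sprintf("population code(s) in more than one group: %s",
                    paste(unique(all_codes[duplicated(all_codes)]), collapse = ", ")),
            "af_config_error")
  }
  structure(groups, class = "population_grouping")
}

#' Flag variants meeting the applied cutoff in any population
#'
#' A variant is flagged as of questionable pathogenicity when its allele
#' frequency in at least one population meets or exceeds the cutoff; the
#' comparison is inclusive (`>=`). Absent frequencies never flag. The
#' mutation type of each record is classified alongside.
#'
#' @param annotated Output of [annotate()].
#' @param cutoff Positive allele-frequency cutoff (e.g. the
#'   `applied_cutoff` of [credible_af_params()]).
#' @return The input with columns `mutation_type`, `flagged` (logical) and
#'   `flagged_populations` (`,`-separated codes, `""` when unflagged)
#'   appended; attributes `"populations"` and `"cutoff"` record the panel
#'   codes and the applied cutoff.
#' @export
flag_variants <- function(annotated, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0) {
    af_stop("cutoff must be a positive allele frequency", "af_validation_error")
  }
  pops <- annotated_populations(annotated)
  out <- annotated
  fm <- per_population_flags(annotated, cutoff)
  out$mutation_type <- classify_mutation_types(annotated)
  out$flagged <- if (nrow(out)) apply(fm, 1L, any) else logical(0)
  out$flagged_populations <- if (nrow(out)) {
    apply(fm, 1L, function(fl) paste(pops[fl], collapse = ","))
  } else character(0)
  attr(out, "populations") <- pops
  attr(out, "cutoff") <- cutoff
  out
}

#' Per-population flag matrix
#'
#' @param annotated Output of [annotate()] or [flag_variants()].
#' @param cutoff Cutoff to apply; defaults to the cutoff stored by
#'   [flag_variants()].
#' @return Logical matrix, rows = variants, columns = population codes;
#'   `TRUE` where the frequency is present and `>=` cutoff.
#' @export
per_population_flags <- function(annotated, cutoff = attr(annotated, "cutoff")) {
  pops <- annotated_populations(annotated)
  m <- as.matrix(as.data.frame(annotated[, pops, drop = FALSE]))
  storage.mode(m) <- "double"
  fm <- !is.na(m) & m >= cutoff
  dimnames(fm) <- list(NULL, pops)
  fm
}

flagged_population_sets <- function(classified) {
  strsplit(ifelse(is.na(classified$flagged_populations), "",
                  classified$flagged_populations), ",", fixed = TRUE)
}

#' Is each flagged variant restricted to one population group?
#'
#' A flagged variant is restricted to a group when every population in
#' which it meets the cutoff belongs to that group (e.g. "frequency
#' >= cutoff only in the Asian reference populations").
#'
#' @param classified Output of [flag_variants()].
#' @param grouping A [population_grouping()].
#' @param group Group label to test against.
#' @return Logical vector, `NA` for unflagged variants.
#' @export
restricted_to_group <- function(classified, grouping, group) {
  stopifnot(inherits(grouping, "population_grouping"))
  if (!group %in% names(grouping)) {
    af_stop(sprintf("unknown population group '%s' (defined: %s)", group,
                    paste(names(grouping), collapse = ", ")),
            "af_config_error")
  }
  members <- grouping[[group]]
  sets <- flagged_population_sets(classified)
  out <- vapply(sets, function(s) length(s) > 0L && all(s %in% members),
                logical(1))
  out[!classified$flagged] <- NA
  out
}

#' Label each flagged variant with the group it is restricted to, if any
#'
#' @inheritParams restricted_to_group
#' @return Character vector: the unique restricting group label, or `NA`
#'   when the variant is unflagged or its flagged populations span groups.
#' @export
restriction_label <- function(classified, grouping) {
  stopifnot(inherits(grouping, "population_grouping"))
  labels <- rep(NA_character_, nrow(classified))
  for (g in names(grouping)) {
    hit <- restricted_to_group(classified, grouping, g)
    labels[!is.na(hit) & hit] <- g
  }
  labels
}

#' Per-variant classification report
#'
#' @param classified Output of [flag_variants()].
#' @param grouping Optional [population_grouping()] used to add a
#'   restriction label per variant.
#' @return A `classification_report`: list with `table` (per-variant rows:
#'   gene, changes, per-population frequencies, flag, flagged populations,
#'   restriction) and `totals` (n, n_flagged, flagged counts by gene and
#'   mutation type).
#' @export
classification_report <- function(classified, grouping = NULL) {
  pops <- annotated_populations(classified)
  tab <- classified[, c("gene", "transcript", "cdna_change", "protein_change",
                        "sources", pops, "mutation_type", "flagged",
                        "flagged_populations"), drop = FALSE]
  if (!is.null(grouping)) tab$restricted_group <- restriction_label(classified, grouping)
  totals <- list(
    n = nrow(classified),
    n_flagged = sum(classified$flagged),
    flagged_by_gene = if (any(classified$flagged)) {
      gene_distribution(classified[classified$flagged, , drop = FALSE])
    } else integer(0),
    flagged_by_type = table(classified$mutation_type[classified$flagged])
  )
  structure(list(table = tab, totals = totals), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification report: %d variants, %d flagged at cutoff\n",
              x$totals$n, x$totals$n_flagged))
  if (nrow(x$table)) {
    shown <- x$table[, c("gene", "protein_change", "mutation_type",
                         "flagged", "flagged_populations")]
    print(utils::head(shown, 25L), row.names = FALSE)
    if (nrow(shown) > 25L) cat(sprintf("... and %d more rows\n", nrow(shown) - 25L))
  }
  invisible(x)
}
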