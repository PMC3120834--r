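# Per-locus isomiR spectra and repertoire statistics: 3' addition shares,
# 5'/3' end heterogeneity, length distributions and the expression-versus-
# isomiR-type relationship.

#' Build the isomiR spectrum of one miRNA locus
#'
#' Observations below the report threshold are dropped; the remaining
#' species get percentages of the locus total and are ordered by count
#' descending then sequence ascending. The most and secondary abundant
#' species and their fold ratio summarise the spectrum's dominance
#' structure.
#'
#' @param observations observation tibble (one sample's worth) whose rows
#'   all belong to `mature_id`.
#' @param mature_id the locus.
#' @param min_count report threshold on sequence counts (default 10).
#' @return an object of class `locus_spectrum`: list with `mature_id`,
#'   `species` (tibble with `percentage`), `most_abundant`,
#'   `secondary_abundant` (row indices into `species`, or `NA`),
#'   `fold_most_secondary`.
#' @export
build_spectrum <- function(observations, mature_id, min_count = 10L) {
  obs <- observations[observations$mature_id == mature_id, , drop = FALSE]
  if ("sample_id" %in% names(obs) && length(unique(obs$sample_id)) > 1L) {
    stop("build_spectrum expects observations from a single sample",
         call. = FALSE)
  }
  obs <- obs[obs$count >= min_count, , drop = FALSE]
  obs <- obs[order(-obs$count, obs$sequence, method = "radix"), ]
  if (nrow(obs) > 0L) obs$percentage <- 100 * obs$count / sum(obs$count)
  else obs$percentage <- numeric(0)
  fold <- if (nrow(obs) >= 2L) obs$count[1L] / obs$count[2L] else NA_real_
  structure(list(mature_id = mature_id,
                 species = tibble::as_tibble(obs),
                 most_abundant = if (nrow(obs) >= 1L) 1L else NA_integer_,
                 secondary_abundant = if (nrow(obs) >= 2L) 2L else NA_integer_,
                 fold_most_secondary = fold),
            class = "locus_spectrum")
}

#' @export
print.locus_spectrum <- function(x, ...) {
  cat("<locus_spectrum> ", x$mature_id, ": ", nrow(x$species),
      " species", sep = "")
  if (!is.na(x$fold_most_secondary)) {
    cat(", most/secondary fold ", format(round(x$fold_most_secondary, 2)),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Build spectra for all loci and samples at once
#'
#' The batch form of [build_spectrum()]: applies the report threshold and
#' computes percentages and abundance ranks within each (sample, locus)
#' group.
#'
#' @param observations observation tibble with `sample_id`.
#' @param min_count report threshold (default 10).
#' @return tibble of retained species with `percentage` and `rank` (1 =
#'   most abundant; ties broken by sequence ascending).
#' @export
build_spectra <- function(observations, min_count = 10L) {
  obs <- observations[observations$count >= min_count, , drop = FALSE]
  if (!"sample_id" %in% names(obs)) obs$sample_id <- "sample"
  obs <- obs[order(obs$sample_id, obs$mature_id, -obs$count, obs$sequence,
                   method = "radix"), ]
  obs %>%
    dplyr::group_by(.data$sample_id, .data$mature_id) %>%
    dplyr::mutate(percentage = 100 * .data$count / sum(.data$count),
                  rank = dplyr::row_number()) %>%
    dplyr::ungroup()
}

#' Shares of isomiRs carrying 3' non-template additions
#'
#' Computes, per sample, the share of isomiR species carrying a 3'
#' addition (type-based) and the read-weighted share (count-based),
#' together with the per-addition breakdown under both the all-isomiRs and
#' the modified-isomiRs-only denominators, and the double-addition table.
#' Additions are keyed by their printed string (U for T), so single
#' nucleotides (`A`, `U`, `C`, `G`) and doubles (`AA`, `AU`, ...) are
#' separate keys and the per-key fractions sum exactly to the totals.
#'
#' @param spectra batch spectra tibble from [build_spectra()] (built at the
#'   report threshold of interest, e.g. 10 or 100).
#' @return list with tibbles `totals` (`sample_id`, `type_fraction`,
#'   `count_fraction`), `by_addition` (fractions under both denominators)
#'   and `doubles` (double additions only, with fractions of all modified
#'   species/reads).
#' @export
nta_summary <- function(spectra) {
  sp <- spectra
  sp$addition_u <- gsub("T", "U", sp$addition, fixed = TRUE)
  sp$modified <- nzchar(sp$addition)
  totals <- sp %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_species = dplyr::n(),
                     n_reads = sum(.data$count),
                     type_fraction = mean(.data$modified),
                     count_fraction = sum(.data$count[.data$modified]) /
                       sum(.data$count),
                     .groups = "drop")
  by_addition <- sp %>%
    dplyr::filter(.data$modified) %>%
    dplyr::group_by(.data$sample_id, addition = .data$addition_u) %>%
    dplyr::summarise(n_species = dplyr::n(), count = sum(.data$count),
                     .groups = "drop") %>%
    dplyr::left_join(totals, by = "sample_id") %>%
    dplyr::mutate(type_fraction_all = .data$n_species.x / .data$n_species.y,
                  count_fraction_all = .data$count / .data$n_reads) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(type_fraction_modified =
                    .data$n_species.x / sum(.data$n_species.x),
                  count_fraction_modified = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::select("sample_id", "addition", n_species = "n_species.x",
                  count = "count", "type_fraction_all", "count_fraction_all",
                  "type_fraction_modified", "count_fraction_modified")
  doubles <- by_addition[nchar(by_addition$addition) == 2L, ]
  list(totals = totals, by_addition = by_addition, doubles = doubles)
}

#' 5' and 3' end heterogeneity of the isomiR repertoire
#'
#' Per sample, the fraction of isomiR species (3'-addition-carrying species
#' excluded) whose template start differs from the canonical start
#' (5'-variant) and whose template end differs from the canonical end
#' (3'-variant); a species may count in both. Canonical coordinates come
#' from [resolve_locus()]; loci without an annotation are excluded and
#' logged in the `excluded` attribute.
#'
#' @param spectra batch spectra tibble.
#' @param ref the `reference_set`.
#' @return tibble with `sample_id`, `n_species`, `frac_5p_variant`,
#'   `frac_3p_variant`.
#' @export
end_heterogeneity <- function(spectra, ref) {
  sp <- spectra[!nzchar(spectra$addition), , drop = FALSE]
  known <- unique(sp$mature_id)
  have <- known[known %in% ref$annotations$mature_id]
  excluded <- setdiff(known, have)
  sp <- sp[sp$mature_id %in% have, , drop = FALSE]
  canon <- do.call(rbind, lapply(have, function(m) {
    a <- resolve_locus(m, ref)
    data.frame(mature_id = m, c_start = a$start, c_end = a$end)
  }))
  i <- match(sp$mature_id, canon$mature_id)
  sp$var5 <- sp$template_start != canon$c_start[i]
  sp$var3 <- sp$template_end != canon$c_end[i]
  out <- sp %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(n_species = dplyr::n(),
                     frac_5p_variant = mean(.data$var5),
                     frac_3p_variant = mean(.data$var3),
                     .groups = "drop")
  attr(out, "excluded") <- excluded
  out
}

#' Read-length distribution of isomiR observations
#'
#' Lengths include any 3' addition. Both the count-weighted (reads) and the
#' species-weighted histograms are returned; the mode is the count-weighted
#' modal length.
#'
#' @param observations observation tibble (optionally with `sample_id`).
#' @return tibble with `sample_id`, `length`, `n_species`, `n_reads`;
#'   attribute `mode` holds the count-weighted modal length per sample.
#' @export
length_distribution <- function(observations) {
  obs <- observations
  if (nrow(obs) == 0L) {
    out <- tibble::tibble(sample_id = character(), length = integer(),
                          n_species = integer(), n_reads = integer())
    attr(out, "mode") <- integer(0)
    return(out)
  }
  if (!"sample_id" %in% names(obs)) obs$sample_id <- "sample"
  obs$length <- obs$template_end - obs$template_start + 1L +
    nchar(obs$addition)
  out <- obs %>%
    dplyr::group_by(.data$sample_id, .data$length) %>%
    dplyr::summarise(n_species = dplyr::n(), n_reads = sum(.data$count),
                     .groups = "drop") %>%
    dplyr::arrange(.data$sample_id, .data$length)
  modes <- out %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(mode = .data$length[which.max(.data$n_reads)],
                     .groups = "drop")
  attr(out, "mode") <- stats::setNames(modes$mode, modes$sample_id)
  out
}

#' Relationship between miRNA expression and number of isomiR types
#'
#' For each abundantly expressed locus (most-abundant isomiR count above
#' `locus_min`), pairs its expression (scheme-selectable) with the number
#' of isomiR species above `species_min` counts, and reports the Spearman
#' rank correlation per sample. With fewer than three qualifying loci the
#' correlation is undefined (`NA`) but the paired table is still returned.
#'
#' @param spectra batch spectra tibble.
#' @param scheme `"most"` (most-abundant isomiR count) or `"sum"`.
#' @param species_min a species counts toward the type number when its
#'   count exceeds this (default 99, i.e. >99).
#' @param locus_min a locus qualifies when its most abundant isomiR count
#'   exceeds this (default 999, i.e. >999).
#' @return list with `table` (per sample and locus: `expression`,
#'   `n_types`) and `rho` (named per-sample Spearman correlations).
#' @export
expression_type_correlation <- function(spectra, scheme = c("most", "sum"),
                                        species_min = 99L, locus_min = 999L) {
  scheme <- match.arg(scheme)
  if (nrow(spectra) == 0L) {
    return(list(table = tibble::tibble(sample_id = character(),
                                       mature_id = character(),
                                       expression = integer(),
                                       n_types = integer()),
                rho = stats::setNames(numeric(0), character(0))))
  }
  per_locus <- spectra %>%
    dplyr::group_by(.data$sample_id, .data$mature_id) %>%
    dplyr::summarise(most = max(.data$count),
                     total = sum(.data$count),
                     n_types = sum(.data$count > species_min),
                     .groups = "drop") %>%
    dplyr::filter(.data$most > locus_min) %>%
    dplyr::mutate(expression = if (scheme == "most") .data$most else .data$total) %>%
    dplyr::select("sample_id", "mature_id", "expression", "n_types")
  rho <- vapply(split(per_locus, per_locus$sample_id), function(d) {
    if (nrow(d) < 3L) return(NA_real_)
    stats::cor(d$expression, d$n_types, method = "spearman")
  }, numeric(1))
  list(table = per_locus, rho = rho)
}
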