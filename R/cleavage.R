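# Dominant Drosha/Dicer cleavage-site inference from isomiR end-position
# heterogeneity. 3' non-template additions never move an end: template
# coordinates are used, so modified species reinforce their template span.

#' Infer dominant cleavage sites for one locus
#'
#' Counts are aggregated by template span (additions stripped), giving
#' count-weighted distributions of 5' ends and 3' template ends. The ends
#' of the most abundant span are the dominant sites; when the fold between
#' the most and secondary abundant spans is below `dominance_fold` the
#' secondary span's ends are additionally flagged (non-dominant cleavage).
#' On a 5p-arm locus the 5' end is the Drosha cut and the 3' end the Dicer
#' cut; on a 3p arm the mapping is reversed; with an unknown arm sites are
#' reported without enzyme labels.
#'
#' @param spectrum a `locus_spectrum` from [build_spectrum()].
#' @param annotation the locus annotation row (e.g. from
#'   [resolve_locus()]); its `arm` may be `NA`.
#' @param dominance_fold dominance threshold on the most/secondary fold
#'   (default 5; a fold of at least 5 is dominant).
#' @return object of class `cleavage_call`: list with `mature_id`, `arm`,
#'   `end5_sites` / `end3_sites` (tibbles `position`, `weight` summing to
#'   1 per end), `dominant_5p_end_sites`, `dominant_3p_end_sites`,
#'   `drosha_sites`, `dicer_sites`, `dominance`, `fold_most_secondary`;
#'   or `NULL` for an empty spectrum.
#' @export
infer_cleavage <- function(spectrum, annotation, dominance_fold = 5) {
  sp <- spectrum$species
  if (nrow(sp) == 0L) return(NULL)
  spans <- sp %>%
    dplyr::group_by(.data$template_start, .data$template_end) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$template_start,
                   .data$template_end)
  w5 <- spans %>%
    dplyr::group_by(position = .data$template_start) %>%
    dplyr::summarise(weight = sum(.data$count), .groups = "drop") %>%
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) %>%
    dplyr::arrange(dplyr::desc(.data$weight), .data$position)
  w3 <- spans %>%
    dplyr::group_by(position = .data$template_end) %>%
    dplyr::summarise(weight = sum(.data$count), .groups = "drop") %>%
    dplyr::mutate(weight = .data$weight / sum(.data$weight)) %>%
    dplyr::arrange(dplyr::desc(.data$weight), .data$position)
  fold <- if (nrow(spans) >= 2L) spans$count[1L] / spans$count[2L] else Inf
  dominance <- fold >= dominance_fold
  dom5 <- spans$template_start[1L]
  dom3 <- spans$template_end[1L]
  if (!dominance && nrow(spans) >= 2L) {
    dom5 <- unique(c(dom5, spans$template_start[2L]))
    dom3 <- unique(c(dom3, spans$template_end[2L]))
  }
  arm <- annotation$arm
  if (is.na(arm) || !arm %in% c("5p", "3p")) {
    drosha <- dicer <- NULL
  } else if (arm == "5p") {
    drosha <- dom5
    dicer <- dom3
  } else {
    drosha <- dom3
    dicer <- dom5
  }
  structure(list(mature_id = spectrum$mature_id,
                 arm = if (is.na(arm)) NA_character_ else arm,
                 end5_sites = w5, end3_sites = w3,
                 dominant_5p_end_sites = dom5,
                 dominant_3p_end_sites = dom3,
                 drosha_sites = drosha, dicer_sites = dicer,
                 dominance = dominance,
                 fold_most_secondary = fold),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  cat("<cleavage_call> ", x$mature_id, " (", x$arm, " arm)\n",
      "  dominant 5' end: ", paste(x$dominant_5p_end_sites, collapse = ","),
      "; dominant 3' end: ", paste(x$dominant_3p_end_sites, collapse = ","),
      "\n  most/secondary fold: ",
      ifelse(is.finite(x$fold_most_secondary),
             format(round(x$fold_most_secondary, 2)), "single span"),
      if (x$dominance) " (dominant)" else " (non-dominant, secondary flagged)",
      "\n", sep = "")
  invisible(x)
}

#' Infer cleavage calls for every locus in a spectra table
#'
#' @param spectra batch spectra tibble from [build_spectra()] (one sample;
#'   filter first or pass `sample` to select).
#' @param ref the `reference_set`.
#' @param sample optional sample id to select from `spectra`.
#' @param dominance_fold see [infer_cleavage()].
#' @return tibble with one row per locus: dominant sites as comma-joined
#'   `pos:weight` strings, enzyme assignments, dominance flag and fold.
#' @export
infer_cleavage_all <- function(spectra, ref, sample = NULL,
                               dominance_fold = 5) {
  sp <- spectra
  if (!is.null(sample)) sp <- sp[sp$sample_id == sample, , drop = FALSE]
  loci <- sort(unique(sp$mature_id))
  rows <- lapply(loci, function(m) {
    spec <- structure(list(mature_id = m,
                           species = sp[sp$mature_id == m, , drop = FALSE]),
                      class = "locus_spectrum")
    call <- infer_cleavage(spec, resolve_locus(m, ref), dominance_fold)
    if (is.null(call)) return(NULL)
    fmt <- function(w) paste(sprintf("%d:%.4f", w$position, w$weight),
                             collapse = ",")
    tibble::tibble(mature_id = m, arm = call$arm,
                   end5_sites = fmt(call$end5_sites),
                   end3_sites = fmt(call$end3_sites),
                   dominant_5p = paste(call$dominant_5p_end_sites, collapse = ","),
                   dominant_3p = paste(call$dominant_3p_end_sites, collapse = ","),
                   drosha = paste(call$drosha_sites, collapse = ","),
                   dicer = paste(call$dicer_sites, collapse = ","),
                   dominance = call$dominance,
                   fold_most_secondary = call$fold_most_secondary)
  })
  dplyr::bind_rows(rows)
}
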