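# End-to-end orchestration: collapse -> blacklist filter -> align -> isomiR
# calls -> spectra -> repertoire statistics -> profiles -> DE -> cleavage.
# The analysis drivers under analysis/ are thin wrappers around this.

#' Pipeline configuration: thresholds and mode
#'
#' Bundles the analysis constants: the spectrum report threshold, the
#' abundant-species and abundant-locus floors, the modified-isomiR DE
#' floor, the fold-change imputation rule, the significance threshold and
#' the cleavage dominance fold.
#'
#' @param report_min spectrum report threshold (counts >= this are kept;
#'   default 10).
#' @param abundant_species_min species counted as an isomiR "type" when
#'   count exceeds this (default 99).
#' @param abundant_locus_min locus tested for DE / correlation when its
#'   expression exceeds this (default 999).
#' @param modified_de_min modified-isomiR DE floor (default 300).
#' @param impute_floor,impute_value fold-change imputation (defaults 100,
#'   10).
#' @param lfc_threshold significance threshold on `|log2fc|` (default 4).
#' @param dominance_fold cleavage dominance fold (default 5).
#' @param mode `"colorspace"` or `"basespace"`.
#' @param primer,adaptor colorspace library constants.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(report_min = 10L, abundant_species_min = 99L,
                            abundant_locus_min = 999L, modified_de_min = 300L,
                            impute_floor = 100L, impute_value = 10L,
                            lfc_threshold = 4, dominance_fold = 5,
                            mode = c("colorspace", "basespace"),
                            primer = solmir_default_primer,
                            adaptor = solmir_default_adaptor) {
  mode <- match.arg(mode)
  vals <- c(report_min, abundant_species_min, abundant_locus_min,
            modified_de_min, impute_floor, impute_value, lfc_threshold,
            dominance_fold)
  if (any(vals <= 0)) stop("all thresholds must be positive", call. = FALSE)
  structure(list(report_min = report_min,
                 abundant_species_min = abundant_species_min,
                 abundant_locus_min = abundant_locus_min,
                 modified_de_min = modified_de_min,
                 impute_floor = impute_floor, impute_value = impute_value,
                 lfc_threshold = lfc_threshold,
                 dominance_fold = dominance_fold,
                 mode = mode, primer = primer, adaptor = adaptor),
            class = "pipeline_config")
}

#' Call isomiR observations for a set of sample libraries
#'
#' Collapses, blacklist-filters, aligns and assigns every sample's reads,
#' returning one observation table with a `sample_id` column and an
#' accounting attribute (`audit`) proving count conservation: aligned +
#' unaligned + blacklisted + unassigned = input reads, per sample.
#'
#' @param read_sets named list (sample id -> read tibble; `colors` +
#'   `primer` columns in colorspace mode, `sequence` in base-space mode).
#' @param ref the `reference_set`.
#' @param config a `pipeline_config`.
#' @return observation tibble (see [call_isomirs()]) with attribute
#'   `audit`.
#' @export
call_sample_isomirs <- function(read_sets, ref, config = pipeline_config()) {
  stopifnot(length(names(read_sets)) == length(read_sets))
  index <- build_align_index(ref, primer = config$primer,
                             adaptor = config$adaptor)
  all_obs <- list()
  audit <- list()
  for (s in names(read_sets)) {
    reads <- collapse_reads(read_sets[[s]])
    total <- sum(reads$count)
    reads <- filter_blacklist(reads, ref$blacklist)
    removed <- attr(reads, "removed_count")
    aligned <- align_reads(reads, index, mode = config$mode)
    aligned$sample_id <- s
    obs <- call_isomirs(aligned, ref)
    unaligned <- sum(attr(obs, "unaligned")$count)
    unassigned <- sum(attr(obs, "unassigned")$count)
    audit[[s]] <- tibble::tibble(
      sample_id = s, total = total, blacklisted = removed,
      unaligned = unaligned, unassigned = unassigned,
      assigned = sum(obs$count))
    all_obs[[s]] <- obs
  }
  out <- dplyr::bind_rows(all_obs)
  attr(out, "audit") <- dplyr::bind_rows(audit)
  out
}

#' Run the full isomiR analysis over sample libraries
#'
#' @param read_sets named list of per-sample read tibbles.
#' @param ref the `reference_set`.
#' @param config a `pipeline_config`.
#' @return list with `observations`, `audit`, `spectra`, `nta`,
#'   `heterogeneity`, `lengths`, `profiles` (most and sum),
#'   `top10` (per scheme), `venn` (per scheme, when >= 2 samples),
#'   `de_mirnas` and `de_modified` (per scheme and sample pair),
#'   `scheme_consistency` (per pair), `cleavage` (per sample),
#'   `correlation`.
#' @export
run_pipeline <- function(read_sets, ref, config = pipeline_config()) {
  obs <- call_sample_isomirs(read_sets, ref, config)
  spectra <- build_spectra(obs, min_count = config$report_min)
  nta <- nta_summary(spectra)
  het <- end_heterogeneity(spectra, ref)
  lens <- length_distribution(obs)
  prof_most <- quantify(spectra, "most")
  prof_sum <- quantify(spectra, "sum")
  top10 <- list(most = top_loci(prof_most), sum = top_loci(prof_sum))
  samples <- unique(obs$sample_id)
  venn <- NULL
  if (length(samples) %in% c(2L, 3L)) {
    venn <- lapply(top10, function(t10) {
      shared_species(split(t10$mature_id, t10$sample_id)[samples])
    })
  }
  pairs <- if (length(samples) >= 2L) utils::combn(samples, 2L, simplify = FALSE) else list()
  de_m <- list(); de_s <- list(); de_mod <- list(); consist <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "_vs_")
    de_m[[key]] <- de_mirnas(prof_most, p, config$abundant_locus_min,
                             config$lfc_threshold, config$impute_floor,
                             config$impute_value)
    de_s[[key]] <- de_mirnas(prof_sum, p, config$abundant_locus_min,
                             config$lfc_threshold, config$impute_floor,
                             config$impute_value)
    de_mod[[key]] <- de_modified_isomirs(spectra, p, config$modified_de_min,
                                         config$lfc_threshold,
                                         config$impute_floor,
                                         config$impute_value)
    consist[[key]] <- scheme_consistency(de_m[[key]], de_s[[key]])
  }
  cleav <- lapply(stats::setNames(samples, samples), function(s) {
    infer_cleavage_all(spectra, ref, sample = s,
                       dominance_fold = config$dominance_fold)
  })
  corr <- expression_type_correlation(spectra, "most",
                                      config$abundant_species_min,
                                      config$abundant_locus_min)
  list(observations = obs, audit = attr(obs, "audit"), spectra = spectra,
       nta = nta, heterogeneity = het, lengths = lens,
       profiles = list(most = prof_most, sum = prof_sum),
       top10 = top10, venn = venn,
       de_mirnas = list(most = de_m, sum = de_s), de_modified = de_mod,
       scheme_consistency = consist, cleavage = cleav, correlation = corr)
}

#' Write the pipeline result bundle as TSV tables
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  w(result$audit, "audit")
  w(result$spectra, "spectra")
  w(result$nta$totals, "nta_totals")
  w(result$nta$by_addition, "nta_by_addition")
  w(result$heterogeneity, "end_heterogeneity")
  w(result$lengths, "length_distribution")
  w(dplyr::bind_rows(most = result$top10$most, sum = result$top10$sum,
                     .id = "scheme"), "top10")
  for (scheme in names(result$de_mirnas)) {
    for (key in names(result$de_mirnas[[scheme]])) {
      w(result$de_mirnas[[scheme]][[key]],
        paste0("de_mirnas_", scheme, "_", key))
    }
  }
  for (key in names(result$de_modified)) {
    w(result$de_modified[[key]], paste0("de_modified_", key))
  }
  w(dplyr::bind_rows(result$cleavage, .id = "sample_id"), "cleavage")
  w(result$correlation$table, "expression_vs_types")
  invisible(dir)
}

#' Load the printed top-10 miRNA tables bundled with the package
#'
#' Accessors for the two published per-sample top-10 lists shipped under
#' `inst/extdata`: the top-10 abundant miRNAs per sample under both
#' estimation schemes, and the top-10 modified isomiRs (with spans) per
#' sample. These are the inputs of the shared-species worked examples.
#'
#' @return tibble.
#' @export
published_top10_mirnas <- function() {
  readr::read_tsv(system.file("extdata", "top10_mirnas.tsv",
                              package = "solmir"),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname published_top10_mirnas
#' @export
published_top10_modified_isomirs <- function() {
  readr::read_tsv(system.file("extdata", "top10_modified_isomirs.tsv",
                              package = "solmir"),
                  show_col_types = FALSE, progress = FALSE)
}
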