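# Expression profiling under the two estimation schemes, shared-species
# (Venn) analysis across samples, and differential-expression calling by
# imputed fold change. Single libraries without replicates: DE is a
# thresholded fold change on raw counts, not a statistical test.

#' Quantify miRNA expression from isomiR spectra
#'
#' Scheme `"most"` takes the sequence count of the most abundant isomiR of
#' each locus; scheme `"sum"` the total over all its isomiRs. The sum
#' scheme value is always at least the most scheme value.
#'
#' @param spectra batch spectra tibble from [build_spectra()].
#' @param scheme `"most"` or `"sum"`.
#' @return tibble `sample_id`, `mature_id`, `value` (attribute `scheme`).
#' @export
quantify <- function(spectra, scheme = c("most", "sum")) {
  scheme <- match.arg(scheme)
  if (nrow(spectra) == 0L) {
    out <- tibble::tibble(sample_id = character(), mature_id = character(),
                          value = integer())
    attr(out, "scheme") <- scheme
    return(out)
  }
  out <- spectra %>%
    dplyr::group_by(.data$sample_id, .data$mature_id) %>%
    dplyr::summarise(value = if (scheme == "most") max(.data$count)
                     else sum(.data$count),
                     .groups = "drop")
  attr(out, "scheme") <- scheme
  out
}

#' Top-N abundant loci per sample
#'
#' @param profile tibble from [quantify()].
#' @param n list length (default 10).
#' @return tibble `sample_id`, `rank`, `mature_id`, `value`, descending by
#'   value with ties broken by mature id ascending.
#' @export
top_loci <- function(profile, n = 10L) {
  profile %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::arrange(dplyr::desc(.data$value), .data$mature_id,
                   .by_group = TRUE) %>%
    dplyr::slice_head(n = n) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::select("sample_id", "rank", "mature_id", "value")
}

#' Venn regions of species lists across two or three samples
#'
#' Returns both readings used in practice: the pairwise-exclusive Venn
#' region cardinalities (what a Venn diagram displays: "common between A
#' and B" excludes the triple intersection) and the plain intersections.
#'
#' @param lists named list of 2 or 3 character vectors (sets; duplicates
#'   within a list are an error).
#' @return object of class `venn_regions`: list with `regions` (named
#'   exclusive region sizes summing to the union), `pairwise` (plain
#'   pairwise intersection sizes), `all` (size of the full intersection),
#'   `members` (the exclusive region members).
#' @export
shared_species <- function(lists) {
  k <- length(lists)
  if (!k %in% c(2L, 3L)) stop("need 2 or 3 lists", call. = FALSE)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- LETTERS[seq_len(k)]
  }
  for (nm in names(lists)) {
    if (anyDuplicated(lists[[nm]])) {
      stop("duplicate entries in list '", nm, "' (lists are sets)",
           call. = FALSE)
    }
  }
  nm <- names(lists)
  universe <- unique(unlist(lists))
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(z) paste(nm[z], collapse = "&"))
  region_names <- if (k == 2L) {
    c(nm[1], nm[2], paste(nm[1], nm[2], sep = "&"))
  } else {
    c(nm, paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
      paste(nm, collapse = "&"))
  }
  members <- lapply(region_names, function(r) universe[pattern == r])
  names(members) <- region_names
  regions <- vapply(members, length, integer(1))
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  pairwise <- vapply(pairs, function(p) {
    length(intersect(lists[[p[1]]], lists[[p[2]]]))
  }, integer(1))
  names(pairwise) <- vapply(pairs, paste, "", collapse = "&")
  all_n <- length(Reduce(intersect, lists))
  structure(list(regions = regions, pairwise = pairwise, all = all_n,
                 members = members),
            class = "venn_regions")
}

#' @export
print.venn_regions <- function(x, ...) {
  cat("<venn_regions>\n exclusive regions:\n")
  for (r in names(x$regions)) cat("  ", r, ": ", x$regions[r], "\n", sep = "")
  cat(" plain intersections:\n")
  for (r in names(x$pairwise)) cat("  ", r, ": ", x$pairwise[r], "\n", sep = "")
  cat("  all: ", x$all, "\n", sep = "")
  invisible(x)
}

#' Imputed log2 fold change between two counts
#'
#' Counts below `impute_floor` (including absent = 0) are replaced by
#' `impute_value` on each side independently before taking
#' `log2(a / b)`, which keeps every fold change finite and makes the
#' statistic antisymmetric in its arguments.
#'
#' @param count_a,count_b non-negative counts (vectorised).
#' @param impute_floor counts below this are imputed (default 100).
#' @param impute_value the imputed count (default 10).
#' @return tibble `log2fc`, `imputed_a`, `imputed_b`.
#' @export
log2_fold_change <- function(count_a, count_b, impute_floor = 100L,
                             impute_value = 10L) {
  imputed_a <- count_a < impute_floor
  imputed_b <- count_b < impute_floor
  a <- ifelse(imputed_a, impute_value, count_a)
  b <- ifelse(imputed_b, impute_value, count_b)
  tibble::tibble(log2fc = log2(a / b), imputed_a = imputed_a,
                 imputed_b = imputed_b)
}

.de_table <- function(values_a, values_b, units, sample_pair, min_count,
                      lfc_threshold, impute_floor, impute_value) {
  tested <- pmax(values_a, values_b) > min_count
  fc <- log2_fold_change(values_a[tested], values_b[tested],
                         impute_floor, impute_value)
  out <- tibble::tibble(unit = units[tested],
                        sample_a = sample_pair[1], sample_b = sample_pair[2],
                        value_a = values_a[tested], value_b = values_b[tested],
                        log2fc = fc$log2fc,
                        imputed_a = fc$imputed_a, imputed_b = fc$imputed_b,
                        significant = abs(fc$log2fc) > lfc_threshold)
  out[order(-abs(out$log2fc), out$unit, method = "radix"), ]
}

#' Differentially expressed miRNAs between two samples
#'
#' Loci whose expression exceeds `min_count` in at least one of the two
#' samples (on raw counts, before imputation) are tested; a locus is
#' marked significant when the absolute imputed log2 fold change exceeds
#' `lfc_threshold` (default 4, i.e. 16-fold).
#'
#' @param profile tibble from [quantify()] covering both samples.
#' @param sample_pair character vector `c(a, b)`; fold changes are
#'   `log2(a / b)`.
#' @param min_count abundance floor (default 999, i.e. >999 in at least
#'   one sample).
#' @param lfc_threshold significance threshold on `|log2fc|` (default 4).
#' @param impute_floor,impute_value imputation rule (defaults 100 and 10).
#' @return tibble of DE calls sorted by `|log2fc|` descending.
#' @export
de_mirnas <- function(profile, sample_pair, min_count = 999L,
                      lfc_threshold = 4, impute_floor = 100L,
                      impute_value = 10L) {
  stopifnot(length(sample_pair) == 2L)
  wide <- profile %>%
    dplyr::filter(.data$sample_id %in% sample_pair) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0L)
  for (s in sample_pair) if (!s %in% names(wide)) wide[[s]] <- 0L
  .de_table(wide[[sample_pair[1]]], wide[[sample_pair[2]]], wide$mature_id,
            sample_pair, min_count, lfc_threshold, impute_floor, impute_value)
}

#' Differentially expressed modified isomiRs between two samples
#'
#' The isomiR-resolution analogue of [de_mirnas()], restricted to species
#' carrying a 3' non-template addition and using a lower abundance floor
#' (default 300). Units are keyed by
#' `mature_id|template_start-template_end|addition`.
#'
#' @param spectra batch spectra tibble covering both samples.
#' @inheritParams de_mirnas
#' @param min_count abundance floor (default 300, i.e. >300).
#' @return tibble of DE calls sorted by `|log2fc|` descending.
#' @export
de_modified_isomirs <- function(spectra, sample_pair, min_count = 300L,
                                lfc_threshold = 4, impute_floor = 100L,
                                impute_value = 10L) {
  mod <- spectra %>%
    dplyr::filter(nzchar(.data$addition),
                  .data$sample_id %in% sample_pair) %>%
    dplyr::mutate(unit = paste0(.data$mature_id, "|", .data$template_start,
                                "-", .data$template_end, "|",
                                gsub("T", "U", .data$addition, fixed = TRUE)))
  wide <- mod %>%
    dplyr::select("unit", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  for (s in sample_pair) if (!s %in% names(wide)) wide[[s]] <- rep(0L, nrow(wide))
  .de_table(wide[[sample_pair[1]]], wide[[sample_pair[2]]], wide$unit,
            sample_pair, min_count, lfc_threshold, impute_floor, impute_value)
}

#' Agreement of DE calls between the two estimation schemes
#'
#' Compares the significant sets from two DE tables over the same sample
#' pair (typically the most-abundant-isomiR and sum-of-isomiRs schemes)
#' and reports their Jaccard index. Two empty sets are in perfect
#' agreement (Jaccard 1).
#'
#' @param de_most,de_sum DE tables from [de_mirnas()].
#' @return list with `jaccard`, `both`, `only_most`, `only_sum` and a
#'   per-locus membership `table`.
#' @export
scheme_consistency <- function(de_most, de_sum) {
  sig_m <- de_most$unit[de_most$significant]
  sig_s <- de_sum$unit[de_sum$significant]
  u <- union(sig_m, sig_s)
  jac <- if (length(u) == 0L) 1 else length(intersect(sig_m, sig_s)) / length(u)
  tab <- tibble::tibble(unit = sort(union(de_most$unit, de_sum$unit)))
  tab$significant_most <- tab$unit %in% sig_m
  tab$significant_sum <- tab$unit %in% sig_s
  list(jaccard = jac,
       both = sort(intersect(sig_m, sig_s)),
       only_most = sort(setdiff(sig_m, sig_s)),
       only_sum = sort(setdiff(sig_s, sig_m)),
       table = tab)
}
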