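#!/usr/bin/env Rscript
# Stage 6: aggregate the study into one JSON + TSV bundle, including a
# recovery audit against the simulator's ground truth.

suppressMessages({
  library(solmir)
  library(jsonlite)
})

need <- c("results/calls/audit.tsv", "results/spectrum/nta_totals.tsv",
          "results/spectrum/end_heterogeneity.tsv")
for (f in need) {
  if (!file.exists(f)) stop("missing ", f, ": run earlier stages first",
                            call. = FALSE)
}
out <- "results/report"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

audit <- readr::read_tsv("results/calls/audit.tsv", show_col_types = FALSE)
nta <- readr::read_tsv("results/spectrum/nta_totals.tsv",
                       show_col_types = FALSE)
het <- readr::read_tsv("results/spectrum/end_heterogeneity.tsv",
                       show_col_types = FALSE)
obs <- readr::read_tsv("results/calls/observations.tsv",
                       show_col_types = FALSE)
obs$addition[is.na(obs$addition)] <- ""

# recovery audit: observed counts vs planted truth per sample
recov <- lapply(c("normal", "mild", "severe"), function(s) {
  truth <- read_truth(file.path("results/sim", paste0("truth_", s)))$species
  o <- obs[obs$sample_id == s, ]
  m <- merge(truth[c("mature_id", "template_start", "template_end",
                     "addition", "count")],
             o[c("mature_id", "template_start", "template_end", "addition",
                 "count")],
             by = c("mature_id", "template_start", "template_end", "addition"),
             all = TRUE, suffixes = c("_truth", "_called"))
  m[is.na(m)] <- 0
  tibble::tibble(sample_id = s,
                 planted_species = sum(m$count_truth > 0),
                 recovered_species = sum(m$count_truth > 0 & m$count_called > 0),
                 count_abs_error = sum(abs(m$count_called - m$count_truth)),
                 count_total = sum(m$count_truth))
})
recov <- dplyr::bind_rows(recov)
readr::write_tsv(recov, file.path(out, "truth_recovery.tsv"))
print(as.data.frame(recov))

summary <- list(
  samples = audit$sample_id,
  reads_total = sum(audit$total),
  reads_assigned_pct = 100 * sum(audit$assigned) / sum(audit$total),
  nta_type_share_pct = stats::setNames(100 * nta$type_fraction, nta$sample_id),
  nta_count_share_pct = stats::setNames(100 * nta$count_fraction,
                                        nta$sample_id),
  heterogeneity_3p_pct = stats::setNames(100 * het$frac_3p_variant,
                                         het$sample_id),
  heterogeneity_5p_pct = stats::setNames(100 * het$frac_5p_variant,
                                         het$sample_id),
  species_recovered = sum(recov$recovered_species),
  species_planted = sum(recov$planted_species),
  count_error_rate = sum(recov$count_abs_error) / sum(recov$count_total))
write_json(summary, file.path(out, "summary.json"), auto_unbox = TRUE,
           digits = 4, pretty = TRUE)
cat("\nreport bundle written to", out, "\n")
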