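#!/usr/bin/env Rscript
# Stage 3: per-locus isomiR spectra and repertoire statistics.
#
# From the called observations: spectra at the report threshold (>= 10
# counts), the 3' addition share panels (species- and read-weighted, per
# addition, with the double-addition table), 5'/3' end heterogeneity,
# read-length distributions, and the expression-versus-isomiR-type
# relationship.

suppressMessages(library(solmir))

if (!file.exists("results/calls/observations.tsv")) {
  stop("missing results/calls: run analysis/02_call_isomirs.R first",
       call. = FALSE)
}
out <- "results/spectrum"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prec <- read_precursor_fasta("results/sim/precursors.fa")
ann <- read_mature_annotations("results/sim/matures.tsv", prec)
ref <- reference_set(prec, ann)
obs <- readr::read_tsv("results/calls/observations.tsv",
                       show_col_types = FALSE)
obs$addition[is.na(obs$addition)] <- ""

spectra <- build_spectra(obs, min_count = 10L)
readr::write_tsv(spectra, file.path(out, "spectra.tsv"))

nta <- nta_summary(spectra)
readr::write_tsv(nta$totals, file.path(out, "nta_totals.tsv"))
readr::write_tsv(nta$by_addition, file.path(out, "nta_by_addition.tsv"))
readr::write_tsv(nta$doubles, file.path(out, "nta_doubles.tsv"))
cat("3' addition shares (type / reads):\n")
print(as.data.frame(nta$totals))

# the paper-style abundant-species variant of the panels (counts > 99)
nta100 <- nta_summary(build_spectra(obs, min_count = 100L))
readr::write_tsv(nta100$totals, file.path(out, "nta_totals_abundant.tsv"))

het <- end_heterogeneity(spectra, ref)
readr::write_tsv(het, file.path(out, "end_heterogeneity.tsv"))
cat("\nend heterogeneity (5' vs 3' variant species):\n")
print(as.data.frame(het))

lens <- length_distribution(obs)
readr::write_tsv(lens, file.path(out, "length_distribution.tsv"))
cat("\nmodal read length per sample:\n")
print(attr(lens, "mode"))

corr <- expression_type_correlation(spectra, "most")
readr::write_tsv(corr$table, file.path(out, "expression_vs_types.tsv"))
cat("\nSpearman rho, expression vs number of isomiR types:\n")
print(round(corr$rho, 3))
cat("\ntables written to", out, "\n")
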