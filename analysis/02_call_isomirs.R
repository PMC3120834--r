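#!/usr/bin/env Rscript
# Stage 2: call isomiRs from the simulated colorspace libraries.
#
# Reads the reference and the CSFASTA libraries written by 01_simulate.R,
# collapses and aligns the reads (one corrected color mismatch; 3'
# additions by the two-junction-color boundary rule), assigns alignments
# to mature loci and writes the observation table plus the count audit.

suppressMessages(library(solmir))

sim <- "results/sim"
if (!file.exists(file.path(sim, "precursors.fa"))) {
  stop("missing ", sim, ": run analysis/01_simulate.R first", call. = FALSE)
}
out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prec <- read_precursor_fasta(file.path(sim, "precursors.fa"))
ann <- read_mature_annotations(file.path(sim, "matures.tsv"), prec)
ref <- reference_set(prec, ann)

samples <- c("normal", "mild", "severe")
reads <- lapply(stats::setNames(samples, samples), function(s) {
  read_csfasta(file.path(sim, paste0(s, ".csfasta")))
})

obs <- call_sample_isomirs(reads, ref)
audit <- attr(obs, "audit")
readr::write_tsv(label_isomirs(obs, ref), file.path(out, "observations.tsv"))
readr::write_tsv(audit, file.path(out, "audit.tsv"))

print(audit)
cat(sprintf("%.3f%% of reads assigned to a mature locus\n",
            100 * sum(audit$assigned) / sum(audit$total)))
cat("observations written to", out, "\n")
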