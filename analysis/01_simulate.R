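#!/usr/bin/env Rscript
# Stage 1: simulate the three-sample study.
#
# Builds the reference set (30 loci) and three SOLiD-style colorspace
# libraries (normal / mild / severe, 1e5 reads each) with the planted
# study structure: 1-3 abundant isomiRs per locus, 3' end shifts dominating
# 5' shifts, adenosine-biased single and double 3' additions carried by
# minor species, per-color sequencing errors, and six +/-6 log2 effects
# planted in the severe sample. Writes the reference, the read libraries
# (CSFASTA and FASTA) and the per-sample ground truth under results/sim/.

suppressMessages(library(solmir))

seed <- 20260923L %% 1000000L   # fixed study seed
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_loci = 30L, n_reads = 100000L, seed = seed)
ref <- generate_reference(cfg)
write_precursor_fasta(ref$precursors, file.path(out, "precursors.fa"))
write_mature_annotations(ref$annotations, file.path(out, "matures.tsv"))

for (s in cfg$samples) {
  lib <- generate_library(ref, cfg, s, seed = seed + match(s, cfg$samples))
  write_csfasta(lib$reads_cs, file.path(out, paste0(s, ".csfasta")),
                expand = TRUE)
  write_read_fasta(lib$reads_bs, file.path(out, paste0(s, ".fa")))
  write_truth(lib$truth, file.path(out, paste0("truth_", s)))
  n_mod <- sum(lib$truth$species$modified)
  cat(sprintf("%-7s %6d reads, %3d planted species (%d with 3' additions)\n",
              s, sum(lib$truth$species$count), nrow(lib$truth$species),
              n_mod))
}
cat("reference and libraries written to", out, "\n")
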