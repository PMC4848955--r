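#!/usr/bin/env Rscript
# Generate the synthetic two-genotype x three-stage small RNA study:
# genome with embedded hairpins and TE loci, precursor catalogs,
# transcripts with planted target sites, ncRNA contaminants, six FASTQ
# libraries and the machine-readable truth table.

suppressPackageStartupMessages(library(pollensmrna))

out_dir <- "results/synth"
cfg <- synth_config(seed = 1)
ref <- make_reference(cfg)
sim <- simulate_libraries(cfg, ref, out_dir)
paths <- write_reference(ref, out_dir)
write.table(cfg$design, file.path(out_dir, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("genome: %d nt; %d rice precursors, %d other-species, %d TE loci",
                nchar(ref$genome$sequence), nrow(ref$rice_precursors),
                nrow(ref$other_precursors), nrow(ref$te_loci)))
message(sprintf("planted: %d miRNA tags (%d with expected names), %d TE siRNA tags",
                nrow(ref$mirna_truth), sum(!is.na(ref$mirna_truth$name)),
                nrow(ref$te_tags)))
for (l in names(sim$fastq)) {
  n <- length(readLines(sim$fastq[[l]])) / 4
  message(sprintf("  %s: %d reads", l, n))
}
message("reference, libraries and truth table written under ", out_dir)
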