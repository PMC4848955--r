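#!/usr/bin/env Rscript
# Predict target sites for the differentially expressed miRNAs by
# complementarity scoring (seed 2-13 doubled, G:U 0.5, mismatch 1.0,
# emitted at score <= 4), roll transcripts up to genes, and run
# hypergeometric term enrichment per stage and direction.

suppressPackageStartupMessages(library(pollensmrna))

catalog <- read.delim("results/catalog.tsv")
design <- read.delim("results/synth/design.tsv")
dem_gen <- lapply(setNames(c("PMA", "MA", "SCP"), c("PMA", "MA", "SCP")),
                  function(st) {
                    read.delim(sprintf("results/dem_genotype_%s.tsv", st))
                  })
dem_names <- unique(unlist(lapply(dem_gen, function(d) {
  d$name[d$call != "ns"]
})))
mirnas <- catalog[match(dem_names, catalog$name), c("name", "sequence")]

transcripts <- read_fasta("results/synth/transcripts.fa")
targets <- predict_targets(mirnas, transcripts)
write.table(targets, "results/targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d target sites on %d genes for %d of %d DEM",
                nrow(targets), length(unique(targets$gene)),
                length(unique(targets$mirna)), length(dem_names)))

annotation <- read.delim("results/synth/annotation.tsv")
enr <- enrich_by_direction(dem_gen, targets, annotation)
for (nm in names(enr)) {
  write.table(enr[[nm]], sprintf("results/enrichment_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- sum(enr[[nm]]$p <= 0.05)
  message(sprintf("  %s: %d terms tested, %d with p <= 0.05",
                  nm, nrow(enr[[nm]]), sig))
}
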