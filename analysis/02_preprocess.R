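#!/usr/bin/env Rscript
# Clean the raw reads (adapter, quality, length 18-30 nt, complexity),
# collapse them to unique tags with per-library counts and remove
# rRNA/tRNA/snRNA/snoRNA matches.

suppressPackageStartupMessages(library(pollensmrna))

synth <- "results/synth"
design <- read.delim(file.path(synth, "design.tsv"))
fastq <- setNames(file.path(synth, paste0(design$library_id, ".fastq")),
                  design$library_id)
cfg <- synth_config()  # the simulated adapter is the generator default

contam <- read_fasta(file.path(synth, "ncrna.fa"))
pp <- preprocess_libraries(fastq, cfg$adapter, contam)

write_count_table(setNames(pp$tags, c("id", design$library_id)),
                  "results/tags.tsv", kind = "raw")
write.table(pp$stats, "results/clean_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("%d unique tags kept (%d ncRNA tags removed)",
                nrow(pp$tags), nrow(pp$removed_ncrna)))
for (i in seq_len(nrow(pp$stats))) {
  s <- pp$stats[i, ]
  message(sprintf("  %s: %d raw -> %d clean (%.1f%%), %d unique tags",
                  s$library, s$raw_reads, s$clean_reads,
                  100 * s$clean_reads / s$raw_reads, s$unique_tags))
}
sizes <- table(nchar(pp$tags$sequence))
message("tag size histogram (unique tags): ",
        paste(sprintf("%snt=%d", names(sizes), sizes), collapse = " "))
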