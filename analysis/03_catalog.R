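#!/usr/bin/env Rscript
# Identify miRNAs: map unique tags to rice precursor hairpins (known
# mature arms and opposite arms), to genome-mapped other-species
# precursors, and scan the remaining expressed tags for novel genomic
# hairpin candidates; derive isomiR variant names and compare with the
# planted truth.

suppressPackageStartupMessages(library(pollensmrna))
suppressPackageStartupMessages(library(jsonlite))

synth <- "results/synth"
tags <- read_count_table("results/tags.tsv")
names(tags)[1] <- "sequence"

genome <- read_fasta(file.path(synth, "genome.fa"))
rice <- read_precursors(file.path(synth, "rice_precursors.fa"),
                        file.path(synth, "rice_mature.tsv"))
other <- read_precursors(file.path(synth, "other_precursors.fa"),
                         file.path(synth, "other_mature.tsv"))

res <- build_catalog(tags, rice, other, genome)
cat_tab <- res$catalog
names(cat_tab)[1] <- "id"
write_count_table(cat_tab[, c("id", setdiff(names(cat_tab),
                                            c("id", "sequence",
                                              "category", "source")))],
                  "results/catalog_counts.tsv", kind = "raw")
write.table(res$catalog, "results/catalog.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("catalog: %d miRNA records from %d tags",
                nrow(res$catalog), nrow(tags)))
for (cat_ in names(table(res$catalog$category))) {
  message(sprintf("  %-35s %d", cat_,
                  sum(res$catalog$category == cat_)))
}

truth <- fromJSON(file.path(synth, "truth.json"))
tc <- truth_compare(res$assignments, truth$mirna)
message(sprintf("planted-category recovery %.1f%%, variant-name recovery %.1f%%",
                100 * tc$category_recall, 100 * tc$name_recall))
write_json(list(category_recall = tc$category_recall,
                name_recall = tc$name_recall,
                precision = tc$precision),
           "results/catalog_recovery.json", auto_unbox = TRUE)
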