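#!/usr/bin/env Rscript
# Profile TE-associated siRNAs: residual (non-miRNA, non-ncRNA) tags
# mapped exactly into annotated transposable-element loci, 24-nt mean
# normalized abundance per TE type and library, and the per-genotype
# stage trends.

suppressPackageStartupMessages(library(pollensmrna))
suppressPackageStartupMessages(library(jsonlite))

synth <- "results/synth"
design <- read.delim(file.path(synth, "design.tsv"))
libs <- design$library_id
tags <- read_count_table("results/tags.tsv")
names(tags)[1] <- "sequence"
assignments_cat <- read.delim("results/catalog.tsv")
catalog_assign <- data.frame(sequence = assignments_cat$sequence,
                             name = assignments_cat$name,
                             stringsAsFactors = FALSE)
contam <- read_fasta(file.path(synth, "ncrna.fa"))
genome <- read_fasta(file.path(synth, "genome.fa"))
te_loci <- read_te_annotation(file.path(synth, "te_loci.gff3"), "gff3")

sirna <- extract_sirna(tags, catalog_assign, contam)
asg <- assign_to_te(sirna, genome, te_loci)
message(sprintf("%d residual tags; %d distinct siRNAs in %d TE types",
                nrow(sirna), length(unique(asg$sequence)),
                nrow(unique(asg[, c("te_class", "te_type")]))))

fits <- fromJSON("results/normalization_fits.json")
f <- setNames(fits$f, fits$sample)
full_mat <- as.matrix(tags[, libs])
rownames(full_mat) <- tags$sequence
norm_tags <- sweep(full_mat, 2, f[libs], `*`)

te_ab <- te_type_abundance(asg, norm_tags, size = 24L)
write.table(te_ab, "results/te_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
trend <- stage_trend(te_ab, design)
write.table(trend, "results/te_trend.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (g in c("2x", "4x")) {
  tg <- trend[trend$genotype == g, ]
  message(sprintf("%s: %d/%d TE types decreasing across PMA->MA->SCP",
                  g, sum(tg$trend == "decreasing"), nrow(tg)))
}
main <- trend[trend$te_type %in% c("Ty3-gypsy", "En/Spm", "unclassified"), ]
for (i in seq_len(nrow(main))) {
  r <- main[i, ]
  message(sprintf("  %s %s/%s: PMA %.0f MA %.0f SCP %.0f (%s)",
                  r$genotype, r$te_class, r$te_type, r$PMA, r$MA, r$SCP,
                  r$trend))
}
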