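#!/usr/bin/env Rscript
# Normalize copy numbers with the median-reference regression
# procedure (reference over all unique tags; per-library factors
# applied to the catalog), then call differentially expressed miRNAs
# between genotypes per stage and between adjacent stages per
# genotype, with the accounting summary.

suppressPackageStartupMessages(library(pollensmrna))
suppressPackageStartupMessages(library(jsonlite))

design <- read.delim("results/synth/design.tsv")
libs <- design$library_id
tags <- read_count_table("results/tags.tsv")
full_mat <- as.matrix(tags[, libs])
rownames(full_mat) <- tags$id
stats <- read.delim("results/clean_stats.tsv")
lib_totals <- setNames(as.list(stats$clean_reads), stats$library)

norm <- normalize_matrix(full_mat)
write_fits_json(norm$fits, "results/normalization_fits.json")
message("correction factors: ",
        paste(sprintf("%s=%.3f", libs,
                      vapply(norm$fits[libs], `[[`, numeric(1), "f")),
              collapse = " "))

catalog <- read.delim("results/catalog.tsv")
cat_mat <- as.matrix(catalog[, libs])
rownames(cat_mat) <- catalog$name
norm_cat <- apply_normalization(cat_mat, norm$fits)
norm_tab <- data.frame(id = rownames(norm_cat), norm_cat,
                       check.names = FALSE)
write_count_table(norm_tab, "results/catalog_normalized.tsv",
                  kind = "normalized")

cfg <- dem_config()
dem_gen <- call_dem_between_genotypes(norm_cat, cat_mat, lib_totals,
                                      design, cfg)
dem_2x <- call_dem_between_stages(norm_cat, cat_mat, lib_totals,
                                  design, "2x", cfg)
dem_4x <- call_dem_between_stages(norm_cat, cat_mat, lib_totals,
                                  design, "4x", cfg)

for (st in names(dem_gen)) {
  write.table(dem_gen[[st]], sprintf("results/dem_genotype_%s.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
summary <- summarize_dem(dem_gen, nrow(catalog))
part <- stage_specific_partition(dem_2x, dem_4x)
write.table(part, "results/dem_stage_partition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_json(summary, "results/dem_summary.json", auto_unbox = TRUE,
           digits = NA)

message(sprintf("DEM between genotypes: %d of %d miRNAs (%.2f%%)",
                summary$n_dem, nrow(catalog), summary$pct_of_detected))
for (i in seq_len(nrow(summary$per_stage))) {
  s <- summary$per_stage[i, ]
  message(sprintf("  %s: %d up / %d down", s$stage, s$n_up, s$n_down))
}
message(sprintf("stage-specific DEM: %d (%.2f%% of DEM); %d up / %d down distinct",
                summary$n_stage_specific, summary$pct_stage_specific,
                summary$up_total, summary$down_total))
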