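#!/usr/bin/env Rscript
# Assemble the run's headline numbers into a markdown + JSON report.

suppressPackageStartupMessages(library(pollensmrna))
suppressPackageStartupMessages(library(jsonlite))

catalog <- read.delim("results/catalog.tsv")
summary <- fromJSON("results/dem_summary.json")
recovery <- fromJSON("results/catalog_recovery.json")
trend <- read.delim("results/te_trend.tsv")
stats <- read.delim("results/clean_stats.tsv")

lines <- c(
  "# Synthetic pollen small RNA study: run report", "",
  sprintf("Libraries: %d; raw reads %s; clean reads %s.",
          nrow(stats), format(sum(stats$raw_reads), big.mark = ","),
          format(sum(stats$clean_reads), big.mark = ",")),
  "",
  sprintf("Catalog: %d miRNA records.", nrow(catalog)),
  paste(sprintf("- %s: %d", names(table(catalog$category)),
                as.integer(table(catalog$category))), collapse = "\n"),
  "",
  sprintf("Planted recovery: categories %.1f%%, variant names %.1f%%.",
          100 * recovery$category_recall, 100 * recovery$name_recall),
  "",
  sprintf("DEM between genotypes: %d (%.2f%% of detected); stage-specific %d (%.2f%%).",
          summary$n_dem, summary$pct_of_detected,
          summary$n_stage_specific, summary$pct_stage_specific),
  sprintf("Distinct up/down: %d / %d (consistent %d / %d, reversed %d).",
          summary$up_total, summary$down_total, summary$up_consistent,
          summary$down_consistent, summary$n_reversed),
  "",
  "Per-stage DEM:",
  paste(sprintf("- %s: %d up / %d down", summary$per_stage$stage,
                summary$per_stage$n_up, summary$per_stage$n_down),
        collapse = "\n"),
  "",
  sprintf("TE siRNA stage trends: diploid decreasing in %d/%d types; autotetraploid decreasing in %d/%d.",
          sum(trend$trend[trend$genotype == "2x"] == "decreasing"),
          sum(trend$genotype == "2x"),
          sum(trend$trend[trend$genotype == "4x"] == "decreasing"),
          sum(trend$genotype == "4x")))

writeLines(lines, "results/report.md")
write_json(list(catalog = as.list(table(catalog$category)),
                dem = summary, recovery = recovery),
           "results/report.json", auto_unbox = TRUE, digits = NA)
message(paste(lines, collapse = "\n"))
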