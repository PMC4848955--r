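# Orchestration: run the whole analysis (preprocess -> catalog ->
# normalize -> DEM -> targets -> siRNA-TE -> enrichment) from one
# configuration, with per-stage logging and deterministic outputs.

#' Validate a study design table
#'
#' @param design data.frame with `library_id`, `genotype`, `stage`.
#' @return the design, invisibly; errors list every violation at once.
#' @export
validate_design <- function(design) {
  errs <- character(0)
  need <- c("library_id", "genotype", "stage")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    errs <- c(errs, paste("missing design columns:",
                          paste(miss, collapse = ", ")))
  } else {
    bad_g <- setdiff(unique(design$genotype), GENOTYPES)
    if (length(bad_g)) {
      errs <- c(errs, paste0("unknown genotype label(s): ",
                             paste(bad_g, collapse = ", "),
                             "; allowed: ", paste(GENOTYPES, collapse = ", ")))
    }
    bad_s <- setdiff(unique(design$stage), STAGES)
    if (length(bad_s)) {
      errs <- c(errs, paste0("unknown stage label(s): ",
                             paste(bad_s, collapse = ", "),
                             "; allowed: ", paste(STAGES, collapse = ", ")))
    }
    if (anyDuplicated(design$library_id)) {
      errs <- c(errs, "duplicated library ids")
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(design)
}

#' Validate a pipeline run configuration
#'
#' @param cfg list with input paths (`fastq` named vector, `adapter`,
#'   `ncrna`, `rice_fa`, `rice_sidecar`, `other_fa`, `other_sidecar`,
#'   `genome`, `te_gff3`, `transcripts`, `annotation`) and a `design`
#'   table.
#' @return the config, invisibly; errors list every violation at once.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  for (key in c("fastq", "ncrna", "rice_fa", "rice_sidecar", "genome",
                "te_gff3", "transcripts", "annotation")) {
    if (is.null(cfg[[key]])) {
      errs <- c(errs, paste("missing config entry:", key))
    } else {
      missing_files <- cfg[[key]][!file.exists(cfg[[key]])]
      if (length(missing_files)) {
        errs <- c(errs, paste("file not found:",
                              paste(missing_files, collapse = ", ")))
      }
    }
  }
  if (is.null(cfg$design)) {
    errs <- c(errs, "missing design table")
  } else {
    d_err <- tryCatch({
      validate_design(cfg$design)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(d_err)) errs <- c(errs, d_err)
  }
  if (is.null(cfg$adapter) || !nzchar(cfg$adapter)) {
    errs <- c(errs, "missing adapter sequence")
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(cfg)
}

tag_matrix <- function(tags, libs) {
  m <- as.matrix(tags[, libs, drop = FALSE])
  rownames(m) <- tags$sequence
  m
}

#' Run the full analysis pipeline
#'
#' @param cfg validated configuration (see [validate_config()]).
#' @param dem_cfg [dem_config()].
#' @param params [scoring_params()].
#' @param verbose log stage boundaries with read/tag counts.
#' @return list with every stage's outputs: `stats`, `tags`,
#'   `catalog`, `fits`, `normalized`, `dem_genotype`, `dem_stages_2x`,
#'   `dem_stages_4x`, `dem_summary`, `stage_partition`, `targets`,
#'   `enrichment`, `sirna`, `te_abundance`, `te_trend`.
#' @export
run_pipeline <- function(cfg, dem_cfg = dem_config(),
                         params = scoring_params(), verbose = TRUE) {
  validate_config(cfg)
  design <- cfg$design
  libs <- design$library_id
  say <- function(...) if (verbose) message(sprintf(...))

  contaminants <- read_fasta(cfg$ncrna)
  pp <- preprocess_libraries(cfg$fastq[libs], cfg$adapter, contaminants)
  say("preprocess: %d unique tags kept over %d libraries",
      nrow(pp$tags), length(libs))

  genome <- read_fasta(cfg$genome)
  rice <- read_precursors(cfg$rice_fa, cfg$rice_sidecar)
  other <- if (!is.null(cfg$other_fa)) {
    read_precursors(cfg$other_fa, cfg$other_sidecar)
  } else {
    NULL
  }
  cat_res <- build_catalog(pp$tags, rice, other, genome)
  say("catalog: %d miRNA records (%s)", nrow(cat_res$catalog),
      paste(names(table(cat_res$catalog$category)),
            table(cat_res$catalog$category), collapse = ", "))

  # the normalization reference is built over the full unique-tag
  # copy-number matrix; the per-library factors are then applied to
  # the catalog counts
  full_mat <- tag_matrix(pp$tags, libs)
  norm <- normalize_matrix(full_mat)
  cat_mat <- as.matrix(cat_res$catalog[, libs, drop = FALSE])
  rownames(cat_mat) <- cat_res$catalog$name
  norm_cat <- apply_normalization(cat_mat, norm$fits)
  lib_totals <- setNames(as.list(pp$stats$clean_reads), pp$stats$library)
  say("normalize: factors %s",
      paste(sprintf("%s=%.3f", libs,
                    vapply(norm$fits[libs], `[[`, numeric(1), "f")),
            collapse = " "))

  dem_gen <- call_dem_between_genotypes(norm_cat, cat_mat,
                                        lib_totals, design, dem_cfg)
  dem_2x <- call_dem_between_stages(norm_cat, cat_mat, lib_totals,
                                    design, "2x", dem_cfg)
  dem_4x <- call_dem_between_stages(norm_cat, cat_mat, lib_totals,
                                    design, "4x", dem_cfg)
  dem_summary <- summarize_dem(dem_gen, nrow(cat_res$catalog))
  stage_part <- stage_specific_partition(dem_2x, dem_4x)
  say("DEM: %d between genotypes (%.2f%% of %d miRNAs)",
      dem_summary$n_dem, dem_summary$pct_of_detected,
      nrow(cat_res$catalog))

  dem_names <- unique(unlist(lapply(dem_gen, function(d) {
    d$name[d$call != "ns"]
  })))
  dem_seqs <- cat_res$catalog[match(dem_names, cat_res$catalog$name),
                              c("name", "sequence")]
  transcripts <- read_fasta(cfg$transcripts)
  targets <- predict_targets(
    data.frame(name = dem_seqs$name, sequence = dem_seqs$sequence,
               stringsAsFactors = FALSE),
    transcripts, params)
  say("targets: %d sites for %d DEM", nrow(targets),
      length(unique(targets$mirna)))

  annotation <- read.delim(cfg$annotation, stringsAsFactors = FALSE)
  enr <- enrich_by_direction(dem_gen, targets, annotation)

  te_loci <- read_te_annotation(cfg$te_gff3, "gff3")
  sirna <- extract_sirna(pp$tags, cat_res$assignments, contaminants)
  assignments <- assign_to_te(sirna, genome, te_loci)
  norm_tags <- norm$normalized
  te_ab <- te_type_abundance(assignments, norm_tags, 24L)
  te_tr <- stage_trend(te_ab, design)
  say("siRNA-TE: %d residual tags, %d assigned to TE types",
      nrow(sirna), length(unique(assignments$sequence)))

  list(stats = pp$stats, tags = pp$tags, catalog = cat_res$catalog,
       assignments = cat_res$assignments, fits = norm$fits,
       normalized = norm_cat, normalized_tags = norm$normalized,
       dem_genotype = dem_gen,
       dem_stages_2x = dem_2x, dem_stages_4x = dem_4x,
       dem_summary = dem_summary, stage_partition = stage_part,
       targets = targets, enrichment = enr, sirna = sirna,
       te_assignments = assignments, te_abundance = te_ab,
       te_trend = te_tr)
}

#' Summarize a pipeline run as a report list
#'
#' @param run [run_pipeline()] output.
#' @return list with catalog category counts, per-stage DEM counts,
#'   percentages and TE trends, suitable for JSON serialization.
#' @export
pipeline_report <- function(run) {
  list(
    n_mirnas = nrow(run$catalog),
    categories = as.list(table(run$catalog$category)),
    dem = run$dem_summary,
    stage_partition = run$stage_partition,
    te_trend = run$te_trend)
}
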