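# TE-associated siRNA profiling: residual (non-miRNA, non-ncRNA) tags
# are mapped exactly to the genome, assigned to transposable-element
# loci by full containment, and summarized as per-type mean normalized
# expression with a 24-nt focus.

#' Extract residual siRNA tags
#'
#' Residual tags are those not assigned any miRNA name in the catalog
#' and not matching the ncRNA contaminant set.
#'
#' @param tags unique-tag table.
#' @param catalog_assignments per-tag assignment table from
#'   [build_catalog()] (`$assignments`), or `NULL`.
#' @param contaminant_db ncRNA sequence table, or `NULL`.
#' @return tag table of residual tags.
#' @export
extract_sirna <- function(tags, catalog_assignments = NULL,
                          contaminant_db = NULL) {
  keep <- rep(TRUE, nrow(tags))
  if (!is.null(catalog_assignments)) {
    assigned <- catalog_assignments$sequence[
      !is.na(catalog_assignments$name)]
    keep <- keep & !tags$sequence %in% assigned
  }
  if (!is.null(contaminant_db) && nrow(contaminant_db)) {
    hay <- paste(c(contaminant_db$sequence,
                   revcomp(contaminant_db$sequence)), collapse = "#")
    keep <- keep & !stringi::stri_detect_fixed(hay, tags$sequence)
  }
  tags[keep, , drop = FALSE]
}

#' Assign tags to transposable-element loci
#'
#' A tag is assigned to a locus iff it maps exactly to the genome (on
#' either strand) with its full span inside the locus interval.
#' Multi-locus tags are assigned to every containing locus but counted
#' once per (tag, te_type).
#'
#' @param tags tag table (residual siRNAs).
#' @param genome genome sequence table.
#' @param te_loci TE annotation from [read_te_annotation()].
#' @return data.frame with `sequence`, `te_class`, `te_type` (unique
#'   tag-type pairs) plus `length` of the tag.
#' @export
assign_to_te <- function(tags, genome, te_loci) {
  if (!nrow(tags) || !nrow(te_loci)) {
    return(data.frame(sequence = character(), te_class = character(),
                      te_type = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  te_gr <- GenomicRanges::GRanges(
    te_loci$chrom,
    IRanges::IRanges(start = te_loci$start + 1L, end = te_loci$end))
  # cheap prescreen: only exactly genome-mapped tags can be assigned
  genome_hay <- paste(genome$sequence, collapse = "#")
  mapped <- stringi::stri_detect_fixed(genome_hay, tags$sequence) |
    stringi::stri_detect_fixed(genome_hay, revcomp(tags$sequence))
  hit_rows <- list()
  for (i in which(mapped)) {
    hits <- genome_hits(tags$sequence[i], genome)
    if (!nrow(hits)) next
    hits$sequence <- tags$sequence[i]
    hit_rows[[length(hit_rows) + 1L]] <- hits
  }
  if (!length(hit_rows)) {
    return(data.frame(sequence = character(), te_class = character(),
                      te_type = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, hit_rows)
  tag_gr <- GenomicRanges::GRanges(
    hits$chrom,
    IRanges::IRanges(start = hits$start + 1L, end = hits$end))
  ov <- GenomicRanges::findOverlaps(tag_gr, te_gr, type = "within")
  if (!length(ov)) {
    return(data.frame(sequence = character(), te_class = character(),
                      te_type = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    sequence = hits$sequence[S4Vectors::queryHits(ov)],
    te_class = te_loci$te_class[S4Vectors::subjectHits(ov)],
    te_type = te_loci$te_type[S4Vectors::subjectHits(ov)],
    length = nchar(hits$sequence[S4Vectors::queryHits(ov)]),
    stringsAsFactors = FALSE)
  unique(out)
}

#' Per-type, per-library mean abundance of size-selected TE siRNAs
#'
#' @param assignments from [assign_to_te()].
#' @param norm_mat normalized count matrix with tag sequences as
#'   rownames and libraries as columns.
#' @param size tag length to keep (default 24 nt; `NA` keeps all).
#' @return data.frame with `te_class`, `te_type`, `library`,
#'   `size_class`, `n_sirnas`, `mean_expr` (0 with `empty = TRUE` flag
#'   when no tag is assigned).
#' @export
te_type_abundance <- function(assignments, norm_mat, size = 24L) {
  sel <- if (is.na(size)) assignments else
    assignments[assignments$length == size, , drop = FALSE]
  types <- unique(assignments[, c("te_class", "te_type")])
  types <- types[order(types$te_class, types$te_type), , drop = FALSE]
  libs <- colnames(norm_mat)
  rows <- list()
  for (i in seq_len(nrow(types))) {
    seqs <- sel$sequence[sel$te_class == types$te_class[i] &
                           sel$te_type == types$te_type[i]]
    seqs <- intersect(seqs, rownames(norm_mat))
    for (l in libs) {
      n <- length(seqs)
      rows[[length(rows) + 1L]] <- data.frame(
        te_class = types$te_class[i], te_type = types$te_type[i],
        library = l, size_class = size,
        n_sirnas = n,
        mean_expr = if (n) mean(norm_mat[seqs, l]) else 0,
        empty = n == 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify the stage trend of TE siRNA abundance per genotype
#'
#' @param abundances from [te_type_abundance()].
#' @param design design table (`library_id`, `genotype`, `stage`).
#' @return data.frame with `genotype`, `te_class`, `te_type`, the three
#'   ordered stage means (`PMA`, `MA`, `SCP`) and `trend`
#'   (`decreasing` / `increasing` / `non-monotone`).
#' @export
stage_trend <- function(abundances, design) {
  validate_design(design)
  stages <- c("PMA", "MA", "SCP")
  types <- unique(abundances[, c("te_class", "te_type")])
  rows <- list()
  for (g in unique(design$genotype)) {
    for (i in seq_len(nrow(types))) {
      vals <- vapply(stages, function(st) {
        lib <- design$library_id[design$stage == st &
                                   design$genotype == g]
        v <- abundances$mean_expr[abundances$library == lib &
                                    abundances$te_class == types$te_class[i] &
                                    abundances$te_type == types$te_type[i]]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
      trend <- if (anyNA(vals)) {
        NA_character_
      } else if (all(diff(vals) < 0)) {
        "decreasing"
      } else if (all(diff(vals) > 0)) {
        "increasing"
      } else {
        "non-monotone"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, te_class = types$te_class[i],
        te_type = types$te_type[i],
        PMA = vals[1], MA = vals[2], SCP = vals[3], trend = trend,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
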