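# Hypergeometric term enrichment of target gene sets with BH adjustment.

#' Hypergeometric term enrichment of a study gene set
#'
#' For each term with at least one annotated population gene, the
#' upper-tail hypergeometric p-value P(X >= k) is computed for k study
#' hits out of n study genes, K annotated genes in a population of N;
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param study_genes character vector of study gene ids (subset of the
#'   population).
#' @param annotation_map data.frame with columns `gene` and `term`
#'   (optionally `term_name`).
#' @param population character vector of background genes; defaults to
#'   all genes in the annotation map.
#' @return data.frame with `term`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p`, `fdr`, sorted by p.
#' @export
hypergeom_enrich <- function(study_genes, annotation_map,
                             population = NULL) {
  stopifnot(all(c("gene", "term") %in% names(annotation_map)))
  if (is.null(population)) population <- unique(annotation_map$gene)
  study_genes <- unique(study_genes)
  if (!length(study_genes)) {
    warning("empty study set; no enrichment computed")
    return(data.frame(term = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  }
  extra <- setdiff(study_genes, population)
  if (length(extra)) {
    stop("study genes missing from the population: ",
         paste(head(extra, 3), collapse = ", "))
  }
  ann <- annotation_map[annotation_map$gene %in% population, , drop = FALSE]
  N <- length(population)
  n <- length(study_genes)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    genes <- unique(ann$gene[ann$term == tm])
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(genes, study_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tn <- if ("term_name" %in% names(ann)) {
      ann$term_name[ann$term == tm][1]
    } else {
      NA_character_
    }
    data.frame(term = tm, term_name = tn, k = k, n = n, K = K, N = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Per-direction, per-stage enrichment of DEM target genes
#'
#' For each stage and direction, the union of target genes of the
#' called miRNAs is tested against the annotation.
#'
#' @param dem_by_stage named list of DEM test tables (with `name`,
#'   `call`).
#' @param targets target table from [predict_targets()].
#' @param annotation_map gene/term map.
#' @param population optional background.
#' @return named list `"<stage>_<direction>"` of enrichment tables.
#' @export
enrich_by_direction <- function(dem_by_stage, targets, annotation_map,
                                population = NULL) {
  out <- list()
  for (st in names(dem_by_stage)) {
    for (dir in c("up", "down")) {
      mirnas <- dem_by_stage[[st]]$name[dem_by_stage[[st]]$call == dir]
      genes <- unique(targets$gene[targets$mirna %in% mirnas])
      genes <- intersect(genes,
                         if (is.null(population)) {
                           unique(annotation_map$gene)
                         } else {
                           population
                         })
      out[[paste(st, dir, sep = "_")]] <- if (length(genes)) {
        hypergeom_enrich(genes, annotation_map, population)
      } else {
        suppressWarnings(hypergeom_enrich(character(), annotation_map,
                                          population))
      }
    }
  }
  out
}
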