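# Differential miRNA expression between genotypes (per stage) and
# between adjacent stages (per genotype), with the accounting summaries
# (per-stage up/down, stage-specific partitions, Venn regions).

#' Differential-expression configuration
#'
#' @param rpm_floor expression floor: a miRNA is "expressed" in a
#'   library iff RPM >= this (complement of "less than 10 removed").
#' @param pseudo_count normalized-count substitution for zero raw
#'   counts when computing fold changes (default 0.01).
#' @param alpha significance level (strict `p < alpha`).
#' @param log2fc_threshold DEM threshold (strict `|log2fc| > 1`).
#' @param test_policy `"auto"` (Fisher when any expected cell < 5, else
#'   Pearson chi-square without continuity correction), `"chi2"` or
#'   `"fisher"`.
#' @param adjust `"none"` (default; matching the original procedure) or
#'   `"BH"`.
#' @return list of class `dem_config`.
#' @export
dem_config <- function(rpm_floor = 10, pseudo_count = 0.01, alpha = 0.05,
                       log2fc_threshold = 1,
                       test_policy = c("auto", "chi2", "fisher"),
                       adjust = c("none", "BH")) {
  test_policy <- match.arg(test_policy)
  adjust <- match.arg(adjust)
  stopifnot(rpm_floor > 0, pseudo_count > 0, alpha > 0, alpha < 1,
            log2fc_threshold > 0)
  structure(list(rpm_floor = rpm_floor, pseudo_count = pseudo_count,
                 alpha = alpha, log2fc_threshold = log2fc_threshold,
                 test_policy = test_policy, adjust = adjust),
            class = "dem_config")
}

#' Expression filter on an RPM matrix
#'
#' @param rpm_mat RPM matrix, miRNAs x libraries.
#' @param floor keep iff RPM >= floor (default 10).
#' @return logical matrix of the same shape ("expressed" flags).
#' @export
expression_filter <- function(rpm_mat, floor = 10) {
  rpm_mat >= floor
}

#' Test one miRNA between two single-library conditions
#'
#' The 2x2 table contrasts the miRNA's raw count against the rest of
#' each library.  Under the `auto` policy the Fisher exact test
#' (two-sided) is used when any expected cell is below 5, otherwise the
#' Pearson chi-square test without continuity correction.  The fold
#' change is computed from normalized counts, substituting
#' `pseudo_count` only for entries whose raw count is zero; condition B
#' relative to condition A.
#'
#' @param raw_a,raw_b raw counts in conditions A and B.
#' @param lib_a,lib_b library clean-read totals.
#' @param norm_a,norm_b normalized counts.
#' @param cfg [dem_config()].
#' @return one-row data.frame: `raw_a`, `raw_b`, `norm_a`, `norm_b`,
#'   `log2fc`, `p_value`, `test_used`, `call` (`up`/`down`/`ns`).
#' @export
test_dem <- function(raw_a, raw_b, lib_a, lib_b, norm_a, norm_b, cfg) {
  stopifnot(raw_a >= 0, raw_b >= 0, lib_a > raw_a, lib_b > raw_b)
  na <- if (raw_a == 0) cfg$pseudo_count else norm_a
  nb <- if (raw_b == 0) cfg$pseudo_count else norm_b
  log2fc <- log2(nb / na)
  if (raw_a == 0 && raw_b == 0) {
    return(data.frame(raw_a = raw_a, raw_b = raw_b, norm_a = norm_a,
                      norm_b = norm_b, log2fc = 0, p_value = 1,
                      test_used = "none", call = "ns",
                      stringsAsFactors = FALSE))
  }
  tab <- matrix(c(raw_a, lib_a - raw_a, raw_b, lib_b - raw_b),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(cfg$test_policy,
                       auto = any(expected < 5),
                       fisher = TRUE,
                       chi2 = FALSE)
  p <- if (use_fisher) {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  call <- if (p < cfg$alpha && log2fc > cfg$log2fc_threshold) {
    "up"
  } else if (p < cfg$alpha && log2fc < -cfg$log2fc_threshold) {
    "down"
  } else {
    "ns"
  }
  data.frame(raw_a = raw_a, raw_b = raw_b, norm_a = norm_a,
             norm_b = norm_b, log2fc = log2fc, p_value = p,
             test_used = if (use_fisher) "fisher" else "chi2",
             call = call, stringsAsFactors = FALSE)
}

dem_compare_libraries <- function(norm_mat, raw_mat, lib_totals, rpm_mat,
                                  lib_a, lib_b, cfg) {
  expr <- expression_filter(rpm_mat[, c(lib_a, lib_b), drop = FALSE],
                            cfg$rpm_floor)
  tested <- rownames(rpm_mat)[rowSums(expr) > 0]
  if (!length(tested)) {
    return(data.frame(name = character(), raw_a = numeric(),
                      raw_b = numeric(), norm_a = numeric(),
                      norm_b = numeric(), log2fc = numeric(),
                      p_value = numeric(), test_used = character(),
                      call = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(tested, function(m) {
    test_dem(raw_mat[m, lib_a], raw_mat[m, lib_b],
             lib_totals[[lib_a]], lib_totals[[lib_b]],
             norm_mat[m, lib_a], norm_mat[m, lib_b], cfg)
  })
  out <- do.call(rbind, rows)
  out <- cbind(name = tested, out, stringsAsFactors = FALSE)
  if (cfg$adjust == "BH") {
    padj <- p.adjust(out$p_value, "BH")
    out$p_adjust <- padj
    out$call <- ifelse(padj < cfg$alpha & out$log2fc > cfg$log2fc_threshold,
                       "up",
                ifelse(padj < cfg$alpha & out$log2fc < -cfg$log2fc_threshold,
                       "down", "ns"))
  }
  rownames(out) <- NULL
  out
}

#' Call DEM between genotypes at each stage
#'
#' For every stage present in the design, miRNAs expressed (at or above
#' the RPM floor) in at least one of the two libraries are tested with
#' the diploid library as reference: `up` means higher in the
#' autotetraploid.
#'
#' @param norm_mat normalized count matrix, miRNAs x libraries.
#' @param raw_mat raw count matrix (same shape).
#' @param lib_totals named clean-read totals per library.
#' @param design data.frame with `library_id`, `genotype` (`2x`/`4x`),
#'   `stage` (`PMA`/`MA`/`SCP`).
#' @param cfg [dem_config()].
#' @return named list (per stage) of test tables.
#' @export
call_dem_between_genotypes <- function(norm_mat, raw_mat, lib_totals,
                                       design, cfg = dem_config()) {
  validate_design(design)
  rpm_mat <- rpm(raw_mat, unlist(lib_totals))
  stages <- intersect(c("PMA", "MA", "SCP"), unique(design$stage))
  out <- list()
  for (st in stages) {
    lib2 <- design$library_id[design$stage == st & design$genotype == "2x"]
    lib4 <- design$library_id[design$stage == st & design$genotype == "4x"]
    if (length(lib2) != 1 || length(lib4) != 1) next
    out[[st]] <- dem_compare_libraries(norm_mat, raw_mat, lib_totals,
                                       rpm_mat, lib2, lib4, cfg)
  }
  out
}

#' Call DEM between adjacent stages within one genotype
#'
#' Comparisons are MA vs PMA and SCP vs MA, with the earlier stage as
#' reference.
#'
#' @inheritParams call_dem_between_genotypes
#' @param genotype `"2x"` or `"4x"`.
#' @return named list (`"MA_vs_PMA"`, `"SCP_vs_MA"`) of test tables.
#' @export
call_dem_between_stages <- function(norm_mat, raw_mat, lib_totals, design,
                                    genotype, cfg = dem_config()) {
  validate_design(design)
  rpm_mat <- rpm(raw_mat, unlist(lib_totals))
  pairs <- list(MA_vs_PMA = c("PMA", "MA"), SCP_vs_MA = c("MA", "SCP"))
  out <- list()
  for (nm in names(pairs)) {
    st <- pairs[[nm]]
    la <- design$library_id[design$stage == st[1] & design$genotype == genotype]
    lb <- design$library_id[design$stage == st[2] & design$genotype == genotype]
    if (length(la) != 1 || length(lb) != 1) next
    out[[nm]] <- dem_compare_libraries(norm_mat, raw_mat, lib_totals,
                                       rpm_mat, la, lb, cfg)
  }
  out
}

#' Stage-specific vs shared DEM partition between two genotypes
#'
#' For each stage comparison and direction, splits the called miRNAs
#' into those specific to each genotype and those common to both.
#'
#' @param dem_2x,dem_4x named lists of test tables from
#'   [call_dem_between_stages()] (same comparison names).
#' @return data.frame with `comparison`, `direction`, `specific_2x`,
#'   `specific_4x`, `common`.
#' @export
stage_specific_partition <- function(dem_2x, dem_4x) {
  comps <- intersect(names(dem_2x), names(dem_4x))
  rows <- list()
  for (cp in comps) {
    for (dir in c("up", "down")) {
      s2 <- dem_2x[[cp]]$name[dem_2x[[cp]]$call == dir]
      s4 <- dem_4x[[cp]]$name[dem_4x[[cp]]$call == dir]
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cp, direction = dir,
        specific_2x = length(setdiff(s2, s4)),
        specific_4x = length(setdiff(s4, s2)),
        common = length(intersect(s2, s4)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Exact 7-region Venn partition of three sets
#'
#' @param sets named list of exactly three character vectors.
#' @return named integer vector over region labels built from the set
#'   names (e.g. `"PMA"`, `"PMA&MA"`, `"PMA&MA&SCP"`); regions sum to
#'   the union size.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  nm <- names(sets)
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  labels <- c(nm,
              paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
              paste(nm, collapse = "&"))
  out <- setNames(integer(length(labels)), labels)
  tab <- table(pattern)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Round half-up to a fixed number of decimals
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values (ties away from zero).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize between-genotype DEM results across stages
#'
#' Produces the accounting used throughout the comparison: per-stage
#' up/down counts, the DEM union and its percentage of all detected
#' miRNAs, the Venn partition over stages, the stage-specific count
#' (exactly one stage) and its percentage of the DEM, and the
#' direction totals in two conventions: counting each miRNA once per
#' direction in which it is ever called (`up_total`/`down_total`,
#' double-counting direction-reversed miRNAs) and counting
#' direction-consistent miRNAs only (`up_consistent`/`down_consistent`)
#' alongside the number of reversed miRNAs.
#'
#' @param dem_by_stage named list (stages) of test tables with `name`
#'   and `call` columns.
#' @param n_total_detected total number of detected miRNAs (the
#'   percentage denominator).
#' @return list with the counts, percentages (2 decimals, half-up) and
#'   the Venn partition.
#' @export
summarize_dem <- function(dem_by_stage, n_total_detected) {
  stages <- names(dem_by_stage)
  up_sets <- lapply(dem_by_stage, function(d) d$name[d$call == "up"])
  down_sets <- lapply(dem_by_stage, function(d) d$name[d$call == "down"])
  dem_sets <- mapply(function(u, d) union(u, d), up_sets, down_sets,
                     SIMPLIFY = FALSE)
  per_stage <- data.frame(stage = stages,
                          n_up = vapply(up_sets, length, integer(1)),
                          n_down = vapply(down_sets, length, integer(1)),
                          stringsAsFactors = FALSE)
  per_stage$n_total <- per_stage$n_up + per_stage$n_down
  dem_union <- unique(unlist(dem_sets))
  venn <- if (length(stages) == 3) venn_partition(dem_sets) else NULL
  stage_specific <- if (!is.null(venn)) sum(venn[stages]) else NA_integer_
  up_any <- unique(unlist(up_sets))
  down_any <- unique(unlist(down_sets))
  reversed <- intersect(up_any, down_any)
  list(per_stage = per_stage,
       n_dem = length(dem_union),
       pct_of_detected = round_half_up(100 * length(dem_union) /
                                         n_total_detected),
       venn = venn,
       n_stage_specific = stage_specific,
       pct_stage_specific = if (!is.na(stage_specific)) {
         round_half_up(100 * stage_specific / length(dem_union))
       } else {
         NA_real_
       },
       up_total = length(up_any),
       down_total = length(down_any),
       up_consistent = length(setdiff(up_any, reversed)),
       down_consistent = length(setdiff(down_any, reversed)),
       n_reversed = length(reversed),
       reversed = sort(reversed))
}
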