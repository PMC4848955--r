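# miRNA identification: tag-to-precursor matching with <=1 internal
# mismatch and bounded end offsets, isomiR variant naming, five-category
# classification, and novel-hairpin candidate detection.

MIRNA_CATEGORIES <- c("KNOWN_RICE_MATURE",
                      "NOVEL_ARM_OF_RICE_PRECURSOR",
                      "KNOWN_OTHER_SPECIES_GENOME_MAPPED",
                      "NOVEL_ARM_OF_OTHER_SPECIES",
                      "NOVEL_PC_CANDIDATE")

#' Read a precursor hairpin set
#'
#' The FASTA holds precursor sequences; the tab-separated sidecar holds
#' mature-arm coordinates with columns `precursor`, `arm` (`5p`/`3p`),
#' `start`, `end` (1-based inclusive, converted to 0-based half-open at
#' ingest) and optionally `mature_name`.
#'
#' @param fasta_path precursor FASTA.
#' @param sidecar_path mature-coordinate TSV.
#' @param species species prefix recorded for the set (e.g. `"osa"`);
#'   if `NULL`, taken from each precursor name's prefix.
#' @return data.frame with columns `name`, `sequence`, `species`,
#'   `m5_start`, `m5_end`, `m5_name`, `m3_start`, `m3_end`, `m3_name`
#'   (NA when an arm is not annotated).
#' @export
read_precursors <- function(fasta_path, sidecar_path, species = NULL) {
  fa <- read_fasta(fasta_path)
  sc <- read.delim(sidecar_path, stringsAsFactors = FALSE)
  stopifnot(all(c("precursor", "arm", "start", "end") %in% names(sc)))
  if (!"mature_name" %in% names(sc)) sc$mature_name <- NA_character_
  out <- data.frame(name = fa$id, sequence = fa$sequence,
                    species = if (is.null(species)) {
                      sub("-.*$", "", fa$id)
                    } else {
                      species
                    },
                    m5_start = NA_integer_, m5_end = NA_integer_,
                    m5_name = NA_character_,
                    m3_start = NA_integer_, m3_end = NA_integer_,
                    m3_name = NA_character_,
                    stringsAsFactors = FALSE)
  default_mature <- function(prec, arm) {
    paste0(sub("MIR", "miR", prec, fixed = TRUE), "-", arm)
  }
  for (i in seq_len(nrow(sc))) {
    j <- match(sc$precursor[i], out$name)
    if (is.na(j)) stop("sidecar references unknown precursor: ", sc$precursor[i])
    s0 <- sc$start[i] - 1L
    e0 <- sc$end[i]
    if (s0 < 0L || e0 > nchar(out$sequence[j]) || s0 >= e0) {
      stop("mature interval outside precursor ", sc$precursor[i])
    }
    nm <- sc$mature_name[i]
    if (is.na(nm) || !nzchar(nm)) nm <- default_mature(sc$precursor[i], sc$arm[i])
    if (sc$arm[i] == "5p") {
      out$m5_start[j] <- s0; out$m5_end[j] <- e0; out$m5_name[j] <- nm
    } else if (sc$arm[i] == "3p") {
      out$m3_start[j] <- s0; out$m3_end[j] <- e0; out$m3_name[j] <- nm
    } else {
      stop("sidecar arm must be '5p' or '3p', got '", sc$arm[i], "'")
    }
  }
  both <- !is.na(out$m5_start) & !is.na(out$m3_start)
  if (any(both & out$m5_start >= out$m3_start)) {
    stop("5p mature must start before 3p mature")
  }
  out
}

#' Align a tag to a precursor with at most one internal mismatch
#'
#' Enumerates every ungapped sense-strand placement of the tag on the
#' precursor with at most `max_mismatch` internal mismatches (the first
#' and last tag base must match exactly), then assigns each placement to
#' an annotated mature arm if both end offsets are within
#' `max_end_offset`; otherwise to `opposite_arm` (placement on the
#' non-annotated half of a hairpin with a single annotated mature) or
#' `other`.
#'
#' @param tag tag sequence.
#' @param precursor one row of a [read_precursors()] table (or a list
#'   with the same fields).
#' @param max_mismatch maximal internal mismatches (default 1).
#' @param max_end_offset maximal |5'| and |3'| offset against the
#'   mature arm (default 3 nt).
#' @return data.frame of placements: `position` (0-based on precursor),
#'   `n_mismatch`, `mm_pos` (1-based on tag), `mm_ref`, `mm_obs`,
#'   `arm_hit`, `left_offset`, `right_offset`.
#' @export
match_tag_to_precursor <- function(tag, precursor, max_mismatch = 1L,
                                   max_end_offset = 3L) {
  L <- nchar(tag)
  pseq <- precursor$sequence
  n <- nchar(pseq)
  empty <- data.frame(position = integer(), n_mismatch = integer(),
                      mm_pos = integer(), mm_ref = character(),
                      mm_obs = character(), arm_hit = character(),
                      left_offset = integer(), right_offset = integer(),
                      stringsAsFactors = FALSE)
  if (L > n) return(empty)
  tag_i <- utf8ToInt(tag)
  prec_i <- utf8ToInt(pseq)
  W <- n - L + 1L
  win <- matrix(prec_i[outer(seq_len(L) - 1L, seq_len(W), "+")], nrow = L)
  diffs <- win != tag_i
  nmm <- colSums(diffs)
  ok <- which(nmm <= max_mismatch)
  if (max_mismatch >= 1L) {
    # a single mismatch must be strictly internal on the tag
    one <- ok[nmm[ok] == 1L]
    if (length(one)) {
      mpos <- apply(diffs[, one, drop = FALSE], 2, which)
      keep1 <- mpos > 1L & mpos < L
      ok <- c(ok[nmm[ok] == 0L], one[keep1])
    }
  }
  if (!length(ok)) return(empty)
  res <- lapply(sort(ok), function(w) {
    p <- w - 1L
    k <- nmm[w]
    if (k == 1L) {
      mp <- which(diffs[, w])
      mref <- intToUtf8(win[mp, w])
      mobs <- intToUtf8(tag_i[mp])
    } else {
      mp <- NA_integer_; mref <- NA_character_; mobs <- NA_character_
    }
    arm <- "other"
    lo <- NA_integer_; ro <- NA_integer_
    cand <- list()
    if (!is.na(precursor$m5_start)) {
      cand$mature_5p <- c(precursor$m5_start - p,
                          (p + L) - precursor$m5_end)
    }
    if (!is.na(precursor$m3_start)) {
      cand$mature_3p <- c(precursor$m3_start - p,
                          (p + L) - precursor$m3_end)
    }
    fits <- vapply(cand, function(o) all(abs(o) <= max_end_offset),
                   logical(1))
    if (any(fits)) {
      sums <- vapply(cand, function(o) sum(abs(o)), numeric(1))
      sums[!fits] <- Inf
      pick <- names(which.min(sums))
      arm <- pick
      lo <- cand[[pick]][1]
      ro <- cand[[pick]][2]
    } else if (length(cand) == 1L) {
      # single annotated mature: a placement centred on the other half
      # of the hairpin is an opposite-arm hit
      centre <- p + L / 2
      if (names(cand) == "mature_5p" &&
          centre > precursor$m5_end + (n - precursor$m5_end) / 4) {
        arm <- "opposite_arm"
      } else if (names(cand) == "mature_3p" &&
                 centre < precursor$m3_start - precursor$m3_start / 4) {
        arm <- "opposite_arm"
      }
    }
    data.frame(position = p, n_mismatch = as.integer(k), mm_pos = mp,
               mm_ref = mref, mm_obs = mobs, arm_hit = arm,
               left_offset = lo, right_offset = ro,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Derive the isomiR variant name for a mature-arm placement
#'
#' End offsets become `_L±n`/`_R±n` tokens and a single internal
#' mismatch becomes a `_1ss<pos><ref><obs>` token (1-based position on
#' the observed tag); an exact full-length match keeps the bare mature
#' name.
#'
#' @param match one row from [match_tag_to_precursor()] with `arm_hit`
#'   `mature_5p` or `mature_3p`.
#' @param base_name the annotated mature name for that arm.
#' @return `mirna_name` object.
#' @export
derive_variant_name <- function(match, base_name) {
  stopifnot(match$arm_hit %in% c("mature_5p", "mature_3p"))
  subs <- NULL
  if (!is.na(match$mm_pos)) {
    subs <- data.frame(pos = match$mm_pos, ref = match$mm_ref,
                       obs = match$mm_obs, stringsAsFactors = FALSE)
  }
  mirna_name(base_name, match$left_offset, match$right_offset, subs)
}

arm_suffix_name <- function(precursor_name, tag_arm) {
  paste0(precursor_name, if (tag_arm == "5p") "-p5" else "-p3")
}

best_match <- function(matches) {
  # tie-break: fewer mismatches, then smaller |L|+|R| offset, then
  # lexicographically smallest precursor name
  osum <- ifelse(is.na(matches$left_offset), Inf,
                 abs(matches$left_offset) + abs(matches$right_offset))
  ord <- order(matches$n_mismatch, osum, matches$precursor_name)
  matches[ord[1], , drop = FALSE]
}

match_against_set <- function(tag, precursors, max_mismatch, max_end_offset) {
  out <- list()
  for (i in seq_len(nrow(precursors))) {
    m <- match_tag_to_precursor(tag, precursors[i, ], max_mismatch,
                                max_end_offset)
    if (nrow(m)) {
      m$precursor_name <- precursors$name[i]
      m$precursor_row <- i
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Classify one tag against precursor catalogs
#'
#' Applies the five identification rules in fixed order: (1) rice
#' mature arm; (2) opposite arm of a rice precursor; (3) mature arm of
#' an other-species precursor whose hairpin maps to the rice genome;
#' (4) opposite arm of such a precursor; (5) unmatched (candidate for
#' [detect_novel_hairpin()], returned as `NULL` here).
#'
#' @param tag tag sequence.
#' @param rice_precursors,other_precursors [read_precursors()] tables;
#'   `other_precursors` should already be restricted to genome-mapped
#'   hairpins (see [build_catalog()]).
#' @param max_mismatch,max_end_offset alignment tolerances.
#' @return list with `name` (string), `category`, `source`
#'   (precursor name), or `NULL` when unmatched.
#' @export
classify_tag <- function(tag, rice_precursors, other_precursors,
                         max_mismatch = 1L, max_end_offset = 3L) {
  for (set in list(list(prec = rice_precursors,
                        mature_cat = "KNOWN_RICE_MATURE",
                        opp_cat = "NOVEL_ARM_OF_RICE_PRECURSOR"),
                   list(prec = other_precursors,
                        mature_cat = "KNOWN_OTHER_SPECIES_GENOME_MAPPED",
                        opp_cat = "NOVEL_ARM_OF_OTHER_SPECIES"))) {
    if (is.null(set$prec) || !nrow(set$prec)) next
    mm <- match_against_set(tag, set$prec, max_mismatch, max_end_offset)
    if (is.null(mm)) next
    mature <- mm[mm$arm_hit %in% c("mature_5p", "mature_3p"), , drop = FALSE]
    if (nrow(mature)) {
      b <- best_match(mature)
      prow <- set$prec[b$precursor_row, ]
      base <- if (b$arm_hit == "mature_5p") prow$m5_name else prow$m3_name
      return(list(name = format_mirna_name(derive_variant_name(b, base)),
                  category = set$mature_cat, source = b$precursor_name))
    }
    opp <- mm[mm$arm_hit == "opposite_arm", , drop = FALSE]
    if (nrow(opp)) {
      b <- best_match(opp)
      prow <- set$prec[b$precursor_row, ]
      tag_arm <- if (!is.na(prow$m5_start)) "3p" else "5p"
      return(list(name = arm_suffix_name(b$precursor_name, tag_arm),
                  category = set$opp_cat, source = b$precursor_name))
    }
  }
  NULL
}

# ---- hairpin heuristic --------------------------------------------------

#' Maximum single-loop base pairing of a sequence
#'
#' Nussinov-style dynamic program over Watson-Crick and G:U pairs,
#' restricted to stem-loop topology: pairs are mutually nested with a
#' single unpaired loop of size between `min_loop` and `max_loop` at
#' the innermost pair.  Arbitrary interior bulges are allowed.
#'
#' @param seq nucleotide string (DNA alphabet; T plays the role of U).
#' @param max_loop maximal loop size (default 60 nt).
#' @param min_loop minimal loop size (default 3 nt).
#' @return maximal number of stem pairs (0 when no valid hairpin fits).
#' @export
hairpin_max_pairing <- function(seq, max_loop = 60L, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < min_loop + 2L) return(0L)
  pairable <- matrix(FALSE, 5, 5,
                     dimnames = list(c("A", "C", "G", "T", "N"),
                                     c("A", "C", "G", "T", "N")))
  pairable["A", "T"] <- pairable["T", "A"] <- TRUE
  pairable["G", "C"] <- pairable["C", "G"] <- TRUE
  pairable["G", "T"] <- pairable["T", "G"] <- TRUE
  cp <- pairable[s, s, drop = FALSE]
  NEG <- -1e9
  P <- matrix(NEG, n, n)
  for (d in seq(min_loop + 1L, n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    ij <- cbind(i, j)
    inner <- if (d >= 2L) P[cbind(i + 1L, j - 1L)] else rep(NEG, length(i))
    innermost_ok <- (d - 1L) >= min_loop && (d - 1L) <= max_loop
    stack <- ifelse(inner >= 1, 1 + inner,
                    if (innermost_ok) 1 else NEG)
    pairval <- ifelse(cp[ij], stack, NEG)
    P[ij] <- pmax(P[cbind(i + 1L, j)], P[cbind(i, j - 1L)], pairval)
  }
  best <- P[1, n]
  if (best < 0) 0L else as.integer(best)
}

#' Best ungapped antiparallel stem between a tag and a flanking window
#'
#' Slides the tag along the reverse complement sense of the window and
#' counts Watson-Crick/G:U pairings at each offset, keeping partner
#' segments that are disjoint from the tag with a loop gap in
#' `[min_loop, max_loop]`.
#'
#' @param window window sequence.
#' @param tag_start,tag_end 1-based inclusive tag interval in `window`.
#' @param max_loop,min_loop allowed gap between tag and partner.
#' @return list with `pairs` (best pairing count; 0 when no admissible
#'   partner) and `arm` (`"5p"` if the partner lies 3' of the tag,
#'   `"3p"` if 5' of it, `NA` when none).
#' @export
tag_stem_pairing <- function(window, tag_start, tag_end,
                             max_loop = 60L, min_loop = 3L) {
  n <- nchar(window)
  L <- tag_end - tag_start + 1L
  s <- utf8ToInt(window)
  tag <- s[tag_start:tag_end]
  # pairing partner of the tag read antiparallel: tag base i pairs
  # window base (p + L - i) for partner segment starting at p
  comp <- rep(NA_integer_, 128)
  comp[utf8ToInt("A")] <- utf8ToInt("T")
  comp[utf8ToInt("T")] <- utf8ToInt("A")
  comp[utf8ToInt("G")] <- utf8ToInt("C")
  comp[utf8ToInt("C")] <- utf8ToInt("G")
  wob <- function(a, b) {
    (a == utf8ToInt("G") & b == utf8ToInt("T")) |
      (a == utf8ToInt("T") & b == utf8ToInt("G"))
  }
  best <- 0L
  arm <- NA_character_
  for (p in seq_len(n - L + 1L)) {
    seg <- s[p:(p + L - 1L)]
    gap5 <- tag_start - (p + L)   # partner entirely 5' of tag
    gap3 <- p - tag_end - 1L      # partner entirely 3' of tag
    if (gap5 >= min_loop && gap5 <= max_loop) {
      this_arm <- "3p"
    } else if (gap3 >= min_loop && gap3 <= max_loop) {
      this_arm <- "5p"
    } else {
      next
    }
    seg_rev <- rev(seg)
    np <- sum(comp[tag] == seg_rev | wob(tag, seg_rev), na.rm = TRUE)
    if (np > best) {
      best <- np
      arm <- this_arm
    }
  }
  list(pairs = as.integer(best), arm = arm)
}

#' Locate exact genomic matches of a tag on either strand
#'
#' @param tag tag sequence.
#' @param genome data.frame with `id`, `sequence` (from [read_fasta()]).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open on the
#'   forward strand), `strand`.
#' @export
genome_hits <- function(tag, genome) {
  out <- list()
  rc <- revcomp(tag)
  L <- nchar(tag)
  for (i in seq_len(nrow(genome))) {
    for (str in c("+", "-")) {
      q <- if (str == "+") tag else rc
      loc <- stringi::stri_locate_all_fixed(genome$sequence[i], q)[[1]]
      if (!is.na(loc[1, 1])) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = genome$id[i], start = loc[, 1] - 1L,
          end = loc[, 1] - 1L + L, strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect a novel miRNA hairpin around a genome-mapped tag
#'
#' For every exact genomic locus of the tag the flanked window is
#' checked with the stem-loop criteria: the window's maximal single-loop
#' pairing ([hairpin_max_pairing()]) must reach `min_pairs`, and the tag
#' itself must form an ungapped antiparallel stem of at least
#' `min_pairs` pairs with a partner segment across a loop of admissible
#' size ([tag_stem_pairing()]), which also places the tag wholly on one
#' arm.
#'
#' @param tag tag sequence.
#' @param genome genome sequence table.
#' @param flank flank width around the tag (default 150 nt).
#' @param min_pairs minimal stem pairs (default 18).
#' @param max_loop maximal loop size (default 60 nt).
#' @param min_pair_frac minimal fraction of tag bases paired in the
#'   stem (default 0.7); for a 24-nt tag this coincides with the
#'   absolute threshold, for longer tags it keeps the mature candidate
#'   predominantly paired.
#' @return data.frame of accepted loci with `chrom`, `start`, `end`,
#'   `strand`, `arm`, `stem_pairs`; zero rows when rejected everywhere.
#' @export
detect_novel_hairpin <- function(tag, genome, flank = 150L,
                                 min_pairs = 18L, max_loop = 60L,
                                 min_pair_frac = 0.7) {
  hits <- genome_hits(tag, genome)
  res <- list()
  for (i in seq_len(nrow(hits))) {
    chrom_seq <- genome$sequence[match(hits$chrom[i], genome$id)]
    n <- nchar(chrom_seq)
    ws <- max(1L, hits$start[i] + 1L - flank)
    we <- min(n, hits$end[i] + flank)
    window <- substr(chrom_seq, ws, we)
    ts <- hits$start[i] + 1L - ws + 1L
    te <- hits$end[i] - ws + 1L
    if (hits$strand[i] == "-") {
      window <- revcomp(window)
      w <- nchar(window)
      new_ts <- w - te + 1L
      te <- w - ts + 1L
      ts <- new_ts
    }
    if (hairpin_max_pairing(window, max_loop) < min_pairs) next
    stem <- tag_stem_pairing(window, ts, te, max_loop)
    need <- max(min_pairs, ceiling(min_pair_frac * nchar(tag)))
    if (stem$pairs < need) next
    res[[length(res) + 1L]] <- data.frame(
      chrom = hits$chrom[i], start = hits$start[i], end = hits$end[i],
      strand = hits$strand[i], arm = stem$arm,
      stem_pairs = stem$pairs, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      arm = character(), stem_pairs = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

# ---- catalog construction ----------------------------------------------

#' Build the miRNA catalog from a unique-tag table
#'
#' Classifies every tag in the miRNA length window against the rice and
#' other-species precursor sets (the latter restricted to hairpins whose
#' sequence maps exactly to the genome), then scans remaining
#' sufficiently-expressed tags for novel genomic hairpins (`PC-`
#' candidates).  Records with the same derived name are aggregated by
#' summing counts.
#'
#' @param tags unique-tag table (from [preprocess_libraries()]).
#' @param rice_precursors,other_precursors [read_precursors()] tables.
#' @param genome genome sequence table.
#' @param mirna_len length window for identification (default 18-25 nt).
#' @param max_mismatch,max_end_offset alignment tolerances.
#' @param flank,min_pairs,max_loop hairpin criteria.
#' @param min_count_novel minimal total raw count for a tag to enter
#'   novel-hairpin detection (default 10).
#' @return list with `catalog` (data.frame: `name`, `sequence`,
#'   `category`, `source`, one count column per library) and
#'   `assignments` (per-tag name/category map).
#' @export
build_catalog <- function(tags, rice_precursors, other_precursors, genome,
                          mirna_len = c(18L, 25L),
                          max_mismatch = 1L, max_end_offset = 3L,
                          flank = 150L, min_pairs = 18L, max_loop = 60L,
                          min_count_novel = 10L) {
  libs <- setdiff(names(tags), "sequence")
  if (!is.null(other_precursors) && nrow(other_precursors)) {
    hay <- paste(genome$sequence, collapse = "#")
    mapped <- stringi::stri_detect_fixed(hay, other_precursors$sequence)
    other_precursors <- other_precursors[mapped, , drop = FALSE]
  }
  n <- nrow(tags)
  name <- rep(NA_character_, n)
  category <- rep(NA_character_, n)
  source <- rep(NA_character_, n)
  lens <- nchar(tags$sequence)
  in_window <- lens >= mirna_len[1] & lens <= mirna_len[2]
  totals <- if (length(libs)) rowSums(tags[, libs, drop = FALSE]) else rep(0, n)
  # exact prescreens: a placement with <= 1 mismatch implies one tag
  # half occurs verbatim in some precursor, and the novel-hairpin path
  # requires an exact genomic hit on either strand
  prec_hay <- paste(c(rice_precursors$sequence,
                      if (!is.null(other_precursors)) {
                        other_precursors$sequence
                      }), collapse = "#")
  half <- nchar(tags$sequence) %/% 2L
  could_match <- stringi::stri_detect_fixed(
    prec_hay, substr(tags$sequence, 1L, half)) |
    stringi::stri_detect_fixed(
      prec_hay, substr(tags$sequence, half + 1L, nchar(tags$sequence)))
  genome_hay <- paste(genome$sequence, collapse = "#")
  on_genome <- stringi::stri_detect_fixed(genome_hay, tags$sequence) |
    stringi::stri_detect_fixed(genome_hay, revcomp(tags$sequence))
  pc_pool <- list()
  for (i in which(in_window & (could_match | on_genome))) {
    cl <- if (could_match[i]) {
      classify_tag(tags$sequence[i], rice_precursors, other_precursors,
                   max_mismatch, max_end_offset)
    } else {
      NULL
    }
    if (!is.null(cl)) {
      name[i] <- cl$name
      category[i] <- cl$category
      source[i] <- cl$source
    } else if (on_genome[i] && totals[i] >= min_count_novel) {
      hp <- detect_novel_hairpin(tags$sequence[i], genome, flank,
                                 min_pairs, max_loop)
      if (nrow(hp)) {
        pc_pool[[length(pc_pool) + 1L]] <-
          data.frame(idx = i, arm = hp$arm[1],
                     chrom = hp$chrom[1], start = hp$start[1],
                     n_loci = nrow(hp), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pc_pool)) {
    pc <- do.call(rbind, pc_pool)
    # deterministic serials: decreasing abundance, then sequence
    ord <- order(-totals[pc$idx], tags$sequence[pc$idx])
    pc <- pc[ord, , drop = FALSE]
    for (k in seq_len(nrow(pc))) {
      i <- pc$idx[k]
      nm <- mirna_name(sprintf("PC-%s-%d", pc$arm[k], k),
                       candidate_id = as.character(totals[i]))
      name[i] <- format_mirna_name(nm)
      category[i] <- "NOVEL_PC_CANDIDATE"
      source[i] <- sprintf("%s:%d", pc$chrom[k], pc$start[k])
    }
  }
  assigned <- !is.na(name)
  assignments <- data.frame(sequence = tags$sequence, name = name,
                            category = category, source = source,
                            stringsAsFactors = FALSE)
  if (!any(assigned)) {
    cat_df <- data.frame(name = character(), sequence = character(),
                         category = character(), source = character(),
                         stringsAsFactors = FALSE)
    for (l in libs) cat_df[[l]] <- numeric()
    return(list(catalog = cat_df, assignments = assignments))
  }
  sub <- cbind(assignments[assigned, , drop = FALSE],
               tags[assigned, libs, drop = FALSE])
  dt <- data.table::as.data.table(sub)
  agg <- dt[, c(list(sequence = sequence[which.max(rowSums(as.matrix(.SD)))],
                     category = category[1], source = source[1]),
                lapply(.SD, sum)),
            by = "name", .SDcols = libs]
  agg <- agg[order(name)]
  list(catalog = as.data.frame(agg[, c("name", "sequence", "category",
                                       "source", libs), with = FALSE]),
       assignments = assignments)
}
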