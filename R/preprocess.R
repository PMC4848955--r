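# Raw-read cleaning: adapter trimming, quality / length / complexity
# filters, collapsing to unique tags and ncRNA removal.

#' Trim the 3' sequencing adapter from reads
#'
#' The adapter is located either as a full internal occurrence or as the
#' longest prefix of the adapter matching the read suffix with at least
#' `min_overlap` bases; the read is truncated before the match.  Reads
#' that are pure adapter (empty insert) are flagged as adapter dimers.
#'
#' @param reads character vector of read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length at the read 3' end
#'   (default 6).
#' @return list with `sequence` (trimmed reads), `trimmed` (logical,
#'   adapter found) and `dimer` (logical, empty insert).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  stopifnot(nzchar(adapter))
  adapter <- normalize_seq(adapter)
  n <- length(reads)
  cut_at <- rep(NA_integer_, n)
  # full adapter occurring anywhere in the read
  loc <- stringi::stri_locate_first_fixed(reads, adapter)[, 1]
  cut_at[!is.na(loc)] <- loc[!is.na(loc)]
  # adapter prefix at the read suffix (adapter runs off the read end);
  # ascending k so the longest (earliest cut) wins
  kmax <- min(nchar(adapter), max(nchar(reads), 0L))
  if (kmax >= min_overlap) {
    for (k in seq(min_overlap, kmax)) {
      pre <- substr(adapter, 1L, k)
      hit <- stringi::stri_endswith_fixed(reads, pre)
      pos <- nchar(reads) - k + 1L
      take <- hit & (is.na(cut_at) | pos < cut_at)
      cut_at[take] <- pos[take]
    }
  }
  out <- reads
  found <- !is.na(cut_at)
  out[found] <- substr(reads[found], 1L, cut_at[found] - 1L)
  list(sequence = out, trimmed = found, dimer = found & cut_at == 1L)
}

#' Mean-quality and N filter
#'
#' @param reads character vector of read sequences.
#' @param quals Phred+33 quality strings (same lengths).
#' @param min_mean_q keep iff mean Phred >= this (default 20) and the
#'   read contains no N.
#' @return logical keep vector.
#' @export
quality_filter <- function(reads, quals, min_mean_q = 20) {
  stopifnot(length(reads) == length(quals),
            all(nchar(reads) == nchar(quals)))
  if (!length(reads)) return(logical())
  widths <- nchar(quals)
  ints <- as.integer(charToRaw(paste(quals, collapse = ""))) - 33L
  grp <- rep.int(seq_along(quals), widths)
  means <- as.vector(rowsum(ints, grp)) / widths
  has_n <- stringi::stri_detect_fixed(reads, "N")
  means >= min_mean_q & !has_n
}

#' Length-window filter
#'
#' @param seqs character vector.
#' @param min_len,max_len inclusive window (defaults 18 and 30 nt).
#' @return logical keep vector.
#' @export
length_filter <- function(seqs, min_len = 18L, max_len = 30L) {
  nchar(seqs) >= min_len & nchar(seqs) <= max_len
}

#' Low-complexity filter
#'
#' Rejects tags in which a single base exceeds 80% of the length, and
#' tags that are full-length mono- or dinucleotide repeats.
#'
#' @param seqs character vector.
#' @param max_mono_frac maximal allowed single-base fraction (default 0.8).
#' @return logical keep vector (`FALSE` = low complexity).
#' @export
low_complexity_filter <- function(seqs, max_mono_frac = 0.8) {
  if (!length(seqs)) return(logical())
  w <- nchar(seqs)
  mono <- rep(FALSE, length(seqs))
  for (b in c("A", "C", "G", "T")) {
    mono <- mono | stringi::stri_count_fixed(seqs, b) / w > max_mono_frac
  }
  di_motif <- substr(seqs, 1L, 2L)
  di_full <- substr(strrep(di_motif, ceiling(w / 2)), 1L, w)
  di <- nchar(seqs) >= 2L & seqs == di_full
  !(mono | di)
}

#' Collapse per-library clean reads to unique tags with counts
#'
#' @param reads_by_lib named list: library id -> character vector of
#'   clean read sequences.
#' @return data.frame with column `sequence` plus one integer count
#'   column per library (zero when absent), rows sorted by sequence.
#' @export
collapse_unique <- function(reads_by_lib) {
  stopifnot(is.list(reads_by_lib), !is.null(names(reads_by_lib)))
  libs <- names(reads_by_lib)
  dt <- data.table::rbindlist(lapply(libs, function(l) {
    data.table::data.table(sequence = reads_by_lib[[l]], lib = l)
  }))
  if (!nrow(dt)) {
    out <- data.frame(sequence = character(), stringsAsFactors = FALSE)
    for (l in libs) out[[l]] <- integer()
    return(out)
  }
  counts <- dt[, .N, by = c("sequence", "lib")]
  wide <- data.table::dcast(counts, sequence ~ lib, value.var = "N",
                            fill = 0L)
  for (l in setdiff(libs, names(wide))) wide[[l]] <- 0L
  wide <- wide[order(sequence), c("sequence", libs), with = FALSE]
  as.data.frame(wide)
}

#' Remove tags matching common ncRNA families
#'
#' A tag is removed iff it occurs as an exact substring of any
#' contaminant sequence on either strand.
#'
#' @param tags tag table from [collapse_unique()].
#' @param contaminant_db data.frame with `id`, `sequence` (e.g. from
#'   [read_fasta()]) of rRNA/tRNA/snRNA/snoRNA sequences.
#' @return list with `kept` and `removed` tag tables.
#' @export
filter_ncrna <- function(tags, contaminant_db) {
  if (is.null(contaminant_db) || !nrow(contaminant_db)) {
    warning("empty contaminant database; no tags removed")
    return(list(kept = tags, removed = tags[0, , drop = FALSE]))
  }
  hay <- paste(c(contaminant_db$sequence, revcomp(contaminant_db$sequence)),
               collapse = "#")
  hit <- stringi::stri_detect_fixed(hay, tags$sequence)
  list(kept = tags[!hit, , drop = FALSE],
       removed = tags[hit, , drop = FALSE])
}

#' Clean one library of raw reads
#'
#' Applies the fixed pipeline order: adapter trimming, quality filter,
#' length window, low-complexity filter.  Collapsing and ncRNA removal
#' are done jointly across libraries by [preprocess_libraries()].
#'
#' @param reads,quals raw read and quality strings.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len tag length window.
#' @param min_mean_q quality threshold.
#' @param min_overlap adapter overlap.
#' @return list with `clean` (character vector) and `stats` (named
#'   counters).
#' @export
clean_reads <- function(reads, quals, adapter,
                        min_len = 18L, max_len = 30L,
                        min_mean_q = 20, min_overlap = 6L) {
  n_raw <- length(reads)
  tr <- trim_adapter(reads, adapter, min_overlap)
  keep <- !tr$dimer
  n_dimer <- sum(tr$dimer)
  seqs <- tr$sequence[keep]
  quals <- substr(quals[keep], 1L, nchar(seqs))
  q_ok <- quality_filter(seqs, quals, min_mean_q)
  n_lowq <- sum(!q_ok)
  seqs <- seqs[q_ok]
  too_short <- nchar(seqs) < min_len
  too_long <- nchar(seqs) > max_len
  n_short <- sum(too_short)
  n_long <- sum(too_long)
  seqs <- seqs[!too_short & !too_long]
  cx_ok <- low_complexity_filter(seqs)
  n_junk <- sum(!cx_ok)
  seqs <- seqs[cx_ok]
  list(clean = seqs,
       stats = c(raw_reads = n_raw,
                 adapter_removed = n_dimer,
                 low_quality = n_lowq,
                 too_short = n_short,
                 too_long = n_long,
                 junk_low_complexity = n_junk,
                 clean_reads = length(seqs)))
}

#' Preprocess a set of libraries into a unique-tag table
#'
#' @param fastq_paths named character vector: library id -> FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param contaminant_db ncRNA sequence table (or `NULL` to skip).
#' @param min_len,max_len,min_mean_q,min_overlap see [clean_reads()].
#' @return list with `tags` (kept unique-tag table), `removed_ncrna`
#'   (tag table) and `stats` (data.frame, one row per library; the
#'   `ncrna_removed` column counts reads, `unique_tags` counts kept
#'   tags present in that library).
#' @export
preprocess_libraries <- function(fastq_paths, adapter, contaminant_db = NULL,
                                 min_len = 18L, max_len = 30L,
                                 min_mean_q = 20, min_overlap = 6L) {
  libs <- names(fastq_paths)
  stopifnot(!is.null(libs), all(nzchar(libs)))
  clean <- list()
  stats <- list()
  for (l in libs) {
    fq <- read_fastq(fastq_paths[[l]])
    cl <- clean_reads(fq$sequence, fq$quality, adapter,
                      min_len, max_len, min_mean_q, min_overlap)
    clean[[l]] <- cl$clean
    stats[[l]] <- cl$stats
  }
  tags <- collapse_unique(clean)
  if (!is.null(contaminant_db)) {
    fl <- filter_ncrna(tags, contaminant_db)
  } else {
    fl <- list(kept = tags, removed = tags[0, , drop = FALSE])
  }
  st <- as.data.frame(do.call(rbind, stats))
  st$library <- libs
  st$ncrna_removed <- vapply(libs, function(l) {
    if (nrow(fl$removed)) sum(fl$removed[[l]]) else 0L
  }, numeric(1))
  st$clean_reads <- st$clean_reads - st$ncrna_removed
  st$unique_tags <- vapply(libs, function(l) {
    sum(fl$kept[[l]] > 0L)
  }, numeric(1))
  rownames(st) <- NULL
  list(tags = fl$kept, removed_ncrna = fl$removed,
       stats = st[, c("library", "raw_reads", "adapter_removed",
                      "low_quality", "too_short", "too_long",
                      "junk_low_complexity", "ncrna_removed",
                      "clean_reads", "unique_tags")])
}
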