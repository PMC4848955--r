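#' @import data.table
#' @importFrom stats median lm coef p.adjust pchisq phyper fisher.test
#'   chisq.test rmultinom rpois setNames complete.cases
#' @importFrom utils write.table read.delim head tail
NULL

# ---- sequence utilities ------------------------------------------------

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Upper-cases and converts U to T so that RNA (miRBase-style) and DNA
#' (genome/transcript) inputs share one internal alphabet.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# ---- FASTA / FASTQ -----------------------------------------------------

#' Read a FASTA file into a sequence table
#'
#' Multi-line records are concatenated and U is normalized to T.
#' Duplicated ids are kept with a warning.
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)
  seqs <- normalize_seq(as.character(set))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1], " in ", path)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1]],
         "' in ", path)
  }
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in record '", ids[which(bad)[1]],
         "' in ", path)
  }
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param ids,seqs character vectors of equal length.
#' @param path output file.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at record ", n %/% 4L + 1L, " in ", path)
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  plus <- lines[idx + 2L]
  if (any(substr(heads, 1, 1) != "@")) {
    stop("malformed FASTQ header at record ",
         which(substr(heads, 1, 1) != "@")[1], " in ", path)
  }
  if (any(substr(plus, 1, 1) != "+")) {
    stop("malformed FASTQ separator at record ",
         which(substr(plus, 1, 1) != "+")[1], " in ", path)
  }
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  if (any(nchar(seqs) != nchar(quals))) {
    stop("sequence/quality length mismatch at record ",
         which(nchar(seqs) != nchar(quals))[1], " in ", path)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", heads)),
             sequence = toupper(seqs), quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file with a constant quality character
#'
#' @param ids,seqs character vectors.
#' @param path output file.
#' @param qual_char single quality character (default `"?"`, Phred 30).
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "?") {
  quals <- stringi::stri_dup(qual_char, nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  invisible(path)
}

# ---- miRNA variant-name codec ------------------------------------------

#' Construct a miRNA name object
#'
#' The structured form of an isomiR-style identifier: a base mature or
#' precursor-arm name plus optional 5'/3' end-offset tokens (`_L+n`,
#' `_R-n`; positive = extended, negative = trimmed, combined as e.g.
#' `_L-1R+1` when both are present) and an internal-substitution token
#' (`_1ss20CT`: one substitution, position 20 on the observed tag,
#' reference C observed T).  Novel-candidate names of the form
#' `PC-5p-<serial>` may carry an opaque trailing `_<number>` id.
#'
#' @param base base name, e.g. `"osa-miR1432-5p"`.
#' @param left_offset,right_offset signed end offsets in nt.
#' @param substitutions data.frame with columns `pos` (1-based on the
#'   observed tag), `ref`, `obs`; or `NULL`.
#' @param candidate_id opaque trailing id for `PC-` candidates, or `NA`.
#' @return object of class `mirna_name`.
#' @export
mirna_name <- function(base, left_offset = 0L, right_offset = 0L,
                       substitutions = NULL, candidate_id = NA_character_) {
  if (is.null(substitutions)) {
    substitutions <- data.frame(pos = integer(), ref = character(),
                                obs = character(), stringsAsFactors = FALSE)
  }
  arm <- if (grepl("-5p$|-p5$", base) || grepl("^PC-5p-", base)) {
    "5p"
  } else if (grepl("-3p$|-p3$", base) || grepl("^PC-3p-", base)) {
    "3p"
  } else {
    "none"
  }
  structure(list(base = base,
                 left_offset = as.integer(left_offset),
                 right_offset = as.integer(right_offset),
                 substitutions = substitutions,
                 arm = arm,
                 candidate_id = candidate_id),
            class = "mirna_name")
}

#' @export
print.mirna_name <- function(x, ...) {
  cat("<mirna_name>", format_mirna_name(x), "\n")
  invisible(x)
}

#' Parse a miRNA identifier into its structured parts
#'
#' Accepts a base name followed by underscore-separated variant tokens:
#' an end-offset token (`L+3`, `R-1`, or combined `L-1R+1`) and a
#' substitution token (`1ss20CT`, `2ss5CT12GA`).  `PC-` candidate names
#' may instead carry a purely numeric trailing token, kept as an opaque
#' `candidate_id`.  Any other trailing token is an error.
#'
#' @param name identifier string.
#' @return `mirna_name` object; `format_mirna_name(parse_mirna_name(x))`
#'   round-trips for every supported grammar form.
#' @export
parse_mirna_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  toks <- strsplit(name, "_", fixed = TRUE)[[1]]
  base <- toks[1]
  toks <- toks[-1]
  left <- 0L
  right <- 0L
  subs <- NULL
  cand <- NA_character_
  re_lr <- "^(L([+-][0-9]+))?(R([+-][0-9]+))?$"
  for (tok in toks) {
    if (grepl("^[0-9]+ss", tok)) {
      k <- as.integer(sub("^([0-9]+)ss.*$", "\\1", tok))
      body <- sub("^[0-9]+ss", "", tok)
      m <- gregexpr("([0-9]+)([ACGTUN])([ACGTUN])", body)
      parts <- regmatches(body, m)[[1]]
      if (length(parts) != k || paste(parts, collapse = "") != body) {
        stop("unparseable substitution token '", tok, "' in '", name, "'")
      }
      subs <- data.frame(
        pos = as.integer(sub("^([0-9]+).*$", "\\1", parts)),
        ref = sub("^[0-9]+(.).$", "\\1", parts),
        obs = sub("^[0-9]+.(.)$", "\\1", parts),
        stringsAsFactors = FALSE)
    } else if (nzchar(tok) && grepl(re_lr, tok) && grepl("[LR]", tok)) {
      lm <- regmatches(tok, regexec("L([+-][0-9]+)", tok))[[1]]
      rm_ <- regmatches(tok, regexec("R([+-][0-9]+)", tok))[[1]]
      if (length(lm)) left <- as.integer(lm[2])
      if (length(rm_)) right <- as.integer(rm_[2])
    } else if (grepl("^[0-9]+$", tok) && grepl("^PC-", base)) {
      cand <- tok
    } else {
      stop("unrecognized name token '", tok, "' in '", name, "'")
    }
  }
  mirna_name(base, left, right, subs, cand)
}

#' Format a structured miRNA name back to its string form
#'
#' Token order is canonical: end-offset token first (combined `L..R..`
#' when both offsets are non-zero), then the substitution token, then a
#' candidate id.
#'
#' @param m `mirna_name` object.
#' @return identifier string; inverse of [parse_mirna_name()].
#' @export
format_mirna_name <- function(m) {
  stopifnot(inherits(m, "mirna_name"))
  out <- m$base
  fmt_off <- function(prefix, v) sprintf("%s%+d", prefix, v)
  if (m$left_offset != 0L && m$right_offset != 0L) {
    out <- paste0(out, "_", fmt_off("L", m$left_offset),
                  fmt_off("R", m$right_offset))
  } else if (m$left_offset != 0L) {
    out <- paste0(out, "_", fmt_off("L", m$left_offset))
  } else if (m$right_offset != 0L) {
    out <- paste0(out, "_", fmt_off("R", m$right_offset))
  }
  if (nrow(m$substitutions)) {
    s <- m$substitutions[order(m$substitutions$pos), , drop = FALSE]
    out <- paste0(out, "_", nrow(s), "ss",
                  paste0(s$pos, s$ref, s$obs, collapse = ""))
  }
  if (!is.na(m$candidate_id)) out <- paste0(out, "_", m$candidate_id)
  out
}

# ---- TE annotation ------------------------------------------------------

TE_CLASSES <- c("I", "II")

#' Read a transposable-element annotation
#'
#' GFF3 input (1-based inclusive) is converted to 0-based half-open
#' coordinates; BED input (columns 1-6 plus `te_class`, `te_type` in
#' columns 7-8) is taken as is.  GFF3 records carry `te_class` and
#' `te_type` attributes; a missing `te_type` defaults to
#' `"unclassified"`.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `te_class`, `te_type`, sorted by (chrom, start).
#' @export
read_te_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("TE annotation not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    mc <- as.data.frame(GenomicRanges::mcols(gr))
    df$te_class <- if ("te_class" %in% names(mc)) {
      as.character(mc$te_class)
    } else {
      NA_character_
    }
    df$te_type <- if ("te_type" %in% names(mc)) {
      as.character(mc$te_type)
    } else {
      NA_character_
    }
  } else {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 8) stop("BED TE annotation needs 8 columns (BED6 + te_class, te_type)")
    df <- data.frame(chrom = as.character(df[[1]]),
                     start = as.integer(df[[2]]),
                     end = as.integer(df[[3]]),
                     strand = as.character(df[[6]]),
                     te_class = as.character(df[[7]]),
                     te_type = as.character(df[[8]]),
                     stringsAsFactors = FALSE)
  }
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$te_type[is.na(df$te_type) | !nzchar(df$te_type)] <- "unclassified"
  bad <- is.na(df$te_class) | !df$te_class %in% TE_CLASSES
  if (any(bad)) {
    stop("unknown te_class value '", df$te_class[which(bad)[1]],
         "'; allowed: ", paste(TE_CLASSES, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("invalid TE locus with start >= end")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a TE annotation as GFF3
#'
#' @param te data.frame as returned by [read_te_annotation()]
#'   (0-based half-open coordinates).
#' @param path output file.
#' @export
write_te_gff3 <- function(te, path) {
  lines <- sprintf("%s\tpollensmrna\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=te%05d;te_class=%s;te_type=%s",
                   te$chrom, te$start + 1L, te$end, te$strand,
                   seq_len(nrow(te)), te$te_class, te$te_type)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---- count tables -------------------------------------------------------

#' Write a tab-separated count table
#'
#' First column is `id` (sequence or miRNA name), remaining columns are
#' library ids.  Rows are written in lexicographic id order; a comment
#' line records whether counts are raw or normalized.
#'
#' @param x data.frame with an `id` column plus one numeric column per
#'   library.
#' @param path output file.
#' @param kind `"raw"` or `"normalized"`, recorded in the header comment.
#' @export
write_count_table <- function(x, path, kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  stopifnot("id" %in% names(x))
  x <- x[order(x$id), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pollensmrna count table; counts=", kind), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated count table written by [write_count_table()]
#'
#' @param path input file.
#' @return data.frame; attribute `"kind"` carries the raw/normalized flag.
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- if (grepl("counts=normalized", first)) "normalized" else "raw"
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  attr(x, "kind") <- kind
  x
}
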