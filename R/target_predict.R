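# miRNA target-site scoring: ungapped antiparallel complementarity with
# G:U wobble penalty 0.5, other mismatch 1.0, penalties doubled in the
# seed (miRNA positions 2-13 from the 5' end), sites kept at score <= 4.

#' Target-scoring parameters
#'
#' @param seed_start,seed_end seed window on the miRNA, 1-based
#'   inclusive from its 5' end (defaults 2 and 13).
#' @param gu_penalty penalty for a G:U wobble pair (default 0.5).
#' @param mismatch_penalty penalty for any other non-Watson-Crick pair
#'   (default 1).
#' @param seed_multiplier multiplier applied to penalties inside the
#'   seed (default 2).
#' @param max_score maximal total score for an emitted site (default 4).
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(seed_start = 2L, seed_end = 13L,
                           gu_penalty = 0.5, mismatch_penalty = 1,
                           seed_multiplier = 2, max_score = 4) {
  stopifnot(seed_start >= 1, seed_end >= seed_start,
            gu_penalty >= 0, mismatch_penalty >= 0)
  structure(list(seed_start = seed_start, seed_end = seed_end,
                 gu_penalty = gu_penalty,
                 mismatch_penalty = mismatch_penalty,
                 seed_multiplier = seed_multiplier,
                 max_score = max_score),
            class = "scoring_params")
}

duplex_penalties <- function(mirna_i, site_rev_i, params) {
  # mirna_i: miRNA as ints 5'->3'; site_rev_i: site reversed so that
  # element i faces miRNA position i (antiparallel pairing)
  A <- utf8ToInt("A"); C <- utf8ToInt("C")
  G <- utf8ToInt("G"); T <- utf8ToInt("T")
  comp <- integer(128)
  comp[A] <- T; comp[T] <- A; comp[G] <- C; comp[C] <- G
  wc <- comp[mirna_i] == site_rev_i
  gu <- (mirna_i == G & site_rev_i == T) | (mirna_i == T & site_rev_i == G)
  pen <- ifelse(wc, 0, ifelse(gu, params$gu_penalty,
                              params$mismatch_penalty))
  seed <- seq_along(mirna_i) >= params$seed_start &
    seq_along(mirna_i) <= params$seed_end
  pen[seed] <- pen[seed] * params$seed_multiplier
  pen
}

#' Score one miRNA:site duplex
#'
#' The site is given 5'->3' on the mRNA and pairs antiparallel to the
#' miRNA: miRNA position i (1-based from its 5' end) faces site
#' position L-i+1.  Watson-Crick pairs score 0, G:U wobbles
#' `gu_penalty`, other mismatches `mismatch_penalty`; penalties inside
#' the seed are multiplied by `seed_multiplier`.
#'
#' @param mirna_seq miRNA sequence (5'->3').
#' @param site_seq site sequence (5'->3' on the mRNA), same length.
#' @param params [scoring_params()].
#' @return list with `score` and `penalties` (per miRNA position).
#' @export
score_duplex <- function(mirna_seq, site_seq, params = scoring_params()) {
  mirna_seq <- normalize_seq(mirna_seq)
  site_seq <- normalize_seq(site_seq)
  if (nchar(mirna_seq) != nchar(site_seq)) {
    stop("miRNA and site must have equal length (no gaps supported)")
  }
  m <- utf8ToInt(mirna_seq)
  s <- rev(utf8ToInt(site_seq))
  pen <- duplex_penalties(m, s, params)
  list(score = sum(pen), penalties = pen)
}

#' Scan a transcript for target sites of one miRNA
#'
#' Every window of miRNA length is scored; windows with score at most
#' `params$max_score` are emitted, sorted by (score, position).
#' Overlapping sites are allowed.
#'
#' @param mirna_seq miRNA sequence (5'->3').
#' @param transcript_seq transcript sequence (sense strand).
#' @param params [scoring_params()].
#' @return data.frame with `start`, `end` (0-based half-open on the
#'   transcript) and `score`.
#' @export
scan_transcript <- function(mirna_seq, transcript_seq,
                            params = scoring_params()) {
  mirna_seq <- normalize_seq(mirna_seq)
  transcript_seq <- normalize_seq(transcript_seq)
  L <- nchar(mirna_seq)
  Tn <- nchar(transcript_seq)
  empty <- data.frame(start = integer(), end = integer(),
                      score = numeric())
  if (Tn < L) return(empty)
  m <- utf8ToInt(mirna_seq)
  tx <- utf8ToInt(transcript_seq)
  W <- Tn - L + 1L
  idx <- outer(seq_len(L) - 1L, seq_len(W), "+")
  win <- matrix(tx[idx], nrow = L)
  win_rev <- win[L:1, , drop = FALSE]
  A <- utf8ToInt("A"); C <- utf8ToInt("C")
  G <- utf8ToInt("G"); T <- utf8ToInt("T")
  comp <- integer(128)
  comp[A] <- T; comp[T] <- A; comp[G] <- C; comp[C] <- G
  wc <- win_rev == comp[m]
  gu <- (m == G & win_rev == T) | (m == T & win_rev == G)
  pen <- ifelse(wc, 0, ifelse(gu, params$gu_penalty,
                              params$mismatch_penalty))
  seed <- seq_len(L) >= params$seed_start & seq_len(L) <= params$seed_end
  pen[seed, ] <- pen[seed, , drop = FALSE] * params$seed_multiplier
  scores <- colSums(pen)
  keep <- which(scores <= params$max_score)
  if (!length(keep)) return(empty)
  out <- data.frame(start = keep - 1L, end = keep - 1L + L,
                    score = scores[keep])
  out[order(out$score, out$start), , drop = FALSE]
}

#' Render a duplex alignment string for reporting
#'
#' @param mirna_seq,site_seq equal-length sequences as in
#'   [score_duplex()].
#' @param params [scoring_params()].
#' @return three-line string: site 5'->3', pairing line (`|` WC, `o`
#'   G:U, space mismatch), miRNA 3'->5'.
#' @export
render_duplex <- function(mirna_seq, site_seq, params = scoring_params()) {
  sd <- score_duplex(mirna_seq, site_seq, params)
  m <- utf8ToInt(normalize_seq(mirna_seq))
  s <- rev(utf8ToInt(normalize_seq(site_seq)))
  G <- utf8ToInt("G"); T <- utf8ToInt("T")
  gu <- (m == G & s == T) | (m == T & s == G)
  base_pen <- sd$penalties
  seedpos <- seq_along(m) >= params$seed_start &
    seq_along(m) <= params$seed_end
  base_pen[seedpos] <- base_pen[seedpos] / params$seed_multiplier
  marks <- ifelse(base_pen == 0, "|", ifelse(gu, "o", " "))
  paste0("5' ", normalize_seq(site_seq), " 3' (site)\n",
         "   ", paste(rev(marks), collapse = ""), "\n",
         "3' ", stringi::stri_reverse(normalize_seq(mirna_seq)),
         " 5' (miRNA)")
}

#' Extract the gene id from a transcript identifier
#'
#' Collapses isoform suffixes: `LOC_Os05g07210.1` -> `LOC_Os05g07210`.
#'
#' @param transcript_ids character vector.
#' @return character vector of gene ids.
#' @export
gene_of_transcript <- function(transcript_ids) {
  sub("\\.\\d+$", "", transcript_ids)
}

#' Predict targets for a set of miRNAs over a transcriptome
#'
#' @param mirnas data.frame with `name` and `sequence`.
#' @param transcripts data.frame with `id` and `sequence` (from
#'   [read_fasta()]).
#' @param params [scoring_params()].
#' @return data.frame with `mirna`, `transcript`, `gene`, `start`,
#'   `end`, `score`.
#' @export
predict_targets <- function(mirnas, transcripts,
                            params = scoring_params()) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(transcripts))) {
      sites <- scan_transcript(mirnas$sequence[i],
                               transcripts$sequence[j], params)
      if (nrow(sites)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mirnas$name[i], transcript = transcripts$id[j],
          gene = gene_of_transcript(transcripts$id[j]),
          start = sites$start, end = sites$end, score = sites$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(), transcript = character(),
                      gene = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
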