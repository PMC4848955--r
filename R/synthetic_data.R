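# Synthetic study generator: a two-genotype (2x/4x) x three-stage
# (PMA/MA/SCP) small-RNA experiment with planted miRNAs (known,
# variant, novel-arm, other-species, novel hairpin candidates),
# TE-derived 24-nt siRNA populations with genotype-specific stage
# profiles, ncRNA contaminants and junk, plus a machine-readable truth
# table.

STAGES <- c("PMA", "MA", "SCP")
GENOTYPES <- c("2x", "4x")

TE_TYPE_VOCAB <- data.frame(
  te_class = c(rep("I", 5), rep("II", 5)),
  te_type = c("Ty3-gypsy", "Copia", "LINE", "SINE", "unclassified",
              "En/Spm", "hAT", "Mutator", "Helitron", "unclassified"),
  stringsAsFactors = FALSE)

#' Default study design table
#'
#' @return data.frame with `library_id`, `genotype`, `stage` for the
#'   six libraries.
#' @export
default_design <- function() {
  data.frame(
    library_id = paste(rep(STAGES, 2), rep(GENOTYPES, each = 3), sep = "_"),
    genotype = rep(GENOTYPES, each = 3),
    stage = rep(STAGES, 2),
    stringsAsFactors = FALSE)
}

#' Synthetic study configuration
#'
#' Defaults emulate the study design at desk scale: six libraries of
#' about 2e5 reads with unequal sizes, tag sizes dominated by 24 nt
#' (TE siRNAs) with a secondary 21 nt peak (miRNAs), planted
#' between-genotype fold changes of 4 (>= 2), and isomiR variant
#' channels with end offsets up to 3 nt and single internal
#' substitutions.
#'
#' @param seed integer seed driving every random choice.
#' @param depth base reads per library (default 2e5).
#' @param lib_multipliers named per-library size multipliers.
#' @param n_known,n_novel_arm,n_other,n_pc planted miRNA counts per
#'   category.
#' @param n_te_per_type TE loci per type (default 4).
#' @param sirna_per_type distinct 24-nt siRNA tags per TE type
#'   (default 12, matching the tens of siRNAs per main type in the
#'   emulated study).
#' @param adapter 3' adapter (Illumina TruSeq small-RNA).
#' @param read_len raw read length (default 36).
#' @param frac_ncrna,frac_dimer ncRNA-contaminant and adapter-dimer
#'   read fractions.
#' @param n_junk number of distinct junk/degradation tags (default
#'   7000); they dominate the unique-tag population, as in real
#'   libraries, and carry no genotype or stage effect.
#' @param junk_rel total junk intensity relative to the miRNA + TE
#'   channels (default 6).
#' @param n_abundant number of abundant stable degradation tags
#'   (default 150); their intensities span the top of the abundance
#'   range, as rRNA-derived fragments do in real libraries.
#' @param error_rate optional per-base sequencing error rate
#'   (default 0).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, depth = 2e5,
                         lib_multipliers = c(PMA_2x = 1.00, MA_2x = 1.10,
                                             SCP_2x = 0.70, PMA_4x = 0.95,
                                             MA_4x = 0.90, SCP_4x = 0.75),
                         n_known = 24L, n_novel_arm = 8L, n_other = 6L,
                         n_pc = 6L, n_te_per_type = 4L,
                         sirna_per_type = 12L,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         read_len = 36L,
                         frac_ncrna = 0.10, n_junk = 7000L,
                         junk_rel = 6, n_abundant = 150L,
                         frac_dimer = 0.015, error_rate = 0) {
  design <- default_design()
  stopifnot(all(design$library_id %in% names(lib_multipliers)),
            depth > 0, all(lib_multipliers > 0),
            frac_ncrna < 1)
  structure(list(seed = as.integer(seed), depth = depth,
                 lib_multipliers = lib_multipliers, design = design,
                 n_known = n_known, n_novel_arm = n_novel_arm,
                 n_other = n_other, n_pc = n_pc,
                 n_te_per_type = n_te_per_type,
                 sirna_per_type = sirna_per_type,
                 adapter = normalize_seq(adapter), read_len = read_len,
                 frac_ncrna = frac_ncrna, n_junk = n_junk,
                 junk_rel = junk_rel, n_abundant = n_abundant,
                 frac_dimer = frac_dimer, error_rate = error_rate),
            class = "synth_config")
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos) {
  b <- substr(seq, pos, pos)
  nb <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
  substr(seq, pos, pos) <- nb
  seq
}

#' Build the synthetic reference set
#'
#' Constructs a genome with embedded other-species precursor hairpins,
#' novel-candidate hairpins (perfect inverted repeats) and TE loci;
#' rice precursor hairpins with annotated mature arms (5p and 3p for
#' the known set, 5p only for the novel-arm set); planted isomiR
#' variant tags; transcripts carrying perfect target sites for a
#' subset of planted miRNAs; a gene/term annotation map; and ncRNA
#' contaminant records.  All randomness is driven by `cfg$seed`.
#'
#' @param cfg [synth_config()].
#' @return list with `genome`, `rice_precursors`, `other_precursors`,
#'   `te_loci`, `transcripts`, `annotation`, `contaminants`,
#'   `mirna_truth` (planted tag sequence, expected name, category),
#'   `te_tags` (planted TE siRNA tags with class/type) and
#'   `target_truth`.
#' @export
make_reference <- function(cfg) {
  set.seed(cfg$seed)
  arm_len <- 21L
  # rice precursors: pad + 5p arm + loop + (rc of 5p with 2 internal
  # substitutions) + pad
  n_rice <- cfg$n_known + cfg$n_novel_arm
  rice <- data.frame(name = sprintf("osa-MIR9%03d", seq_len(n_rice)),
                     sequence = NA_character_, species = "osa",
                     m5_start = NA_integer_, m5_end = NA_integer_,
                     m5_name = NA_character_, m3_start = NA_integer_,
                     m3_end = NA_integer_, m3_name = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_rice)) {
    m5 <- rand_seq(arm_len)
    m3 <- revcomp(m5)
    for (p in sample(3:(arm_len - 2), 2)) m3 <- mutate_at(m3, p)
    seq <- paste0(rand_seq(8), m5, rand_seq(15), m3, rand_seq(8))
    rice$sequence[i] <- seq
    rice$m5_start[i] <- 8L
    rice$m5_end[i] <- 8L + arm_len
    rice$m5_name[i] <- sprintf("osa-miR9%03d-5p", i)
    if (i <= cfg$n_known) {
      rice$m3_start[i] <- 8L + arm_len + 15L
      rice$m3_end[i] <- 8L + 2L * arm_len + 15L
      rice$m3_name[i] <- sprintf("osa-miR9%03d-3p", i)
    }
  }
  # other-species precursors (embedded in the genome later); one of
  # them donates an opposite-arm tag
  prefixes <- rep(c("zma", "mes", "bdi"), length.out = cfg$n_other)
  other <- data.frame(
    name = sprintf("%s-MIR95%02d", prefixes, seq_len(cfg$n_other)),
    sequence = NA_character_, species = prefixes,
    m5_start = NA_integer_, m5_end = NA_integer_,
    m5_name = NA_character_, m3_start = NA_integer_,
    m3_end = NA_integer_, m3_name = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_other)) {
    m5 <- rand_seq(arm_len)
    m3 <- revcomp(m5)
    for (p in sample(3:(arm_len - 2), 2)) m3 <- mutate_at(m3, p)
    other$sequence[i] <- paste0(rand_seq(8), m5, rand_seq(15), m3,
                                rand_seq(8))
    other$m5_start[i] <- 8L
    other$m5_end[i] <- 8L + arm_len
    # armless mature names, as printed for foreign families
    other$m5_name[i] <- sprintf("%s-miR95%02d", prefixes[i], i)
  }
  # novel hairpin candidates: perfect inverted repeats in the genome,
  # tag = the whole 5' arm (24 nt)
  pc_arm <- 24L
  pc_tags <- character(cfg$n_pc)
  pc_blocks <- character(cfg$n_pc)
  for (i in seq_len(cfg$n_pc)) {
    arm <- rand_seq(pc_arm)
    pc_tags[i] <- arm
    pc_blocks[i] <- paste0(arm, rand_seq(8), revcomp(arm))
  }
  # TE loci blocks
  te_vocab <- TE_TYPE_VOCAB
  te_rows <- te_vocab[rep(seq_len(nrow(te_vocab)),
                          each = cfg$n_te_per_type), ]
  te_len <- 300L
  te_blocks <- vapply(seq_len(nrow(te_rows)), function(i) rand_seq(te_len),
                      character(1))
  # assemble the genome: spacer | blocks | spacer
  blocks <- c(other$sequence, pc_blocks, te_blocks)
  block_kind <- c(rep("other", cfg$n_other), rep("pc", cfg$n_pc),
                  rep("te", nrow(te_rows)))
  spacer_len <- function() sample(80:150, 1)
  genome_parts <- character(0)
  coords <- data.frame(kind = character(), idx = integer(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  pos <- 0L
  ord <- sample(length(blocks))
  for (b in ord) {
    sp <- rand_seq(spacer_len())
    genome_parts <- c(genome_parts, sp)
    pos <- pos + nchar(sp)
    genome_parts <- c(genome_parts, blocks[b])
    coords <- rbind(coords, data.frame(
      kind = block_kind[b], idx = b, start = pos,
      end = pos + nchar(blocks[b]), stringsAsFactors = FALSE))
    pos <- pos + nchar(blocks[b])
  }
  genome_parts <- c(genome_parts, rand_seq(spacer_len()))
  genome <- data.frame(id = "chr1",
                       sequence = paste(genome_parts, collapse = ""),
                       stringsAsFactors = FALSE)
  te_idx <- which(block_kind == "te")
  te_coord <- coords[match(te_idx, coords$idx), ]
  te_loci <- data.frame(chrom = "chr1", start = te_coord$start,
                        end = te_coord$end,
                        strand = sample(c("+", "-"), nrow(te_rows),
                                        replace = TRUE),
                        te_class = te_rows$te_class,
                        te_type = te_rows$te_type,
                        stringsAsFactors = FALSE)
  te_loci <- te_loci[order(te_loci$chrom, te_loci$start), ]
  # planted miRNA tags ---------------------------------------------------
  sub1 <- function(seq, s, e) substr(seq, s + 1L, e)   # 0-based helper
  truth <- list()
  add_truth <- function(seq, name, category, source) {
    truth[[length(truth) + 1L]] <<- data.frame(
      sequence = seq, name = name, category = category,
      source = source, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_known)) {
    add_truth(sub1(rice$sequence[i], rice$m5_start[i], rice$m5_end[i]),
              rice$m5_name[i], "KNOWN_RICE_MATURE", rice$name[i])
  }
  # isomiR variant channels on the first known precursors: R offsets,
  # L offsets, single internal substitutions
  variant_spec <- data.frame(
    prec = c(1:4, 5:8, 9:14),
    type = c(rep("R", 4), rep("L", 4), rep("ss", 6)),
    off = c(1L, 2L, 3L, -1L, 1L, 2L, -1L, -2L, rep(0L, 6)),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(variant_spec))) {
    i <- variant_spec$prec[k]
    s0 <- rice$m5_start[i]; e0 <- rice$m5_end[i]
    base <- rice$m5_name[i]
    if (variant_spec$type[k] == "R") {
      off <- variant_spec$off[k]
      tag <- sub1(rice$sequence[i], s0, e0 + off)
      nm <- mirna_name(base, 0L, off)
    } else if (variant_spec$type[k] == "L") {
      off <- variant_spec$off[k]
      tag <- sub1(rice$sequence[i], s0 - off, e0)
      nm <- mirna_name(base, off, 0L)
    } else {
      mseq <- sub1(rice$sequence[i], s0, e0)
      p <- sample(3:(arm_len - 2), 1)
      ref <- substr(mseq, p, p)
      tag <- mutate_at(mseq, p)
      nm <- mirna_name(base, 0L, 0L,
                       data.frame(pos = p, ref = ref,
                                  obs = substr(tag, p, p),
                                  stringsAsFactors = FALSE))
    }
    add_truth(tag, format_mirna_name(nm), "KNOWN_RICE_MATURE",
              rice$name[i])
  }
  for (i in (cfg$n_known + seq_len(cfg$n_novel_arm))) {
    # tag on the unannotated 3p arm
    s0 <- 8L + arm_len + 15L
    add_truth(sub1(rice$sequence[i], s0, s0 + arm_len),
              paste0(rice$name[i], "-p3"),
              "NOVEL_ARM_OF_RICE_PRECURSOR", rice$name[i])
  }
  for (i in seq_len(cfg$n_other)) {
    add_truth(sub1(other$sequence[i], other$m5_start[i], other$m5_end[i]),
              other$m5_name[i], "KNOWN_OTHER_SPECIES_GENOME_MAPPED",
              other$name[i])
  }
  # one opposite-arm tag on an other-species hairpin
  s0 <- 8L + arm_len + 15L
  add_truth(sub1(other$sequence[1], s0, s0 + arm_len),
            paste0(other$name[1], "-p3"), "NOVEL_ARM_OF_OTHER_SPECIES",
            other$name[1])
  for (i in seq_len(cfg$n_pc)) {
    add_truth(pc_tags[i], NA_character_, "NOVEL_PC_CANDIDATE",
              "genome")
  }
  mirna_truth <- do.call(rbind, truth)
  # TE siRNA tags: 24-nt substrings of each locus
  te_tag_rows <- list()
  for (i in seq_len(nrow(te_loci))) {
    if ((i - 1L) %% cfg$n_te_per_type == 0L) {
      # distribute sirna_per_type tags over the type's loci
      remaining <- cfg$sirna_per_type
    }
    type_loci_left <- cfg$n_te_per_type - (i - 1L) %% cfg$n_te_per_type
    k <- if (type_loci_left == 1L) {
      remaining
    } else {
      min(remaining, ceiling(cfg$sirna_per_type / cfg$n_te_per_type))
    }
    remaining <- remaining - k
    if (k <= 0) next
    starts <- sample(seq(te_loci$start[i] + 1L, te_loci$end[i] - 24L),
                     k)
    for (s in starts) {
      te_tag_rows[[length(te_tag_rows) + 1L]] <- data.frame(
        sequence = substr(genome$sequence, s, s + 23L),
        te_class = te_loci$te_class[i], te_type = te_loci$te_type[i],
        stringsAsFactors = FALSE)
    }
  }
  te_tags <- unique(do.call(rbind, te_tag_rows))
  # contaminants and junk -----------------------------------------------
  contaminants <- data.frame(
    id = c("rRNA1", "rRNA2", "tRNA1", "snRNA1", "snoRNA1"),
    sequence = vapply(1:5, function(i) rand_seq(150), character(1)),
    stringsAsFactors = FALSE)
  # transcripts with perfect target sites for the planted miRNAs
  with_targets <- mirna_truth[!is.na(mirna_truth$name), ]
  n_tx <- nrow(with_targets)
  tx_ids <- sprintf("LOC_Os%02dg%05d.1", sample(1:12, n_tx, TRUE),
                    sample(10000:99999, n_tx))
  tx_rows <- list()
  tt_rows <- list()
  for (i in seq_len(n_tx)) {
    site <- revcomp(with_targets$sequence[i])
    offset <- sample(40:120, 1)
    seq <- paste0(rand_seq(offset), site,
                  rand_seq(260 - offset))
    tx_rows[[i]] <- data.frame(id = tx_ids[i], sequence = seq,
                               stringsAsFactors = FALSE)
    tt_rows[[i]] <- data.frame(mirna = with_targets$name[i],
                               transcript = tx_ids[i],
                               gene = gene_of_transcript(tx_ids[i]),
                               start = offset, score = 0,
                               stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, tx_rows)
  target_truth <- do.call(rbind, tt_rows)
  # annotation map: every target gene plus background genes; one term
  # planted on a block of genes so enrichment has signal to find
  genes <- unique(c(target_truth$gene,
                    sprintf("LOC_Os%02dg%05d", sample(1:12, 30, TRUE),
                            sample(10000:99999, 30))))
  terms <- c("GO:0006810", "GO:0000003", "GO:0016740", "GO:0005215",
             "GO:0005634")
  ann_rows <- list()
  for (g in genes) {
    for (tm in sample(terms, sample(1:2, 1))) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene = g, term = tm, stringsAsFactors = FALSE)
    }
  }
  annotation <- unique(do.call(rbind, ann_rows))
  list(genome = genome, rice_precursors = rice,
       other_precursors = other, te_loci = te_loci,
       transcripts = transcripts, annotation = annotation,
       contaminants = contaminants, mirna_truth = mirna_truth,
       te_tags = te_tags, target_truth = target_truth)
}

#' Planted expression model and truth table
#'
#' Assigns base intensities to every planted tag and the
#' genotype-by-stage modulation: a subset of miRNAs carries 4-fold
#' changes in the autotetraploid (some in all stages, some
#' stage-specific, some down-regulated); TE siRNAs follow per-genotype
#' stage profiles (declining in the diploid, MA-enriched in the
#' autotetraploid).
#'
#' @param cfg [synth_config()].
#' @param ref [make_reference()] output.
#' @return list with `weights` (matrix: tag x library intensity),
#'   `channel` (per-tag channel label), `dem_truth` (per planted
#'   miRNA and stage: `up`/`down`/`ns`), `te_profile` (per genotype
#'   and stage multipliers).
#' @export
plant_expression <- function(cfg, ref) {
  set.seed(cfg$seed + 1L)
  design <- cfg$design
  libs <- design$library_id
  mt <- ref$mirna_truth
  n_mir <- nrow(mt)
  mir_base <- exp(rnorm(n_mir, log(400), 0.5))
  mir_base <- pmax(mir_base, 120)
  # DEM spec over named miRNAs (PC candidates get names later; use
  # their sequences as keys)
  named_idx <- seq_len(n_mir)
  de_all_up <- named_idx[1:6]
  de_ma_up <- named_idx[7:10]
  de_scp_up <- named_idx[11:13]
  de_all_down <- named_idx[14:18]
  ratio <- 4
  dem_truth <- expand.grid(sequence = mt$sequence, stage = STAGES,
                           stringsAsFactors = FALSE)
  dem_truth$status <- "ns"
  w_mir <- matrix(rep(mir_base, length(libs)), ncol = length(libs),
                  dimnames = list(mt$sequence, libs))
  for (j in seq_along(libs)) {
    g <- design$genotype[j]
    st <- design$stage[j]
    if (g == "4x") {
      w_mir[de_all_up, j] <- w_mir[de_all_up, j] * ratio
      if (st == "MA") w_mir[de_ma_up, j] <- w_mir[de_ma_up, j] * ratio
      if (st == "SCP") w_mir[de_scp_up, j] <- w_mir[de_scp_up, j] * ratio
      w_mir[de_all_down, j] <- w_mir[de_all_down, j] / ratio
    }
  }
  for (st in STAGES) {
    up <- c(de_all_up, if (st == "MA") de_ma_up,
            if (st == "SCP") de_scp_up)
    dem_truth$status[dem_truth$stage == st &
                       dem_truth$sequence %in% mt$sequence[up]] <- "up"
    dem_truth$status[dem_truth$stage == st &
                       dem_truth$sequence %in%
                       mt$sequence[de_all_down]] <- "down"
  }
  # TE siRNA channel, modulated by per-genotype stage profiles; per
  # tag the abundance sits inside the bulk range so the siRNA class
  # does not form its own high-abundance stratum
  te <- ref$te_tags
  te_base <- exp(rnorm(nrow(te), log(250), 0.4))
  te_base <- pmax(te_base, 20)
  te_profile <- rbind(`2x` = c(PMA = 3.0, MA = 2.0, SCP = 1.0),
                      `4x` = c(PMA = 1.5, MA = 3.2, SCP = 2.8))
  w_te <- matrix(0, nrow(te), length(libs),
                 dimnames = list(te$sequence, libs))
  for (j in seq_along(libs)) {
    w_te[, j] <- te_base * te_profile[design$genotype[j],
                                      design$stage[j]]
  }
  # ncRNA fragments
  frag <- character(0)
  for (i in seq_len(nrow(ref$contaminants))) {
    for (k in 1:8) {
      L <- sample(19:24, 1)
      s <- sample(seq_len(150 - L), 1)
      frag <- c(frag, substr(ref$contaminants$sequence[i], s, s + L - 1L))
    }
  }
  frag <- unique(frag)
  # junk/degradation: the stable bulk of the unique-tag population,
  # with a 24-nt-dominant (21-nt secondary) length mixture as in the
  # study's unique-tag size histogram
  len_mix <- c(`18` = 0.03, `19` = 0.04, `20` = 0.06, `21` = 0.18,
               `22` = 0.08, `23` = 0.08, `24` = 0.30, `25` = 0.06,
               `26` = 0.04, `27` = 0.04, `28` = 0.03, `29` = 0.03,
               `30` = 0.03)
  n_plain <- cfg$n_junk
  n_hi <- cfg$n_abundant
  junk <- character(0)
  while (length(junk) < n_plain + n_hi) {
    need <- n_plain + n_hi - length(junk)
    lens <- sample(as.integer(names(len_mix)), need + 50L,
                   replace = TRUE, prob = len_mix)
    cand <- vapply(lens, rand_seq, character(1))
    ok <- !stringi::stri_detect_fixed(ref$genome$sequence, cand) &
      !cand %in% junk & !duplicated(cand)
    junk <- c(junk, cand[ok])
  }
  junk <- junk[seq_len(n_plain + n_hi)]
  base_total <- sum(mir_base) + sum(te_base)
  w_plain <- exp(rnorm(n_plain, log(30), 1.0))
  w_plain <- w_plain * base_total * cfg$junk_rel / sum(w_plain)
  # abundant stable degradation tags anchor the top of the range
  w_hi <- exp(rnorm(n_hi, log(1000), 0.7))
  w_junk <- c(w_plain, w_hi)
  w_frag <- rep((base_total + sum(w_junk)) * cfg$frac_ncrna /
                  (1 - cfg$frac_ncrna) / length(frag), length(frag))
  w_other <- matrix(rep(c(w_frag, w_junk), length(libs)),
                    ncol = length(libs),
                    dimnames = list(c(frag, junk), libs))
  weights <- rbind(w_mir, w_te, w_other)
  channel <- c(rep("mirna", nrow(w_mir)), rep("te", nrow(w_te)),
               rep("ncrna", length(frag)), rep("junk", n_plain),
               rep("degradation", n_hi))
  names(channel) <- rownames(weights)
  list(weights = weights, channel = channel, dem_truth = dem_truth,
       te_profile = te_profile, mir_base = mir_base, te_base = te_base)
}

#' Simulate the six FASTQ libraries
#'
#' Reads are drawn multinomially from the planted tag intensities with
#' per-library size multipliers; a small adapter-dimer channel is
#' added; the 3' adapter is appended and reads are clipped to
#' `read_len` with constant Phred 30 qualities.  Identical seed and
#' configuration give byte-identical outputs.
#'
#' @param cfg [synth_config()].
#' @param ref [make_reference()] output.
#' @param out_dir directory for the FASTQ files (created).
#' @return list with `fastq` (named paths), `expression` (the
#'   [plant_expression()] model), `expected_rpm` (tag x library
#'   expected reads per million of non-dimer reads) and `truth_path`
#'   (JSON truth table).
#' @export
simulate_libraries <- function(cfg, ref, out_dir) {
  expr <- plant_expression(cfg, ref)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed + 2L)
  libs <- cfg$design$library_id
  W <- expr$weights
  paths <- setNames(character(length(libs)), libs)
  expected_rpm <- sweep(W, 2, colSums(W), "/") * 1e6
  for (j in seq_along(libs)) {
    l <- libs[j]
    depth <- round(cfg$depth * cfg$lib_multipliers[[l]])
    n_dimer <- round(depth * cfg$frac_dimer)
    n_tags <- depth - n_dimer
    counts <- rmultinom(1, n_tags, W[, j] / sum(W[, j]))[, 1]
    tags <- rep(rownames(W), counts)
    reads <- c(tags, rep("", n_dimer))
    reads <- reads[sample(length(reads))]
    full <- substr(paste0(reads, strrep(cfg$adapter, 3L)), 1L,
                   cfg$read_len)
    if (cfg$error_rate > 0) {
      nerr <- rpois(1, cfg$error_rate * sum(nchar(full)))
      if (nerr > 0) {
        ridx <- sample(length(full), nerr, replace = TRUE)
        for (r in ridx) {
          p <- sample(nchar(full[r]), 1)
          full[r] <- mutate_at(full[r], p)
        }
      }
    }
    path <- file.path(out_dir, paste0(l, ".fastq"))
    write_fastq(sprintf("%s_read%07d", l, seq_along(full)), full, path)
    paths[l] <- path
  }
  truth <- list(
    mirna = ref$mirna_truth,
    te_tags = ref$te_tags,
    dem = expr$dem_truth,
    te_profile = as.data.frame(expr$te_profile),
    design = cfg$design)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  list(fastq = paths, expression = expr, expected_rpm = expected_rpm,
       truth_path = truth_path)
}

#' Write the synthetic reference set to files
#'
#' @param ref [make_reference()] output.
#' @param out_dir output directory.
#' @return named list of paths.
#' @export
write_reference <- function(ref, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    rice_fa = file.path(out_dir, "rice_precursors.fa"),
    rice_sidecar = file.path(out_dir, "rice_mature.tsv"),
    other_fa = file.path(out_dir, "other_precursors.fa"),
    other_sidecar = file.path(out_dir, "other_mature.tsv"),
    te_gff3 = file.path(out_dir, "te_loci.gff3"),
    transcripts = file.path(out_dir, "transcripts.fa"),
    annotation = file.path(out_dir, "annotation.tsv"),
    contaminants = file.path(out_dir, "ncrna.fa"))
  write_fasta(ref$genome$id, ref$genome$sequence, paths$genome)
  write_fasta(ref$rice_precursors$name, ref$rice_precursors$sequence,
              paths$rice_fa)
  write_fasta(ref$other_precursors$name, ref$other_precursors$sequence,
              paths$other_fa)
  sidecar <- function(prec) {
    rows <- list()
    for (i in seq_len(nrow(prec))) {
      if (!is.na(prec$m5_start[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          precursor = prec$name[i], arm = "5p",
          start = prec$m5_start[i] + 1L, end = prec$m5_end[i],
          mature_name = prec$m5_name[i], stringsAsFactors = FALSE)
      }
      if (!is.na(prec$m3_start[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          precursor = prec$name[i], arm = "3p",
          start = prec$m3_start[i] + 1L, end = prec$m3_end[i],
          mature_name = prec$m3_name[i], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  write.table(sidecar(ref$rice_precursors), paths$rice_sidecar,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sidecar(ref$other_precursors), paths$other_sidecar,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_te_gff3(ref$te_loci, paths$te_gff3)
  write_fasta(ref$transcripts$id, ref$transcripts$sequence,
              paths$transcripts)
  write.table(ref$annotation, paths$annotation, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(ref$contaminants$id, ref$contaminants$sequence,
              paths$contaminants)
  paths
}

#' Compare pipeline catalog output against the planted truth
#'
#' @param assignments per-tag assignment table (from
#'   [build_catalog()]).
#' @param mirna_truth planted miRNA table (`sequence`, `name`,
#'   `category`).
#' @return list with `category_recall`, `name_recall` (over planted
#'   tags with expected names), `precision` (assigned planted tags
#'   among all assigned non-PC tags) and the per-tag join.
#' @export
truth_compare <- function(assignments, mirna_truth) {
  j <- merge(mirna_truth, assignments, by = "sequence",
             suffixes = c("_truth", "_obs"), all.x = TRUE)
  cat_ok <- !is.na(j$category_obs) & j$category_obs == j$category_truth
  named <- !is.na(j$name_truth)
  name_ok <- named & !is.na(j$name_obs) & j$name_obs == j$name_truth
  assigned_all <- assignments[!is.na(assignments$name) &
                                assignments$category != "NOVEL_PC_CANDIDATE", ]
  prec <- if (nrow(assigned_all)) {
    mean(assigned_all$sequence %in% mirna_truth$sequence)
  } else {
    NA_real_
  }
  list(category_recall = mean(cat_ok),
       name_recall = if (any(named)) sum(name_ok) / sum(named) else NA_real_,
       precision = prec,
       detail = j)
}
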