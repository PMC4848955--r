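test_that("tag-to-precursor matching equals brute-force placement enumeration", {
  set.seed(21)
  for (i in 1:30) {
    prec <- make_precursor(sprintf("osa-MIR8%02d", i))
    L <- sample(18:25, 1)
    tag <- if (i %% 3 == 0) {
      # random tag: usually no placement
      rand_dna(L)
    } else {
      # tag sampled from the precursor with an occasional mutation
      p0 <- sample(0:(nchar(prec$sequence) - L), 1)
      t <- substr(prec$sequence, p0 + 1, p0 + L)
      if (i %% 2 == 0) {
        pos <- sample(seq_len(L), 1)  # sometimes terminal: must drop
        b <- substr(t, pos, pos)
        substr(t, pos, pos) <- setdiff(c("A", "C", "G", "T"), b)[1]
      }
      t
    }
    got <- match_tag_to_precursor(tag, prec)
    want <- oracle_placements(tag, prec$sequence)
    expect_equal(got$position, vapply(want, `[[`, integer(1), "position"),
                 info = sprintf("case %d", i))
  }
})

test_that("matching applies the internal-mismatch and end-offset rules", {
  prec <- make_precursor(seed = 3)
  mat <- prec_mature5(prec)
  # identity: mature arm, zero offsets, no mismatch
  m <- match_tag_to_precursor(mat, prec)
  expect_equal(m$arm_hit, "mature_5p")
  expect_equal(m$left_offset, 0L)
  expect_equal(m$right_offset, 0L)
  expect_equal(m$n_mismatch, 0L)

  # 1 nt 3' extension
  ext <- substr(prec$sequence, prec$m5_start + 1, prec$m5_end + 1)
  m <- match_tag_to_precursor(ext, prec)
  expect_equal(m$right_offset, 1L)
  nm <- derive_variant_name(m, prec$m5_name)
  expect_equal(format_mirna_name(nm), paste0(prec$m5_name, "_R+1"))

  # mismatch at the first tag base is not allowed
  t1 <- mat
  b <- substr(t1, 1, 1)
  substr(t1, 1, 1) <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_equal(nrow(match_tag_to_precursor(t1, prec)), 0L)

  # two internal mismatches exceed the tolerance
  t2 <- mat
  for (p in c(5L, 10L)) {
    b <- substr(t2, p, p)
    substr(t2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  expect_equal(nrow(match_tag_to_precursor(t2, prec)), 0L)

  # offsets beyond the bound are not assigned to the arm
  far <- substr(prec$sequence, prec$m5_start + 1 - 4, prec$m5_end)
  m <- match_tag_to_precursor(far, prec, max_end_offset = 3)
  expect_false(any(m$arm_hit == "mature_5p"))
})

test_that("variant names carry substitution tokens with 1-based tag positions", {
  prec <- make_precursor(seed = 4)
  mat <- prec_mature5(prec)
  pos <- 7L
  ref <- substr(mat, pos, pos)
  obs <- setdiff(c("A", "C", "G", "T"), ref)[1]
  t <- mat
  substr(t, pos, pos) <- obs
  m <- match_tag_to_precursor(t, prec)
  m <- m[m$arm_hit == "mature_5p", ]
  nm <- format_mirna_name(derive_variant_name(m[1, ], prec$m5_name))
  expect_equal(nm, sprintf("%s_1ss%d%s%s", prec$m5_name, pos, ref, obs))
})

test_that("classification follows the five-rule order", {
  rice1 <- make_precursor("osa-MIR8101", seed = 31)
  rice2 <- make_precursor("osa-MIR8102", annotate_3p = FALSE, seed = 32)
  other <- make_precursor("zma-MIR8201", annotate_3p = FALSE,
                          species = "zma", seed = 33)
  other$m5_name <- "zma-miR8201"
  rice <- rbind(rice1, rice2)

  # rule 1: rice mature
  cl <- classify_tag(prec_mature5(rice1), rice, other)
  expect_equal(cl$category, "KNOWN_RICE_MATURE")
  expect_equal(cl$name, rice1$m5_name)

  # rule 2: opposite (unannotated) arm of a rice precursor
  cl <- classify_tag(prec_arm3_seq(rice2), rice, other)
  expect_equal(cl$category, "NOVEL_ARM_OF_RICE_PRECURSOR")
  expect_equal(cl$name, "osa-MIR8102-p3")

  # rule 3: other-species mature keeps the foreign prefix
  cl <- classify_tag(prec_mature5(other), rice, other)
  expect_equal(cl$category, "KNOWN_OTHER_SPECIES_GENOME_MAPPED")
  expect_equal(cl$name, "zma-miR8201")

  # rule 4: opposite arm of the other-species precursor
  cl <- classify_tag(prec_arm3_seq(other), rice, other)
  expect_equal(cl$category, "NOVEL_ARM_OF_OTHER_SPECIES")
  expect_equal(cl$name, "zma-MIR8201-p3")

  # rule 5: unmatched
  expect_null(classify_tag(rand_dna(21), rice, other))
})

test_that("single-loop maximum pairing equals the brute-force oracle on short sequences", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(12:34, 1)
    s <- rand_dna(n)
    expect_equal(hairpin_max_pairing(s, max_loop = 8, min_loop = 3),
                 oracle_hairpin(s, max_loop = 8, min_loop = 3),
                 info = s)
  }
  # a perfect planted stem is found in full
  arm <- rand_dna(10)
  hp <- paste0(arm, "AAAA", rc(arm))
  expect_gte(hairpin_max_pairing(hp, max_loop = 8), 10)
})

test_that("novel-hairpin detection accepts planted inverted repeats and rejects random context", {
  set.seed(43)
  tag <- rand_dna(24)
  genome <- data.frame(
    id = "chr1",
    sequence = paste0(rand_dna(200), tag, rand_dna(8), rc(tag),
                      rand_dna(200)),
    stringsAsFactors = FALSE)
  hp <- detect_novel_hairpin(tag, genome)
  # a perfect inverted repeat yields a candidate at both arm loci
  # (forward hit on the 5' arm, reverse-complement hit on the 3' arm)
  expect_equal(nrow(hp), 2L)
  expect_true(all(hp$arm == "5p"))
  expect_true(all(hp$stem_pairs >= 18L))

  # the same tag in a purely random context is rejected
  genome2 <- data.frame(id = "chr1",
                        sequence = paste0(rand_dna(200), tag, rand_dna(200)),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(detect_novel_hairpin(tag, genome2)), 0L)

  # a tag spanning the loop lies on no single arm
  half1 <- rand_dna(12)
  spanning <- paste0(half1, rand_dna(8), rc(half1))  # 32 nt: arm|loop|arm
  genome3 <- data.frame(id = "chr1",
                        sequence = paste0(rand_dna(150), spanning,
                                          rand_dna(150)),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(detect_novel_hairpin(spanning, genome3)), 0L)

  # minus-strand mapping is detected too
  genome4 <- data.frame(
    id = "chr1",
    sequence = rc(paste0(rand_dna(180), tag, rand_dna(8), rc(tag),
                         rand_dna(180))),
    stringsAsFactors = FALSE)
  expect_equal(nrow(detect_novel_hairpin(tag, genome4)), 2L)
})

test_that("catalog building aggregates identical names and partitions tags", {
  prec <- make_precursor("osa-MIR8301", seed = 51)
  mat <- prec_mature5(prec)
  genome <- data.frame(id = "chr1", sequence = rand_dna(400),
                       stringsAsFactors = FALSE)
  # two tags both resolving to the bare mature name cannot exist
  # (names are derived from sequence), so check aggregation over
  # duplicate-sequence rows is by name after classification
  tags <- make_tags(c(mat, prec_arm3_seq(prec), rand_dna(21)),
                    list(A = c(10L, 20L, 30L), B = c(1L, 2L, 3L)))
  res <- build_catalog(tags, prec, NULL, genome)
  expect_equal(sort(res$catalog$category),
               sort(c("KNOWN_RICE_MATURE", "KNOWN_RICE_MATURE")))
  # every tag got exactly one category or none
  expect_true(all(is.na(res$assignments$category) |
                    res$assignments$category %in%
                      c("KNOWN_RICE_MATURE",
                        "NOVEL_ARM_OF_RICE_PRECURSOR",
                        "KNOWN_OTHER_SPECIES_GENOME_MAPPED",
                        "NOVEL_ARM_OF_OTHER_SPECIES",
                        "NOVEL_PC_CANDIDATE")))
  # the random tag is unassigned
  expect_true(is.na(res$assignments$category[3]))
})
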